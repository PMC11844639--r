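#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.2) into a [genotype_data()] object. Dosage is the
#' effect (ALT) allele count from the GT field, or the DS field when
#' present. Coordinates stay 1-based as in the VCF.
#'
#' Multi-allelic records are rejected by default: silently splitting
#' them risks allele mismatches between platforms, so the caller must
#' opt in via `multiallelic = "split"` (each ALT allele becomes its own
#' bi-allelic variant, dosage counting only that allele).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param samples Optional character vector of sample ids to keep, in
#'   the requested order. Missing samples are an error.
#' @param multiallelic `"reject"` (default) or `"split"`.
#' @return A [genotype_data()]; variant annotation columns
#'   `consequence_class`/`consequence_gene` are populated from the INFO
#'   keys `CSQCLASS` and `CSQGENE` when present, `"none"`/`NA` otherwise.
#' @export
read_genotype_vcf <- function(path, samples = NULL,
                              multiallelic = c("reject", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "reject")
    stop("multi-allelic record(s) at line(s): ",
         paste(which(multi), collapse = ", "),
         " (use multiallelic = 'split' to split them)")

  vcf_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- vcf_samples
  missing <- setdiff(samples, vcf_samples)
  if (length(missing))
    stop("requested sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))

  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")

  count_allele <- function(g, allele) {
    # g: character vector of GT strings for one record
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & g != "." & g != "./." & g != ".|."
    parts <- strsplit(gsub("|", "/", g[ok], fixed = TRUE), "/", fixed = TRUE)
    bad <- vapply(parts, function(p) any(!p %in% c(".", as.character(0:9))),
                  logical(1))
    if (any(bad))
      stop("malformed GT in record: ", paste(g[ok][bad][1]))
    out[ok] <- vapply(parts, function(p) sum(p == as.character(allele)),
                      numeric(1))
    out
  }

  info <- fix[, "INFO"]
  info_key <- function(info, key) {
    vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]*"), info)),
           function(x) if (length(x)) sub(paste0("^;?", key, "="), "", x[1])
           else NA_character_,
           character(1))
  }
  csq_class <- info_key(info, "CSQCLASS")
  csq_gene <- info_key(info, "CSQGENE")

  rows <- list()
  dos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      vid <- fix[i, "ID"]
      if (is.na(vid) || vid == ".")
        vid <- paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[k],
                     sep = ":")
      else if (length(alts) > 1) vid <- paste0(vid, "_alt", k)
      if (has_ds && length(alts) == 1) {
        d <- ds[i, ]
      } else {
        d <- count_allele(gt[i, ], k)
      }
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = vid, chrom = fix[i, "CHROM"],
        pos = as.numeric(fix[i, "POS"]), ref = fix[i, "REF"], alt = alts[k],
        consequence_class = ifelse(is.na(csq_class[i]), "none", csq_class[i]),
        consequence_gene = csq_gene[i], stringsAsFactors = FALSE)
      dos[[length(dos) + 1]] <- d[match(samples, vcf_samples)]
    }
  }
  variants <- do.call(rbind, rows)
  dosages <- do.call(cbind, dos)
  rownames(dosages) <- samples
  genotype_data(dosages, variants)
}

#' Write genotypes to a VCF file
#'
#' Writes a [genotype_data()] object as VCF v4.2. Integer dosages are
#' written as hard genotypes (0/0, 0/1, 1/1) so that a write/read round
#' trip preserves them exactly; fractional dosages are written in a DS
#' field with GT set from the rounded dosage.
#'
#' @param g A [genotype_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path) {
  d <- g$dosages
  v <- g$variants
  frac <- any(abs(d - round(d)) > 1e-9, na.rm = TRUE)
  gt_of <- function(x) c("0/0", "0/1", "1/1")[round(x) + 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
               "##INFO=<ID=CSQGENE,Number=1,Type=String,Description=\"Consequence gene\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               if (frac) "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")),
             con)
  for (j in seq_len(nrow(v))) {
    info <- if (v$consequence_class[j] != "none")
      paste0("CSQCLASS=", v$consequence_class[j],
             ";CSQGENE=", v$consequence_gene[j]) else "."
    x <- d[, j]
    cells <- ifelse(is.na(x), "./.", gt_of(x))
    fmt <- "GT"
    if (frac) {
      cells <- paste0(cells, ":", ifelse(is.na(x), ".", format(x, digits = 6)))
      fmt <- "GT:DS"
    }
    writeLines(paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE),
                       v$variant_id[j], v$ref[j], v$alt[j], ".", "PASS",
                       info, fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a protein abundance matrix from TSV
#'
#' Expects a header row of probe ids and sample ids in the first
#' column (samples in rows). Empty cells become `NA`.
#'
#' @param path TSV path.
#' @param platform `"A"` or `"B"`.
#' @param layer Processing layer tag (default `"raw"`).
#' @return A [protein_matrix()].
#' @export
read_matrix_tsv <- function(path, platform, layer = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  probes <- colnames(df)[-1]
  if (anyDuplicated(probes))
    stop("duplicate probe id in header: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(probes),
              dimnames = list(df[[1]], probes))
  for (j in seq_along(probes)) {
    cell <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], probes[j], cell[bad[1]]))
    m[, j] <- num
  }
  protein_matrix(m, platform = platform, layer = layer)
}

#' Write a protein matrix to TSV
#'
#' @param pm A [protein_matrix()].
#' @param path Output path.
#' @param digits Significant digits for values (default 10).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(pm, path, digits = 10) {
  m <- pm$values
  df <- data.frame(sample_id = rownames(m),
                   signif(m, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Writes any result `data.frame` with a stable column order and one
#' header row; an empty record set yields a header-only file.
#'
#' @param records A `data.frame` (possibly 0 rows, but with columns).
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 10).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(records, path, digits = 10) {
  if (!is.data.frame(records) || ncol(records) == 0)
    stop("records must be a data.frame with a schema (>= 1 column)")
  out <- as.data.frame(records)
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- signif(out[[j]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
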