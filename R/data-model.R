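#' @keywords internal
"_PACKAGE"

#' Construct a sample (participant) table
#'
#' The sample table carries the cohort metadata used throughout the
#' pipeline: covariates for residualization (age, sex, site, plate),
#' the ancestry group label used for stratified concordance analysis,
#' and phenotypes for the epidemiological models.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param age Numeric, years.
#' @param sex Integer/numeric binary code (0/1).
#' @param site Categorical recruitment site (coerced to factor).
#' @param plate Categorical measurement plate (coerced to factor).
#' @param ancestry Character ancestry label; must be one of `groups` or
#'   `"unassigned"`. Unassigned samples are kept in overall analyses and
#'   excluded from per-ancestry stratification.
#' @param bmi Numeric, kg/m^2.
#' @param t2d Binary type-2-diabetes indicator.
#' @param groups Character vector declaring the valid ancestry labels.
#' @param ... Additional per-sample columns (other phenotypes).
#'
#' @return A `data.frame` of class `sample_table` with an
#'   `ancestry_groups` attribute.
#' @export
sample_table <- function(sample_id, age, sex, site, plate, ancestry,
                         bmi = NA_real_, t2d = NA_integer_,
                         groups = sort(setdiff(unique(ancestry), "unassigned")),
                         ...) {
  sample_id <- as.character(sample_id)
  if (anyNA(sample_id) || any(!nzchar(sample_id)))
    stop("sample_id must be non-missing")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  ancestry <- as.character(ancestry)
  bad <- setdiff(unique(ancestry), c(groups, "unassigned"))
  if (length(bad))
    stop("ancestry labels not in declared group set: ",
         paste(bad, collapse = ", "))
  st <- data.frame(sample_id = sample_id, age = as.numeric(age),
                   sex = as.numeric(sex), site = factor(site),
                   plate = factor(plate), ancestry = ancestry,
                   bmi = as.numeric(bmi), t2d = as.integer(t2d),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) st[[nm]] <- extra[[nm]]
  attr(st, "ancestry_groups") <- groups
  class(st) <- c("sample_table", "data.frame")
  st
}

#' Declared ancestry groups of a sample table
#' @param st A [sample_table()].
#' @return Character vector of group labels (excluding `"unassigned"`).
#' @export
ancestry_groups <- function(st) attr(st, "ancestry_groups")

#' Construct a probe map
#'
#' Maps each platform probe to its protein target (UniProt ID, gene
#' symbol) and the gene transcription start site used to define the cis
#' window.
#'
#' @param probe_id Character probe identifiers.
#' @param platform `"A"` (aptamer) or `"B"` (antibody) per probe.
#' @param uniprot_id UniProt accession of the target protein.
#' @param gene_symbol Encoding gene symbol.
#' @param chrom Chromosome of the encoding gene.
#' @param tss Transcription start site, 1-based.
#' @return A `data.frame` of class `probe_map`.
#' @export
probe_map <- function(probe_id, platform, uniprot_id, gene_symbol, chrom, tss) {
  platform <- as.character(platform)
  if (!all(platform %in% c("A", "B")))
    stop("platform must be 'A' or 'B'")
  if (anyNA(uniprot_id) || any(!nzchar(uniprot_id)))
    stop("every probe needs a uniprot_id")
  tss <- as.numeric(tss)
  if (any(tss < 1)) stop("tss must be >= 1")
  key <- paste(probe_id, platform)
  if (anyDuplicated(key))
    stop("duplicate (probe_id, platform): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  pm <- data.frame(probe_id = as.character(probe_id), platform = platform,
                   uniprot_id = as.character(uniprot_id),
                   gene_symbol = as.character(gene_symbol),
                   chrom = as.character(chrom), tss = tss,
                   stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Construct a protein abundance matrix
#'
#' Samples x probes matrix for a single platform, tagged with the
#' processing layer. Downstream stages check the layer so that e.g. the
#' limit of detection is only ever computed on raw-scale values.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns (colnames = probe ids).
#' @param platform `"A"` or `"B"`.
#' @param layer One of `"raw"`, `"transformed"`, `"residualized"`.
#' @return A `protein_matrix` object.
#' @export
protein_matrix <- function(values, platform, layer = "raw") {
  platform <- match.arg(platform, c("A", "B"))
  layer <- match.arg(layer, c("raw", "transformed", "residualized"))
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (any(is.infinite(values))) stop("infinite values not allowed")
  if (is.null(rownames(values))) stop("values needs sample ids as rownames")
  if (is.null(colnames(values))) stop("values needs probe ids as colnames")
  structure(list(values = values, platform = platform, layer = layer),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("<protein_matrix platform=%s layer=%s: %d samples x %d probes>\n",
              x$platform, x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

VALID_CONSEQUENCES <- c("missense", "start_loss", "stop_gain", "stop_loss",
                        "other", "none")

#' Protein-altering consequence classes
#'
#' Consequence classes treated as protein-altering variants (PAVs):
#' missense, start-loss, stop-gain and stop-loss. These can change the
#' epitope recognized by an affinity reagent and so generate apparent
#' abundance differences that are binding artifacts.
#' @return Character vector of PAV consequence classes.
#' @export
pav_classes <- function() c("missense", "start_loss", "stop_gain", "stop_loss")

#' Construct genotype data
#'
#' @param dosages Numeric matrix samples x variants of effect-allele
#'   dosages in `[0, 2]`; rownames = sample ids, colnames = variant ids.
#' @param variants `data.frame` with columns `variant_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, and optionally `consequence_class`
#'   (one of missense, start_loss, stop_gain, stop_loss, other, none)
#'   and `consequence_gene`.
#' @return A `genotype_data` object.
#' @export
genotype_data <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (anyDuplicated(variants$variant_id)) stop("variant_id must be unique")
  if (any(variants$pos < 1)) stop("variant pos must be >= 1")
  if (is.null(variants$consequence_class))
    variants$consequence_class <- "none"
  if (is.null(variants$consequence_gene))
    variants$consequence_gene <- NA_character_
  bad <- setdiff(unique(variants$consequence_class), VALID_CONSEQUENCES)
  if (length(bad))
    stop("unknown consequence_class: ", paste(bad, collapse = ", "))
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns and variant rows disagree")
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data: %d samples x %d variants>\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Construct a negative-control table
#'
#' Holds per-probe negative-control measurements (raw NPX-like scale)
#' from which the limit of detection is derived.
#'
#' @param controls Named list: probe id -> numeric vector of control
#'   values; each probe needs at least 2 values so a sample SD exists.
#' @return A `negative_control_table` object.
#' @export
negative_control_table <- function(controls) {
  if (is.null(names(controls)) || any(!nzchar(names(controls))))
    stop("controls must be a named list keyed by probe_id")
  nv <- vapply(controls, function(v) sum(!is.na(v)), integer(1))
  if (any(nv < 2))
    stop("need >= 2 control values per probe: ",
         paste(names(controls)[nv < 2], collapse = ", "))
  structure(list(controls = lapply(controls, as.numeric)),
            class = "negative_control_table")
}

#' Construct an external sentinel table
#'
#' External evidence (eQTL, mass-spectrometry pQTL, GWAS-catalog-like)
#' used to flag credible sets that contain a previously reported
#' sentinel variant, with per-context effect directions.
#'
#' @param source One of `"eqtl"`, `"ms_pqtl"`, `"gwas"` per row.
#' @param variant_id Sentinel variant identifier.
#' @param gene Target gene (required for eqtl rows; may be NA for gwas).
#' @param context Context of the effect direction (e.g. a tissue).
#' @param sign Effect direction, `+1` or `-1`.
#' @return A `data.frame` of class `sentinel_table`.
#' @export
sentinel_table <- function(source, variant_id, gene = NA_character_,
                           context = NA_character_, sign) {
  source <- as.character(source)
  if (!all(source %in% c("eqtl", "ms_pqtl", "gwas")))
    stop("source must be eqtl, ms_pqtl or gwas")
  if (anyNA(variant_id)) stop("variant_id required")
  gene <- as.character(gene)
  if (any(source == "eqtl" & (is.na(gene) | !nzchar(gene))))
    stop("eqtl rows require a target gene")
  sign <- as.numeric(sign)
  if (!all(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  st <- data.frame(source = source, variant_id = as.character(variant_id),
                   gene = gene, context = as.character(context), sign = sign,
                   stringsAsFactors = FALSE)
  class(st) <- c("sentinel_table", "data.frame")
  st
}

#' Check that an object's samples match the sample table order
#'
#' Every pipeline stage verifies, rather than assumes, that matrices
#' are aligned with the sample table. Mismatched order or membership is
#' an error, never silently reordered.
#'
#' @param x A `protein_matrix`, `genotype_data`, or matrix with rownames.
#' @param st A [sample_table()].
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_sample_alignment <- function(x, st) {
  ids <- if (inherits(x, "protein_matrix")) rownames(x$values)
         else if (inherits(x, "genotype_data")) rownames(x$dosages)
         else rownames(x)
  if (is.null(ids)) stop("object carries no sample ids")
  if (!identical(ids, st$sample_id))
    stop("sample ids do not match the sample table order")
  invisible(TRUE)
}
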