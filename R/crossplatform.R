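#' Classify a cross-platform pair of credible sets
#'
#' Two credible sets for the same protein target, one per platform,
#' overlap when they share at least one member variant. An overlapping
#' pair is compared for effect direction only when at least one
#' platform's sentinel (lead) variant is contained in the other
#' platform's set; the comparison uses that shared sentinel's
#' per-platform betas. Same sign: `overlapping_concordant`; opposite:
#' `overlapping_discordant`; overlap without a shared sentinel:
#' `overlapping_uncompared`. A set present on one platform only gives
#' `A_only` / `B_only`.
#'
#' The compared sentinel's beta on each platform comes from the set's
#' lead when it is the lead, else from the set's recorded per-round
#' member statistics, else from the optional `stats_A` / `stats_B`
#' association tables.
#'
#' @param set_A,set_B `credible_set` objects (either may be `NULL`).
#' @param stats_A,stats_B Optional association tables (`variant_id`,
#'   `beta`) used as a fallback source for the compared sentinel's
#'   beta.
#' @return List with `category`, `compared_variant` (or `NA`),
#'   `beta_A`, `beta_B`.
#' @export
classify_pair <- function(set_A, set_B, stats_A = NULL, stats_B = NULL) {
  if (is.null(set_A) && is.null(set_B)) stop("both sets absent")
  if (is.null(set_B))
    return(list(category = "A_only", compared_variant = NA_character_,
                beta_A = set_A$lead$beta, beta_B = NA_real_))
  if (is.null(set_A))
    return(list(category = "B_only", compared_variant = NA_character_,
                beta_A = NA_real_, beta_B = set_B$lead$beta))
  shared <- intersect(set_A$members, set_B$members)
  if (length(shared) == 0)
    return(list(category = "non_overlapping", compared_variant = NA_character_,
                beta_A = NA_real_, beta_B = NA_real_))
  beta_of <- function(set, stats, vid) {
    if (identical(set$lead$variant_id, vid)) return(set$lead$beta)
    if (!is.null(set$member_stats)) {
      i <- match(vid, set$member_stats$variant_id)
      if (!is.na(i) && !is.na(set$member_stats$beta[i]))
        return(set$member_stats$beta[i])
    }
    if (!is.null(stats)) {
      i <- match(vid, stats$variant_id)
      if (!is.na(i)) return(stats$beta[i])
    }
    NA_real_
  }
  # prefer comparing at a lead that the other platform's set contains
  cand <- c(if (set_A$lead$variant_id %in% set_B$members) set_A$lead$variant_id,
            if (set_B$lead$variant_id %in% set_A$members) set_B$lead$variant_id)
  for (vid in cand) {
    bA <- beta_of(set_A, stats_A, vid)
    bB <- beta_of(set_B, stats_B, vid)
    if (!is.na(bA) && !is.na(bB)) {
      cat_ <- if (sign(bA) == sign(bB)) "overlapping_concordant"
              else "overlapping_discordant"
      return(list(category = cat_, compared_variant = vid,
                  beta_A = bA, beta_B = bB))
    }
  }
  list(category = "overlapping_uncompared", compared_variant = NA_character_,
       beta_A = NA_real_, beta_B = NA_real_)
}

#' Does a credible set contain a protein-altering variant?
#'
#' True iff any member variant has a protein-altering consequence
#' (missense, start-loss, stop-gain, stop-loss) annotated for the
#' target gene.
#'
#' @param set A `credible_set`.
#' @param variants Variant table with `variant_id`,
#'   `consequence_class`, `consequence_gene`.
#' @param target_gene Gene symbol encoding the measured protein.
#' @return Logical.
#' @export
contains_pav <- function(set, variants, target_gene) {
  i <- match(set$members, variants$variant_id)
  i <- i[!is.na(i)]
  any(variants$consequence_class[i] %in% pav_classes() &
        variants$consequence_gene[i] == target_gene, na.rm = TRUE)
}

#' Effect-allele frequencies per ancestry group
#'
#' EAF is computed on observed alleles only (missing dosages drop out;
#' no imputation here): `sum(dosage) / (2 * n_nonmissing)` per group.
#' Allele counts are retained for the contingency chi-square.
#'
#' @param g A [genotype_data()].
#' @param st A [sample_table()] aligned with `g`; samples labeled
#'   `"unassigned"` are excluded.
#' @return `data.frame` with one row per (variant, group): `variant_id`,
#'   `group`, `eaf`, `alt_count`, `total_alleles`.
#' @export
eaf_by_group <- function(g, st) {
  check_sample_alignment(g, st)
  groups <- ancestry_groups(st)
  empty <- groups[!groups %in% st$ancestry]
  if (length(empty)) stop("empty ancestry group(s): ",
                          paste(empty, collapse = ", "))
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    sel <- st$ancestry == groups[k]
    d <- g$dosages[sel, , drop = FALSE]
    nn <- colSums(!is.na(d))
    ac <- colSums(d, na.rm = TRUE)
    out[[k]] <- data.frame(variant_id = colnames(d), group = groups[k],
                           eaf = ifelse(nn > 0, ac / (2 * nn), NA_real_),
                           alt_count = ac, total_alleles = 2 * nn,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square for allele-frequency differences across groups
#'
#' Contingency chi-square on the groups x {alt, ref} table of allele
#' counts; `df = #groups - 1`. When the pooled EAF is 0 or 1 the
#' expected counts vanish and the statistic is defined as 0 with
#' `p = 1` and a degenerate flag.
#'
#' @param alt_count Per-group effect-allele counts.
#' @param total_alleles Per-group total allele counts (2n).
#' @return List with `x2`, `df`, `p`, `degenerate`.
#' @export
eaf_chi_square <- function(alt_count, total_alleles) {
  if (length(alt_count) != length(total_alleles) || length(alt_count) < 2)
    stop("need >= 2 groups of aligned counts")
  if (any(total_alleles <= 0)) stop("total alleles must be > 0 per group")
  df <- length(alt_count) - 1L
  pooled <- sum(alt_count) / sum(total_alleles)
  if (pooled <= 0 || pooled >= 1)
    return(list(x2 = 0, df = df, p = 1, degenerate = TRUE))
  exp_alt <- total_alleles * pooled
  exp_ref <- total_alleles * (1 - pooled)
  ref_count <- total_alleles - alt_count
  x2 <- sum((alt_count - exp_alt)^2 / exp_alt) +
    sum((ref_count - exp_ref)^2 / exp_ref)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Upper-tail chi-square p-value
#'
#' Convenience mapping of an allele-frequency chi-square statistic to
#' its upper-tail probability.
#'
#' @param x2 Chi-square statistic.
#' @param df Degrees of freedom (for K ancestry groups, K - 1).
#' @return Upper-tail probability.
#' @export
chi_square_p <- function(x2, df) stats::pchisq(x2, df, lower.tail = FALSE)

#' Flag ancestry-differentiated variants by empirical quantile
#'
#' A variant is called differentiated when its allele-frequency
#' chi-square exceeds the empirical 75th percentile
#' (linear-interpolation quantile) of all tested variants; the
#' comparison is strict, so with all-equal statistics nothing is
#' flagged.
#'
#' @param x2_values Chi-square statistics of all tested variants.
#' @param quantile Quantile defining the threshold (default 0.75).
#' @return List with `threshold` and logical `flags`.
#' @export
differentiation_flags <- function(x2_values, quantile = 0.75) {
  if (length(x2_values) < 4) stop("need >= 4 values")
  thr <- unname(stats::quantile(x2_values, quantile, type = 7, na.rm = TRUE))
  list(threshold = thr, flags = !is.na(x2_values) & x2_values > thr)
}

#' Ancestry-differentiation table for a set of variants
#'
#' Combines [eaf_by_group()], [eaf_chi_square()] and
#' [differentiation_flags()] into one record per variant.
#'
#' @param g A [genotype_data()].
#' @param st A [sample_table()].
#' @param quantile Threshold quantile (default 0.75).
#' @return `data.frame` with per-group `eaf_<g>` columns, `x2`, `df`,
#'   `p`, `differentiated`, plus the threshold as an attribute.
#' @export
ancestry_differentiation <- function(g, st, quantile = 0.75) {
  eafs <- eaf_by_group(g, st)
  groups <- ancestry_groups(st)
  vids <- g$variants$variant_id
  out <- data.frame(variant_id = vids, stringsAsFactors = FALSE)
  for (gp in groups)
    out[[paste0("eaf_", gp)]] <-
      eafs$eaf[eafs$group == gp][match(vids, eafs$variant_id[eafs$group == gp])]
  stats_ <- lapply(vids, function(v) {
    rows <- eafs[eafs$variant_id == v, ]
    eaf_chi_square(rows$alt_count, rows$total_alleles)
  })
  out$x2 <- vapply(stats_, `[[`, numeric(1), "x2")
  out$df <- vapply(stats_, `[[`, integer(1), "df")
  out$p <- vapply(stats_, `[[`, numeric(1), "p")
  fl <- differentiation_flags(out$x2, quantile)
  out$differentiated <- fl$flags
  attr(out, "threshold") <- fl$threshold
  out
}

merge_intervals <- function(chrom, start, end) {
  ord <- order(chrom, start, end)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  out <- list()
  cur <- NULL
  for (i in seq_along(chrom)) {
    if (!is.null(cur) && cur$chrom == chrom[i] && start[i] <= cur$end) {
      cur$end <- max(cur$end, end[i])
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- list(chrom = chrom[i], start = start[i], end = end[i])
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  data.frame(chrom = vapply(out, `[[`, character(1), "chrom"),
             start = vapply(out, `[[`, numeric(1), "start"),
             end = vapply(out, `[[`, numeric(1), "end"),
             stringsAsFactors = FALSE)
}

#' Pleiotropic trans-pQTL regions
#'
#' Builds 1 Mb windows (+/- `half_window` bp) around the sentinel
#' variants of significant trans credible sets, merges overlapping
#' windows on the same chromosome transitively (across both platforms,
#' so cross-platform regions overlapping by >= 1 bp become one paired
#' region), counts the distinct probes per platform whose significant
#' trans lead lies in each region, and categorizes: at least
#' `min_proteins` on both platforms is `shared_pleiotropic`; at least
#' `min_proteins` on one and at most `max_other` on the other is
#' platform-specific; anything else is `not_pleiotropic`.
#'
#' @param sentinels `data.frame` with columns `platform`, `probe_id`,
#'   `chrom`, `pos` (sentinel position), one row per significant trans
#'   credible set.
#' @param half_window Half-width of the sentinel window in bp
#'   (default 5e5, i.e. a 1 Mb window around the sentinel).
#' @param min_proteins Pleiotropy threshold (default 5).
#' @param max_other Maximum count on the other platform for a
#'   platform-specific call (default 1).
#' @return `data.frame` of regions: `chrom`, `start`, `end`,
#'   `protein_count_A`, `protein_count_B`, `category`.
#' @export
trans_regions <- function(sentinels, half_window = 5e5, min_proteins = 5,
                          max_other = 1) {
  if (nrow(sentinels) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), protein_count_A = integer(),
                      protein_count_B = integer(), category = character()))
  regions <- merge_intervals(as.character(sentinels$chrom),
                             pmax(1, sentinels$pos - half_window),
                             sentinels$pos + half_window)
  count_in <- function(reg, plat) {
    sel <- sentinels$platform == plat &
      as.character(sentinels$chrom) == reg$chrom &
      sentinels$pos >= reg$start & sentinels$pos <= reg$end
    length(unique(sentinels$probe_id[sel]))
  }
  regions$protein_count_A <- vapply(seq_len(nrow(regions)), function(i)
    count_in(regions[i, ], "A"), integer(1))
  regions$protein_count_B <- vapply(seq_len(nrow(regions)), function(i)
    count_in(regions[i, ], "B"), integer(1))
  a <- regions$protein_count_A; b <- regions$protein_count_B
  regions$category <- ifelse(
    a >= min_proteins & b >= min_proteins, "shared_pleiotropic",
    ifelse(a >= min_proteins & b <= max_other, "A_specific",
           ifelse(b >= min_proteins & a <= max_other, "B_specific",
                  "not_pleiotropic")))
  regions
}

#' Flag credible sets containing external sentinel variants
#'
#' For each credible set, checks whether any member is a sentinel in
#' an external evidence table (eQTL / MS-pQTL / GWAS-like). For eqtl
#' and ms_pqtl rows the sentinel must target the set's gene. Direction
#' concordance requires the pQTL lead's sign to equal the external
#' sign in every context in which the sentinel is reported; sentinels
#' reported with internally conflicting signs exclude the set from
#' direction comparison.
#'
#' @param sets List of `credible_set` objects.
#' @param ext A [sentinel_table()].
#' @param target_genes Named character vector probe_id -> gene symbol.
#' @return `data.frame`: `probe_id`, `platform`, `signal_index`,
#'   `matched` (any sentinel member), `matched_variant`, `concordant`
#'   (NA when unmatched or excluded), `excluded_conflict`.
#' @export
sentinel_overlap <- function(sets, ext, target_genes) {
  rows <- lapply(sets, function(s) {
    gene <- unname(target_genes[s$probe_id])
    rel <- ext[ext$variant_id %in% s$members &
                 (ext$source == "gwas" |
                    (!is.na(ext$gene) & ext$gene == gene)), , drop = FALSE]
    if (nrow(rel) == 0)
      return(data.frame(probe_id = s$probe_id, platform = s$platform,
                        signal_index = s$signal_index, matched = FALSE,
                        matched_variant = NA_character_, concordant = NA,
                        excluded_conflict = FALSE, stringsAsFactors = FALSE))
    conflict <- any(tapply(rel$sign, rel$variant_id,
                           function(sg) length(unique(sg)) > 1))
    conc <- if (conflict) NA else
      all(rel$sign == sign(s$lead$beta))
    data.frame(probe_id = s$probe_id, platform = s$platform,
               signal_index = s$signal_index, matched = TRUE,
               matched_variant = rel$variant_id[1],
               concordant = if (conflict) NA else conc,
               excluded_conflict = conflict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify all cross-platform credible-set pairs for shared proteins
#'
#' Matches cis credible sets across platforms per UniProt target
#' (pairing sets that share at least one member; unmatched sets become
#' platform-only records), classifies each pair, and flags
#' protein-altering members per platform.
#'
#' @param sets_A,sets_B Credible-set lists from [map_pqtl()] for the
#'   two platforms.
#' @param probes A [probe_map()].
#' @param variants Variant annotation table (from [genotype_data()]).
#' @param stats_A,stats_B Optional named lists probe_id -> association
#'   table, used to fetch the compared sentinel's beta on the platform
#'   where it is not the lead.
#' @param kind Which signals to classify (default `"cis"`).
#' @return `data.frame` with `uniprot_id`, probe/signal columns,
#'   `category`, `compared_variant`, `beta_A`, `beta_B`, `pav_in_A`,
#'   `pav_in_B`.
#' @export
classify_all_pairs <- function(sets_A, sets_B, probes, variants,
                               stats_A = NULL, stats_B = NULL,
                               kind = "cis") {
  up_of <- stats::setNames(probes$uniprot_id, probes$probe_id)
  gene_of <- stats::setNames(probes$gene_symbol, probes$probe_id)
  sets_A <- Filter(function(s) s$kind == kind && s$significant, sets_A)
  sets_B <- Filter(function(s) s$kind == kind && s$significant, sets_B)
  ups <- union(vapply(sets_A, function(s) up_of[[s$probe_id]], character(1)),
               vapply(sets_B, function(s) up_of[[s$probe_id]], character(1)))
  rows <- list()
  for (up in ups) {
    sa <- Filter(function(s) up_of[[s$probe_id]] == up, sets_A)
    sb <- Filter(function(s) up_of[[s$probe_id]] == up, sets_B)
    used_b <- rep(FALSE, length(sb))
    emit <- function(A, B) {
      cl <- classify_pair(A, B,
                          stats_A = if (!is.null(A)) stats_A[[A$probe_id]],
                          stats_B = if (!is.null(B)) stats_B[[B$probe_id]])
      gene <- gene_of[[if (!is.null(A)) A$probe_id else B$probe_id]]
      rows[[length(rows) + 1]] <<- data.frame(
        uniprot_id = up,
        probe_id_A = if (!is.null(A)) A$probe_id else NA_character_,
        signal_A = if (!is.null(A)) A$signal_index else NA_integer_,
        probe_id_B = if (!is.null(B)) B$probe_id else NA_character_,
        signal_B = if (!is.null(B)) B$signal_index else NA_integer_,
        category = cl$category, compared_variant = cl$compared_variant,
        beta_A = cl$beta_A, beta_B = cl$beta_B,
        pav_in_A = if (!is.null(A)) contains_pav(A, variants, gene) else NA,
        pav_in_B = if (!is.null(B)) contains_pav(B, variants, gene) else NA,
        stringsAsFactors = FALSE)
    }
    for (A in sa) {
      match_j <- 0
      for (j in seq_along(sb)) {
        if (!used_b[j] && length(intersect(A$members, sb[[j]]$members))) {
          match_j <- j; break
        }
      }
      if (match_j > 0) {
        used_b[match_j] <- TRUE
        emit(A, sb[[match_j]])
      } else emit(A, NULL)
    }
    for (j in seq_along(sb)) if (!used_b[j]) emit(NULL, sb[[j]])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(uniprot_id = character(), probe_id_A = character(),
               signal_A = integer(), probe_id_B = character(),
               signal_B = integer(), category = character(),
               compared_variant = character(), beta_A = numeric(),
               beta_B = numeric(), pav_in_A = logical(),
               pav_in_B = logical())
  rownames(out) <- NULL
  out
}
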