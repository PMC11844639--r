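#' Pearson correlation over complete pairs
#'
#' Correlates two aligned measure vectors using pairwise deletion:
#' only indices where both values are non-missing contribute.
#'
#' @param x,y Numeric vectors, aligned by sample.
#' @return List with `r` (Pearson correlation) and `n` (complete pairs
#'   used). Errors if fewer than 3 complete pairs or either vector is
#'   constant over the complete pairs.
#' @export
pairwise_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 complete pairs")
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero variance over complete pairs")
  list(r = stats::cor(xs, ys), n = n)
}

#' Select the best probe pair for a protein
#'
#' Given candidate cross-platform probe pairs for one UniProt target,
#' returns the pair with the highest inter-platform correlation. Ties
#' break deterministically by lexicographic (probe_A, probe_B).
#'
#' @param pairs `data.frame` with columns `probe_A`, `probe_B`, `r`.
#' @return The selected row of `pairs`.
#' @export
best_probe_pair <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0)
    stop("no candidate probe pairs")
  ord <- order(-pairs$r, pairs$probe_A, pairs$probe_B)
  pairs[ord[1], , drop = FALSE]
}

#' Cochran's Q heterogeneity of correlations across groups
#'
#' Tests whether per-group Pearson correlations share a common value.
#' Each correlation is Fisher-Z transformed, `z = atanh(r)`, with
#' weight `w = n - 3` (the inverse variance of z). Then
#' `Q = sum w (z - zbar)^2` with `zbar` the weighted mean, referred to
#' a chi-square distribution with `#groups - 1` degrees of freedom.
#'
#' Groups with `n < 4` carry non-positive weight and are excluded with
#' a warning, reducing the degrees of freedom.
#'
#' @param r Numeric vector of per-group correlations, `|r| < 1`.
#' @param n Integer vector of per-group sample sizes.
#' @return List with `Q`, `df`, `p`, and `groups_used`.
#' @export
correlation_heterogeneity <- function(r, n) {
  if (length(r) != length(n)) stop("r and n must align")
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("|r| = 1 gives infinite Fisher z")
  keep <- !is.na(r) & !is.na(n) & n >= 4
  if (any(!keep))
    warning(sum(!keep), " group(s) with n < 4 (or missing r) excluded")
  r <- r[keep]; n <- n[keep]
  if (length(r) < 2) stop("need >= 2 groups with n >= 4")
  z <- atanh(r)
  w <- n - 3
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  df <- length(r) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       groups_used = length(r))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Per-protein cross-platform concordance table
#'
#' For each UniProt target measured on both platforms, selects the
#' best probe pair (highest overall correlation across all samples),
#' then computes per-ancestry correlations (samples labeled
#' `"unassigned"` are excluded from stratification) and the
#' Fisher-Z / Cochran's-Q heterogeneity test across groups.
#'
#' @param pm_a,pm_b [protein_matrix()] objects (transformed layer) for
#'   platforms A and B, aligned with `st`.
#' @param probes A [probe_map()] covering the probes of both matrices.
#' @param st A [sample_table()].
#' @param min_group_n Minimum per-group complete pairs for a group to
#'   enter the heterogeneity test (default 4).
#' @return A `data.frame` with one row per UniProt target: probe pair,
#'   overall `r`/`n`, flat per-group `r_<g>`/`n_<g>` columns, `Q`,
#'   `df`, `p_het`.
#' @export
concordance_table <- function(pm_a, pm_b, probes, st, min_group_n = 4) {
  check_sample_alignment(pm_a, st)
  check_sample_alignment(pm_b, st)
  groups <- ancestry_groups(st)
  pa <- probes[probes$platform == "A" & probes$probe_id %in% colnames(pm_a$values), ]
  pb <- probes[probes$platform == "B" & probes$probe_id %in% colnames(pm_b$values), ]
  shared <- intersect(pa$uniprot_id, pb$uniprot_id)
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    up <- shared[i]
    cand_a <- pa$probe_id[pa$uniprot_id == up]
    cand_b <- pb$probe_id[pb$uniprot_id == up]
    cand <- expand.grid(probe_A = cand_a, probe_B = cand_b,
                        stringsAsFactors = FALSE)
    cand$r <- NA_real_; cand$n <- NA_integer_
    for (j in seq_len(nrow(cand))) {
      pc <- tryCatch(
        pairwise_correlation(pm_a$values[, cand$probe_A[j]],
                             pm_b$values[, cand$probe_B[j]]),
        error = function(e) NULL)
      if (!is.null(pc)) { cand$r[j] <- pc$r; cand$n[j] <- pc$n }
    }
    cand <- cand[!is.na(cand$r), , drop = FALSE]
    if (nrow(cand) == 0) next
    best <- best_probe_pair(cand)
    xa <- pm_a$values[, best$probe_A]
    xb <- pm_b$values[, best$probe_B]
    rg <- ng <- stats::setNames(rep(NA_real_, length(groups)), groups)
    for (g in groups) {
      sel <- st$ancestry == g
      pc <- tryCatch(pairwise_correlation(xa[sel], xb[sel]),
                     error = function(e) NULL)
      if (!is.null(pc)) { rg[g] <- pc$r; ng[g] <- pc$n }
    }
    het <- tryCatch(
      suppressWarnings(
        correlation_heterogeneity(rg[ng >= min_group_n & !is.na(ng)],
                                  ng[ng >= min_group_n & !is.na(ng)])),
      error = function(e) list(Q = NA_real_, df = NA_integer_, p = NA_real_))
    row <- data.frame(uniprot_id = up, probe_id_A = best$probe_A,
                      probe_id_B = best$probe_B, r_overall = best$r,
                      n_overall = best$n, stringsAsFactors = FALSE)
    for (g in groups) {
      row[[paste0("r_", g)]] <- rg[[g]]
      row[[paste0("n_", g)]] <- ng[[g]]
    }
    row$Q <- het$Q; row$df <- het$df; row$p_het <- het$p
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(uniprot_id = character(), probe_id_A = character(),
                      probe_id_B = character(), r_overall = numeric(),
                      n_overall = integer(), Q = numeric(), df = integer(),
                      p_het = numeric())
  rownames(out) <- NULL
  out
}
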