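#' Marginal association scan of one phenotype against variants
#'
#' Simple per-variant linear regression of a residualized measure on
#' effect-allele dosage: `beta = cov(g, y) / var(g)`, standard error
#' from the residual variance on `n - 2` degrees of freedom, two-sided
#' p from the t distribution. Missing dosages are mean-imputed per
#' variant for the scan (never for allele-frequency counting, which is
#' done elsewhere on observed alleles only). Monomorphic variants are
#' skipped with `flag = "monomorphic"`; fits with zero residual
#' variance are flagged `"degenerate"`.
#'
#' @param pheno Numeric phenotype vector (residualized measure).
#' @param g A [genotype_data()] aligned with `pheno`.
#' @param variant_ids Optional subset of variant ids to scan.
#' @param covariates Optional numeric covariate matrix (no intercept
#'   column needed); the coefficient then equals the variant term of
#'   the multiple regression `pheno ~ variant + covariates`, computed
#'   by residualizing both sides on the covariates, with degrees of
#'   freedom reduced accordingly. Used for PAV-as-covariate remapping.
#' @return `data.frame` with `variant_id`, `beta`, `se`, `p`, `n`,
#'   `flag` (`"ok"`, `"monomorphic"`, `"degenerate"`).
#' @export
association_scan <- function(pheno, g, variant_ids = NULL, covariates = NULL) {
  d <- g$dosages
  if (length(pheno) != nrow(d)) stop("pheno and genotypes must align")
  if (is.null(variant_ids)) variant_ids <- colnames(d)
  keep <- !is.na(pheno)
  n <- sum(keep)
  if (n < 10) stop("n < 10: refusing degenerate inference")
  y <- pheno[keep]
  d <- d[keep, variant_ids, drop = FALSE]
  k_cov <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    k_cov <- ncol(covariates)
    xc <- cbind(1, covariates)
    qc <- qr(xc)
    y <- qr.resid(qc, y)
  }
  res <- data.frame(variant_id = variant_ids, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n = n, flag = "ok",
                    stringsAsFactors = FALSE)
  dfree <- n - 2 - k_cov
  ybar <- mean(y)
  for (j in seq_along(variant_ids)) {
    x <- d[, j]
    nas <- is.na(x)
    if (any(nas)) x[nas] <- mean(x, na.rm = TRUE)
    if (k_cov > 0) x <- qr.resid(qc, x)
    sxx <- sum((x - mean(x))^2)
    if (sxx <= n * .Machine$double.eps || length(unique(round(x, 12))) < 2) {
      res$flag[j] <- "monomorphic"
      next
    }
    b <- sum((x - mean(x)) * (y - ybar)) / sxx
    ssr <- sum((y - ybar - b * (x - mean(x)))^2)
    if (ssr <= .Machine$double.eps * max(sum((y - ybar)^2), 1)) {
      res$beta[j] <- b
      res$flag[j] <- "degenerate"
      next
    }
    se <- sqrt(ssr / dfree / sxx)
    res$beta[j] <- b
    res$se[j] <- se
    res$p[j] <- 2 * stats::pt(abs(b / se), dfree, lower.tail = FALSE)
  }
  res
}

#' Variants inside / outside the cis window of a gene
#'
#' The cis window is the closed interval within 1 Mb of the gene's
#' transcription start site on the same chromosome; everything else
#' (same chromosome beyond 1 Mb, or any other chromosome) is the trans
#' universe.
#'
#' @param variants Variant table with `variant_id`, `chrom`, `pos`.
#' @param chrom,tss Gene chromosome and transcription start site.
#' @param window Half-width in bp (default 1e6).
#' @return List with `cis` and `trans` character vectors of variant ids.
#' @export
cis_window <- function(variants, chrom, tss, window = 1e6) {
  if (tss < 1) stop("tss must be >= 1")
  incis <- variants$chrom == as.character(chrom) &
    abs(variants$pos - tss) <= window
  list(cis = variants$variant_id[incis],
       trans = variants$variant_id[!incis])
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation of dosages over shared non-missing
#' samples.
#'
#' @param g_i,g_j Numeric dosage vectors, aligned.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]; gj <- g_j[ok]
  if (stats::sd(gi) == 0 || stats::sd(gj) == 0)
    stop("monomorphic input")
  stats::cor(gi, gj)^2
}

#' Wakefield approximate Bayes factor
#'
#' `ABF = sqrt(se^2 / (se^2 + W)) * exp(z^2 W / (2 (se^2 + W)))` with
#' `z = beta / se` and prior effect variance `W`.
#'
#' @param beta,se Effect estimate and standard error.
#' @param W Prior variance of the effect (default 0.04).
#' @param log Return the natural log of the ABF (used internally to
#'   avoid overflow at very large z).
#' @return Numeric ABF (in favour of association), or its log.
#' @export
wakefield_abf <- function(beta, se, W = 0.04, log = FALSE) {
  z2 <- (beta / se)^2
  v <- se^2
  labf <- 0.5 * base::log(v / (v + W)) + z2 * W / (2 * (v + W))
  if (log) labf else exp(labf)
}

new_credible_set <- function(probe_id, platform, signal_index, members, pip,
                             lead, kind, significant, member_stats = NULL) {
  structure(list(probe_id = probe_id, platform = platform,
                 signal_index = signal_index, members = members, pip = pip,
                 lead = lead, kind = kind, significant = significant,
                 member_stats = member_stats),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf(
    "<credible_set %s/%s signal %d (%s): lead %s beta=%.3g se=%.3g p=%.3g; %d member(s)>\n",
    x$probe_id, x$platform, x$signal_index, x$kind, x$lead$variant_id,
    x$lead$beta, x$lead$se, x$lead$p, length(x$members)))
  invisible(x)
}

#' Stepwise-conditional fine-mapping into 95% credible sets
#'
#' Deterministic fine-mapper for one probe and one variant universe
#' (cis or trans). Forward pass: each round (1) the top variant by
#' p-value becomes the signal lead, provided it passes the
#' significance threshold for the signal kind; (2) the phenotype is
#' residualized on the lead dosage and the scan repeats, up to
#' `max_signals` rounds or until no variant passes the threshold.
#' Refinement pass: each signal's statistics are then recomputed
#' conditional on the other signals' lead dosages, Wakefield
#' approximate Bayes factors are computed for all candidate variants
#' from that signal's (beta, se), posterior inclusion probabilities
#' are the normalized ABFs, and the credible set is the smallest
#' pip-ranked set with cumulative pip >= `coverage`. Conditioning on
#' the other leads keeps each credible set specific to its own signal
#' when two independent signals have comparable marginal strength
#' (otherwise both would enter the first round's set and the LD
#' deduplication would merge genuinely distinct signals). Signals
#' whose conditional lead no longer passes the threshold are flagged
#' not significant.
#'
#' @param pheno Residualized phenotype vector.
#' @param g A [genotype_data()] aligned with `pheno`.
#' @param variant_ids Candidate variant ids (the cis window or the
#'   trans universe).
#' @param kind `"cis"` or `"trans"`; selects the significance
#'   threshold.
#' @param probe_id,platform Labels recorded in the output sets.
#' @param threshold Significance threshold on the lead p-value;
#'   defaults to 5e-8 for cis and 1e-11 for trans.
#' @param W Wakefield prior variance (default 0.04).
#' @param coverage Credible-set coverage (default 0.95).
#' @param max_signals Maximum number of conditional rounds (default 5).
#' @param covariates Optional covariate matrix passed to
#'   [association_scan()] (e.g. a PAV dosage for adjusted remapping).
#' @return List of `credible_set` objects (possibly empty).
#' @export
finemap <- function(pheno, g, variant_ids, kind = c("cis", "trans"),
                    probe_id = "", platform = "A",
                    threshold = NULL, W = 0.04, coverage = 0.95,
                    max_signals = 5, covariates = NULL) {
  kind <- match.arg(kind)
  if (is.null(threshold))
    threshold <- if (kind == "cis") 5e-8 else 1e-11
  if (length(variant_ids) == 0) return(list())
  impute <- function(x) {
    nas <- is.na(x)
    if (any(nas)) x[nas] <- mean(x, na.rm = TRUE)
    x
  }
  # forward pass: pick one lead per conditional round
  leads <- character(0)
  y <- pheno
  for (round in seq_len(max_signals)) {
    stats_tab <- association_scan(y, g, variant_ids, covariates = covariates)
    usable <- stats_tab$flag == "ok" & !is.na(stats_tab$p)
    if (!any(usable)) break
    top <- which(usable)[which.min(stats_tab$p[usable])]
    if (stats_tab$p[top] >= threshold) break
    leads <- c(leads, stats_tab$variant_id[top])
    y <- residualize(y, cbind(1, impute(g$dosages[, stats_tab$variant_id[top]])))
  }
  # refinement pass: per-signal statistics conditional on the other leads
  sets <- vector("list", length(leads))
  for (round in seq_along(leads)) {
    others <- leads[-round]
    cov_r <- covariates
    if (length(others))
      cov_r <- cbind(cov_r,
                     apply(g$dosages[, others, drop = FALSE], 2, impute))
    stats_tab <- association_scan(pheno, g, variant_ids, covariates = cov_r)
    usable <- stats_tab$flag == "ok" & !is.na(stats_tab$p)
    if (!any(usable)) next
    top <- which(usable)[which.min(stats_tab$p[usable])]
    labf <- rep(-Inf, nrow(stats_tab))
    labf[usable] <- wakefield_abf(stats_tab$beta[usable], stats_tab$se[usable],
                                  W = W, log = TRUE)
    labf <- labf - max(labf)
    pip <- exp(labf) / sum(exp(labf))
    ord <- order(-pip, stats_tab$variant_id)
    csum <- cumsum(pip[ord])
    k <- which(csum >= coverage)[1]
    members <- stats_tab$variant_id[ord[seq_len(k)]]
    mpip <- pip[ord[seq_len(k)]]
    lead <- list(variant_id = stats_tab$variant_id[top],
                 beta = stats_tab$beta[top], se = stats_tab$se[top],
                 p = stats_tab$p[top])
    mrows <- stats_tab[match(members, stats_tab$variant_id),
                       c("variant_id", "beta", "se", "p")]
    rownames(mrows) <- NULL
    sets[[round]] <- new_credible_set(
      probe_id = probe_id, platform = platform, signal_index = round,
      members = members, pip = mpip, lead = lead, kind = kind,
      significant = min(mrows$p, na.rm = TRUE) < threshold,
      member_stats = mrows)
  }
  Filter(Negate(is.null), sets)
}

#' Deduplicate credible sets linked by LD
#'
#' The stepwise fine-mapper (like any fine-mapper) can emit multiple
#' sets for one probe that tag the same underlying signal. For any
#' pair of sets whose members include a cross-pair combination with
#' r-squared > `ld_threshold`, the set with the less significant lead
#' is dropped. Comparison order is deterministic: sets are visited by
#' ascending lead p and kept greedily.
#'
#' @param sets List of `credible_set` objects for one probe.
#' @param g A [genotype_data()] providing member dosages.
#' @param ld_threshold LD r-squared above which sets are linked
#'   (default 0.1).
#' @return Filtered list of credible sets.
#' @export
dedup_credible_sets <- function(sets, g, ld_threshold = 0.1) {
  if (length(sets) <= 1) return(sets)
  leadp <- vapply(sets, function(s) s$lead$p, numeric(1))
  ord <- order(leadp)
  kept <- list()
  linked <- function(a, b) {
    for (vi in a$members) for (vj in b$members) {
      if (vi == vj) return(TRUE)
      r2 <- tryCatch(ld_r2(g$dosages[, vi], g$dosages[, vj]),
                     error = function(e) 0)
      if (r2 > ld_threshold) return(TRUE)
    }
    FALSE
  }
  for (i in ord) {
    s <- sets[[i]]
    if (!any(vapply(kept, function(k) linked(s, k), logical(1))))
      kept[[length(kept) + 1]] <- s
  }
  kept
}

#' Map cis and trans pQTL credible sets for every probe of a platform
#'
#' Runs the association scan and stepwise fine-mapper per probe over
#' its cis window and the trans universe, then deduplicates LD-linked
#' sets per probe.
#'
#' @param pm Residualized [protein_matrix()].
#' @param g A [genotype_data()] aligned with `pm`.
#' @param probes [probe_map()] rows for this platform (chrom/tss define
#'   the cis windows).
#' @param cis_threshold,trans_threshold Significance thresholds
#'   (defaults 5e-8 and 1e-11).
#' @param scan_trans Whether to map trans signals (default TRUE).
#' @param ... Passed to [finemap()] (`W`, `coverage`, `max_signals`,
#'   `covariates`).
#' @return List of `credible_set` objects across probes.
#' @export
map_pqtl <- function(pm, g, probes, cis_threshold = 5e-8,
                     trans_threshold = 1e-11, scan_trans = TRUE, ...) {
  stopifnot(inherits(pm, "protein_matrix"))
  sets <- list()
  pr <- probes[probes$platform == pm$platform &
                 probes$probe_id %in% colnames(pm$values), ]
  for (i in seq_len(nrow(pr))) {
    pid <- pr$probe_id[i]
    y <- pm$values[, pid]
    win <- cis_window(g$variants, pr$chrom[i], pr$tss[i])
    probe_sets <- list()
    if (length(win$cis))
      probe_sets <- c(probe_sets,
                      finemap(y, g, win$cis, kind = "cis", probe_id = pid,
                              platform = pm$platform,
                              threshold = cis_threshold, ...))
    if (scan_trans && length(win$trans))
      probe_sets <- c(probe_sets,
                      finemap(y, g, win$trans, kind = "trans", probe_id = pid,
                              platform = pm$platform,
                              threshold = trans_threshold, ...))
    sets <- c(sets, dedup_credible_sets(probe_sets, g))
  }
  sets
}

#' Flatten credible sets to a result table
#'
#' @param sets List of `credible_set` objects.
#' @return `data.frame` with one row per set; members and pips
#'   semicolon-packed.
#' @export
credible_sets_table <- function(sets) {
  if (length(sets) == 0)
    return(data.frame(probe_id = character(), platform = character(),
                      signal_index = integer(), kind = character(),
                      lead_variant = character(), lead_beta = numeric(),
                      lead_se = numeric(), lead_p = numeric(),
                      n_members = integer(), members = character(),
                      pips = character(), significant = logical()))
  do.call(rbind, lapply(sets, function(s) data.frame(
    probe_id = s$probe_id, platform = s$platform,
    signal_index = s$signal_index, kind = s$kind,
    lead_variant = s$lead$variant_id, lead_beta = s$lead$beta,
    lead_se = s$lead$se, lead_p = s$lead$p,
    n_members = length(s$members),
    members = paste(s$members, collapse = ";"),
    pips = paste(signif(s$pip, 4), collapse = ";"),
    significant = s$significant, stringsAsFactors = FALSE)))
}
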