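#' Adjust protein measures for a protein-altering variant
#'
#' Regresses the measure on intercept + effect-allele dosage (additive
#' 0/1/2 coding) and returns the residuals, which are uncorrelated
#' with the dosage. When a probe's apparent signal contains an epitope
#' artifact — the PAV changes probe binding rather than abundance —
#' this removes the artifactual component and typically restores
#' cross-platform concordance. A monomorphic dosage leaves the
#' measures unchanged with a warning.
#'
#' @param measures Numeric vector (transformed protein measures).
#' @param dosage PAV dosage vector aligned with `measures`.
#' @return Residual vector, same length and NA pattern as `measures`.
#' @export
pav_adjust <- function(measures, dosage) {
  if (length(measures) != length(dosage)) stop("inputs must align")
  ok <- !is.na(measures) & !is.na(dosage)
  if (stats::sd(dosage[ok]) == 0) {
    warning("monomorphic dosage: returning measures unchanged")
    return(measures)
  }
  out <- rep(NA_real_, length(measures))
  out[ok] <- residualize(measures[ok], cbind(1, dosage[ok]))
  out
}

#' Effect-size heterogeneity between two platform estimates
#'
#' `Q = (beta_A - beta_B)^2 / (se_A^2 + se_B^2)`, referred to
#' chi-square with 1 df. Used to compare protein-phenotype effect
#' sizes (and pQTL effects) across platforms.
#'
#' @param beta_A,se_A,beta_B,se_B Estimates and standard errors.
#' @return List with `Q` and `p`.
#' @export
effect_heterogeneity <- function(beta_A, se_A, beta_B, se_B) {
  if (any(c(se_A, se_B) <= 0)) stop("standard errors must be > 0")
  Q <- (beta_A - beta_B)^2 / (se_A^2 + se_B^2)
  list(Q = Q, p = stats::pchisq(Q, 1, lower.tail = FALSE))
}

#' Compare pre- and post-adjustment credible sets
#'
#' Matches each post-adjustment set to pre-adjustment sets that share
#' a member variant or contain cross-set members in LD
#' (r-squared > `ld_threshold`). Matched sets are labeled
#' `strengthened` when the post lead p is smaller than the matched pre
#' lead p, else `attenuated`. Post sets with no member overlap and no
#' cross-set LD to any pre set are `newly_associated`; pre sets with
#' no surviving post match are `lost`.
#'
#' @param pre_sets,post_sets Credible-set lists for the same probe,
#'   mapped before and after PAV adjustment.
#' @param g A [genotype_data()] for LD lookups.
#' @param ld_threshold LD rule threshold (default 0.1).
#' @return `data.frame` with one row per post set (label in
#'   `{strengthened, attenuated, newly_associated}`) plus one per
#'   unmatched pre set (`lost`).
#' @export
compare_signals_post_adjustment <- function(pre_sets, post_sets, g,
                                            ld_threshold = 0.1) {
  cross_linked <- function(a, b) {
    if (length(intersect(a$members, b$members))) return(TRUE)
    for (vi in a$members) for (vj in b$members) {
      r2 <- tryCatch(ld_r2(g$dosages[, vi], g$dosages[, vj]),
                     error = function(e) 0)
      if (r2 > ld_threshold) return(TRUE)
    }
    FALSE
  }
  pre_matched <- rep(FALSE, length(pre_sets))
  rows <- list()
  for (s in post_sets) {
    hits <- which(vapply(pre_sets, function(p) cross_linked(s, p), logical(1)))
    if (length(hits) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = s$probe_id, platform = s$platform, phase = "post",
        signal_index = s$signal_index, lead_variant = s$lead$variant_id,
        lead_p = s$lead$p, matched_pre_signal = NA_integer_,
        label = "newly_associated", stringsAsFactors = FALSE)
      next
    }
    pre_matched[hits] <- TRUE
    prep <- vapply(pre_sets[hits], function(p) p$lead$p, numeric(1))
    best <- hits[which.min(prep)]
    rows[[length(rows) + 1]] <- data.frame(
      probe_id = s$probe_id, platform = s$platform, phase = "post",
      signal_index = s$signal_index, lead_variant = s$lead$variant_id,
      lead_p = s$lead$p, matched_pre_signal = pre_sets[[best]]$signal_index,
      label = if (s$lead$p < min(prep)) "strengthened" else "attenuated",
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(pre_sets)) {
    if (!pre_matched[i]) {
      p <- pre_sets[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = p$probe_id, platform = p$platform, phase = "pre",
        signal_index = p$signal_index, lead_variant = p$lead$variant_id,
        lead_p = p$lead$p, matched_pre_signal = p$signal_index,
        label = "lost", stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), platform = character(),
               phase = character(), signal_index = integer(),
               lead_variant = character(), lead_p = numeric(),
               matched_pre_signal = integer(), label = character())
}

#' Quantify the effect of PAV adjustment on one protein
#'
#' Adjusts both platforms' measures for a PAV dosage, recomputes the
#' overall and per-ancestry cross-platform correlations and the
#' Cochran's-Q heterogeneity, and reports pre/post values side by
#' side.
#'
#' @param x_a,x_b Transformed measure vectors (platforms A and B).
#' @param dosage PAV dosage vector.
#' @param st A [sample_table()] aligned with the vectors.
#' @param min_group_n Minimum complete pairs per group for
#'   stratification (default 4).
#' @return List with `r_pre`, `r_post`, `delta`, per-group
#'   `by_group` table, `Q_pre`, `Q_post`, and the adjusted vectors.
#' @export
adjustment_report <- function(x_a, x_b, dosage, st, min_group_n = 4) {
  a_post <- pav_adjust(x_a, dosage)
  b_post <- pav_adjust(x_b, dosage)
  r_pre <- pairwise_correlation(x_a, x_b)
  r_post <- pairwise_correlation(a_post, b_post)
  groups <- ancestry_groups(st)
  bg <- data.frame(group = groups, r_pre = NA_real_, r_post = NA_real_,
                   n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    sel <- st$ancestry == groups[i]
    pre <- tryCatch(pairwise_correlation(x_a[sel], x_b[sel]),
                    error = function(e) NULL)
    post <- tryCatch(pairwise_correlation(a_post[sel], b_post[sel]),
                     error = function(e) NULL)
    if (!is.null(pre)) { bg$r_pre[i] <- pre$r; bg$n[i] <- pre$n }
    if (!is.null(post)) bg$r_post[i] <- post$r
  }
  het <- function(r, n) tryCatch(
    suppressWarnings(correlation_heterogeneity(r[n >= min_group_n],
                                               n[n >= min_group_n])),
    error = function(e) list(Q = NA_real_, df = NA_integer_, p = NA_real_))
  q_pre <- het(bg$r_pre, bg$n)
  q_post <- het(bg$r_post, bg$n)
  list(r_pre = r_pre$r, r_post = r_post$r, delta = r_post$r - r_pre$r,
       n = r_pre$n, by_group = bg,
       Q_pre = q_pre$Q, p_het_pre = q_pre$p,
       Q_post = q_post$Q, p_het_post = q_post$p,
       adjusted_A = a_post, adjusted_B = b_post)
}
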