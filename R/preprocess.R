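#' Rank-based inverse normal transformation
#'
#' Maps a measure to normal scores: non-missing values are replaced by
#' `qnorm((rank - c) / (m - 2c + 1))` where `m` is the number of
#' non-missing values and `c` is the rank offset (default 0.5, the
#' common QTL convention). Ties receive average ranks; missing values
#' stay missing. The transform is monotone in the input and invariant
#' to any increasing affine rescaling.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param offset Rank offset `c` in `(0, 1]`; default 0.5.
#' @return Numeric vector of normal scores, same length and NA pattern.
#' @export
rank_int <- function(values, offset = 0.5) {
  ok <- !is.na(values)
  m <- sum(ok)
  if (m == 0) stop("all values missing")
  if (m < 3) stop("need >= 3 non-missing values")
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (m - 2 * offset + 1))
  out
}

#' Build a covariate design matrix
#'
#' Assembles the residualization design: an intercept, continuous
#' covariates as given, and categorical covariates one-hot encoded
#' dropping the first level. Errors if the result is rank deficient,
#' naming the collinear columns.
#'
#' @param st A [sample_table()].
#' @param continuous Character vector of continuous covariate columns.
#' @param categorical Character vector of categorical covariate columns.
#' @param extra Optional numeric matrix of additional columns (e.g.
#'   genotype or protein principal components), rows aligned with `st`.
#' @return Numeric design matrix with an `(Intercept)` column.
#' @export
covariate_matrix <- function(st, continuous = c("age"),
                             categorical = c("sex", "site", "plate"),
                             extra = NULL) {
  parts <- list(`(Intercept)` = rep(1, nrow(st)))
  for (v in continuous) parts[[v]] <- as.numeric(st[[v]])
  for (v in categorical) {
    f <- factor(st[[v]])
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1])
      for (j in seq_len(ncol(mm))) parts[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  x <- do.call(cbind, parts)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (nrow(extra) != nrow(st)) stop("extra rows must match sample table")
    x <- cbind(x, extra)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("covariate matrix rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  x
}

#' Residualize columns on a covariate matrix
#'
#' Replaces each column of `y` by its ordinary-least-squares residual
#' on `x`. Residuals are orthogonal to every covariate column, and the
#' operation is idempotent: residualizing residuals returns them
#' unchanged. Missing values in a column are ignored for that column's
#' fit and stay missing.
#'
#' @param y Numeric matrix (samples x features) or vector.
#' @param x Numeric full-rank design matrix, rows aligned with `y`.
#' @return Matrix (or vector) of residuals, same shape as `y`.
#' @export
residualize <- function(y, x) {
  vec <- is.null(dim(y))
  y <- as.matrix(y)
  x <- as.matrix(x)
  if (nrow(y) != nrow(x)) stop("y and x rows must align")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  out <- y
  complete <- !is.na(y)
  if (all(complete)) {
    out[] <- qr.resid(qrx, y)
  } else {
    for (j in seq_len(ncol(y))) {
      ok <- complete[, j]
      out[ok, j] <- qr.resid(qr(x[ok, , drop = FALSE]), y[ok, j])
    }
  }
  if (vec) drop(out) else out
}

#' Principal components of a feature matrix
#'
#' Columns are mean-centered (and mean-imputed when missing) before the
#' decomposition. Returns sample scores, the fraction of variance
#' explained by each component, and the smallest number of components
#' whose cumulative fraction reaches a target.
#'
#' @param m Numeric matrix, samples x features.
#' @param n_components Number of component scores to return (default
#'   all).
#' @param variance_target Cumulative variance fraction used to compute
#'   `n_for_target` (default 0.95).
#' @return List with `scores` (samples x components), `var_explained`
#'   (fractions summing to 1 over all components), `n_for_target`, and
#'   `imputed` (count of imputed cells).
#' @export
principal_components <- function(m, n_components = NULL,
                                 variance_target = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 samples")
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) ncol(pc$x) else min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = ve,
       n_for_target = which(cumsum(ve) >= variance_target)[1],
       imputed = n_imputed)
}

#' Transform and residualize a protein matrix for QTL analysis
#'
#' Applies [rank_int()] per probe, then residualizes on the covariate
#' design (age, sex, site, plate, supplied genotype PCs, and protein
#' PCs computed from the transformed layer of this platform).
#'
#' @param pm A [protein_matrix()] with `layer = "raw"`.
#' @param st A [sample_table()] aligned with `pm`.
#' @param genotype_pcs Optional numeric matrix of genotype PCs.
#' @param n_protein_pcs Number of protein PCs to include (default 10;
#'   capped at the available component count).
#' @param int_offset Rank offset for [rank_int()].
#' @return List with `transformed` and `residualized` [protein_matrix()]
#'   objects and the covariate design used.
#' @export
prepare_protein_matrix <- function(pm, st, genotype_pcs = NULL,
                                   n_protein_pcs = 10, int_offset = 0.5) {
  check_sample_alignment(pm, st)
  tr <- apply(pm$values, 2, rank_int, offset = int_offset)
  rownames(tr) <- rownames(pm$values)
  transformed <- protein_matrix(tr, pm$platform, "transformed")
  extra <- NULL
  if (n_protein_pcs > 0 && ncol(tr) > 1) {
    k <- min(n_protein_pcs, ncol(tr) - 1, nrow(tr) - 1)
    ppc <- principal_components(tr, n_components = k)$scores
    colnames(ppc) <- paste0("proteinPC", seq_len(ncol(ppc)))
    extra <- ppc
  }
  if (!is.null(genotype_pcs)) {
    genotype_pcs <- as.matrix(genotype_pcs)
    colnames(genotype_pcs) <- paste0("genoPC", seq_len(ncol(genotype_pcs)))
    extra <- cbind(extra, genotype_pcs)
  }
  x <- covariate_matrix(st, extra = extra)
  res <- residualize(tr, x)
  list(transformed = transformed,
       residualized = protein_matrix(res, pm$platform, "residualized"),
       design = x)
}
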