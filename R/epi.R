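#' Protein-phenotype association model
#'
#' Associates a transformed protein measure with a phenotype. For
#' continuous phenotypes (age, BMI) the phenotype is the outcome of an
#' ordinary linear model with the protein as predictor plus
#' covariates; for binary phenotypes (sex, prevalent T2D) a logistic
#' model is fit by maximum likelihood. The reported coefficient is the
#' protein term. Complete separation in the logistic fit is flagged
#' and no estimate is returned.
#'
#' @param protein Transformed measure vector.
#' @param pheno Outcome vector (continuous, or binary 0/1 for
#'   logistic).
#' @param covariates Optional numeric design matrix of covariates
#'   (without intercept column).
#' @param family `"linear"` or `"logistic"`.
#' @return List with `beta`, `se`, `p`, `n`, `model`, `flag`
#'   (`"ok"`, `"separation"`, `"degenerate"`).
#' @export
phenotype_association <- function(protein, pheno, covariates = NULL,
                                  family = c("linear", "logistic")) {
  family <- match.arg(family)
  df <- data.frame(.y = pheno, .protein = protein)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    df <- cbind(df, as.data.frame(covariates))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  out <- list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
              model = family, flag = "ok")
  if (family == "linear") {
    fit <- stats::lm(.y ~ ., data = df)
    cf <- summary(fit)$coefficients
    if (!".protein" %in% rownames(cf) ||
        !is.finite(cf[".protein", "Std. Error"]) ||
        summary(fit)$sigma < .Machine$double.eps^0.5 * stats::sd(df$.y)) {
      out$flag <- "degenerate"
      if (".protein" %in% rownames(cf)) out$beta <- cf[".protein", "Estimate"]
      return(out)
    }
    out$beta <- cf[".protein", "Estimate"]
    out$se <- cf[".protein", "Std. Error"]
    out$p <- cf[".protein", "Pr(>|t|)"]
  } else {
    if (!all(df$.y %in% c(0, 1))) stop("logistic outcome must be 0/1")
    if (length(unique(df$.y)) < 2) stop("logistic outcome needs both classes")
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    if (sep || !fit$converged || cf[".protein", "Std. Error"] > 1e3) {
      out$flag <- "separation"
      return(out)
    }
    out$beta <- cf[".protein", "Estimate"]
    out$se <- cf[".protein", "Std. Error"]
    out$p <- cf[".protein", "Pr(>|z|)"]
  }
  out
}

#' Protein-phenotype association table for a platform
#'
#' Runs [phenotype_association()] for each probe against the standard
#' phenotype set: age and BMI as linear outcomes, sex and prevalent
#' T2D as logistic outcomes. Covariates follow the usual convention:
#' plate and site for age/sex models, additionally age and sex for
#' BMI/T2D models.
#'
#' @param pm Transformed [protein_matrix()].
#' @param st A [sample_table()] aligned with `pm`.
#' @param phenotypes Subset of `c("age", "sex", "bmi", "t2d")`.
#' @return `data.frame` with one row per probe x phenotype.
#' @export
phenotype_association_table <- function(pm, st,
                                        phenotypes = c("age", "sex", "bmi",
                                                       "t2d")) {
  check_sample_alignment(pm, st)
  fam <- c(age = "linear", bmi = "linear", sex = "logistic",
           t2d = "logistic")
  base_cov <- function(vars) {
    keep <- list()
    for (v in vars) {
      f <- factor(st[[v]])
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(v, seq_len(ncol(mm)))
        keep[[v]] <- mm
      } else if (is.numeric(st[[v]]) && stats::sd(st[[v]]) > 0) {
        keep[[v]] <- matrix(st[[v]], dimnames = list(NULL, v))
      }
    }
    if (length(keep)) do.call(cbind, keep) else NULL
  }
  rows <- list()
  for (ph in phenotypes) {
    covs <- if (ph %in% c("age", "sex")) base_cov(c("plate", "site"))
            else cbind(base_cov(c("plate", "site")),
                       age = st$age, sex = st$sex)
    for (pid in colnames(pm$values)) {
      fit <- phenotype_association(pm$values[, pid], st[[ph]], covs,
                                   family = fam[[ph]])
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = pid, platform = pm$platform, phenotype = ph,
        model = fit$model, beta = fit$beta, se = fit$se, p = fit$p,
        n = fit$n, flag = fit$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Limit of detection from negative controls
#'
#' `LOD = median(controls) + 3 * sample SD(controls)`, computed on the
#' raw measurement scale.
#'
#' @param control_values Numeric vector of negative-control measures
#'   for one probe (>= 2 values).
#' @return Numeric LOD.
#' @export
olink_lod <- function(control_values) {
  v <- control_values[!is.na(control_values)]
  if (length(v) < 2) stop("need >= 2 control values")
  stats::median(v) + 3 * stats::sd(v)
}

#' Fraction of measures above the limit of detection
#'
#' Strict inequality: a measure equal to the LOD does not count as
#' above it.
#'
#' @param measures Raw measure vector.
#' @param lod Limit of detection on the same scale.
#' @return Fraction in `[0, 1]` of non-missing measures above `lod`.
#' @export
frac_above_lod <- function(measures, lod) {
  ok <- !is.na(measures)
  if (!any(ok)) stop("all measures missing")
  sum(measures[ok] > lod) / sum(ok)
}

#' Limit-of-detection table for a platform
#'
#' Computes the per-probe LOD from negative controls and the fraction
#' of cohort measures above it. Refuses transformed input: the LOD is
#' defined on the raw measurement scale.
#'
#' @param pm A [protein_matrix()] with `layer = "raw"`.
#' @param controls A [negative_control_table()].
#' @return `data.frame` with `probe_id`, `platform`, `lod`,
#'   `frac_above`.
#' @export
lod_table <- function(pm, controls) {
  if (pm$layer != "raw")
    stop("LOD must be computed on the raw layer, got '", pm$layer, "'")
  probes <- intersect(colnames(pm$values), names(controls$controls))
  out <- data.frame(probe_id = probes, platform = pm$platform,
                    lod = NA_real_, frac_above = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(probes)) {
    lod <- olink_lod(controls$controls[[probes[i]]])
    out$lod[i] <- lod
    out$frac_above[i] <- frac_above_lod(pm$values[, probes[i]], lod)
  }
  out
}
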