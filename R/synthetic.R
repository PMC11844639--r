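#' Draw subpopulation allele frequencies (Balding-Nichols model)
#'
#' Each ancestry group's frequency is drawn from
#' `Beta(p0 (1 - fst) / fst, (1 - p0)(1 - fst) / fst)`, which has mean
#' `p0` and variance `fst * p0 * (1 - p0)`. With `fst = 0` all groups
#' get exactly `p0`. Draws are clamped away from 0 and 1 so simulated
#' loci stay polymorphic.
#'
#' @param p0 Ancestral frequency in (0, 1).
#' @param fst Differentiation parameter in `[0, 1)`.
#' @param K Number of groups.
#' @return Numeric vector of K frequencies.
#' @export
draw_subpop_freqs <- function(p0, fst, K) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (fst == 0) return(rep(p0, K))
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(K, a, b), 1e-4), 1 - 1e-4)
}

#' Describe one simulated protein
#'
#' A protein block specifies the genetic and noise architecture of one
#' protein target measured on both platforms: a cis-regulatory variant
#' acting on true abundance, an optional protein-altering variant
#' (PAV) with platform-specific epitope effects `delta_A` / `delta_B`
#' (possibly of opposite sign), neutral cis variants, and per-platform
#' measurement noise.
#'
#' @param uniprot,gene,chrom,tss Identity and location of the target.
#' @param beta_cis Effect of the cis-regulatory variant on the shared
#'   abundance (SD units per allele).
#' @param cis_freq,cis_fst Ancestral frequency and differentiation of
#'   the cis-regulatory variant.
#' @param pav Whether a PAV is planted.
#' @param delta_A,delta_B Platform-specific PAV effects on the
#'   measured (not true) abundance.
#' @param pav_freqs Optional fixed per-group PAV frequencies (named or
#'   in group order); when `NULL`, drawn by [draw_subpop_freqs()] from
#'   `pav_freq` and `pav_fst`.
#' @param pav_freq,pav_fst Balding-Nichols parameters for the PAV when
#'   `pav_freqs` is not fixed.
#' @param sigma_shared2 Residual variance of the shared abundance.
#' @param sigma_eA2,sigma_eB2 Platform noise variances.
#' @param n_cis_neutral Number of neutral variants in the cis window.
#' @param neutral_freq Ancestral frequency of neutral cis variants.
#' @return A list of class `protein_block`.
#' @export
protein_block <- function(uniprot = "P00001", gene = "GENE1", chrom = "7",
                          tss = 100e6, beta_cis = 0.5, cis_freq = 0.3,
                          cis_fst = 0, pav = FALSE, delta_A = 0,
                          delta_B = 0, pav_freqs = NULL, pav_freq = 0.3,
                          pav_fst = 0.12, sigma_shared2 = 1,
                          sigma_eA2 = 1, sigma_eB2 = 1, n_cis_neutral = 10,
                          neutral_freq = 0.3) {
  structure(list(uniprot = uniprot, gene = gene, chrom = as.character(chrom),
                 tss = tss, beta_cis = beta_cis, cis_freq = cis_freq,
                 cis_fst = cis_fst, pav = pav, delta_A = delta_A,
                 delta_B = delta_B, pav_freqs = pav_freqs,
                 pav_freq = pav_freq, pav_fst = pav_fst,
                 sigma_shared2 = sigma_shared2, sigma_eA2 = sigma_eA2,
                 sigma_eB2 = sigma_eB2, n_cis_neutral = n_cis_neutral,
                 neutral_freq = neutral_freq),
            class = "protein_block")
}

#' Simulation configuration
#'
#' Defines a synthetic cohort: K ancestry groups with
#' Balding-Nichols-differentiated allele frequencies, protein blocks
#' (see [protein_block()]), an optional pleiotropic trans hub variant
#' affecting several proteins on both platforms, covariate and
#' phenotype structure, background variants for the
#' ancestry-differentiation quantile, and negative-control
#' measurements.
#'
#' @param groups Named integer vector of per-group sample sizes.
#' @param fst Default differentiation parameter.
#' @param n_unassigned Samples with ancestry label `"unassigned"`
#'   (genotyped at the mean of the group frequencies).
#' @param n_null_variants Background variants (no phenotypic effect)
#'   used to populate the differentiation quantile.
#' @param null_fst Differentiation of background variants.
#' @param proteins List of [protein_block()]s.
#' @param trans_hub Optional list
#'   `(chrom, pos, freq, fst, beta, targets)`: a single variant with
#'   effect `beta` on the shared abundance of every protein whose
#'   uniprot id is in `targets`.
#' @param age_mean,age_sd Age distribution (years).
#' @param age_beta,sex_beta Covariate effects on shared abundance.
#' @param n_sites,n_plates Numbers of recruitment sites and plates.
#' @param bmi_link,t2d_link Effect of the first protein's shared
#'   abundance on BMI (linear) and T2D liability (logistic).
#' @param lod_mu,lod_sd,n_controls Negative-control distribution and
#'   count per platform-B probe.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(groups = c(AFR = 500, AMR = 500, EAS = 500, EUR = 500),
                       fst = 0.12, n_unassigned = 0, n_null_variants = 40,
                       null_fst = fst, proteins = list(protein_block()),
                       trans_hub = NULL, age_mean = 60, age_sd = 10,
                       age_beta = 0.005, sex_beta = 0.1, n_sites = 4,
                       n_plates = 8, bmi_link = 0.3, t2d_link = 0.3,
                       lod_mu = 1, lod_sd = 0.3, n_controls = 20) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of sizes")
  if (any(groups < 2)) stop("group sizes must be >= 2")
  for (b in proteins)
    if (any(c(b$sigma_shared2, b$sigma_eA2, b$sigma_eB2) <= 0))
      stop("all variances must be > 0")
  structure(list(groups = groups, fst = fst, n_unassigned = n_unassigned,
                 n_null_variants = n_null_variants, null_fst = null_fst,
                 proteins = proteins, trans_hub = trans_hub,
                 age_mean = age_mean, age_sd = age_sd, age_beta = age_beta,
                 sex_beta = sex_beta, n_sites = n_sites, n_plates = n_plates,
                 bmi_link = bmi_link, t2d_link = t2d_link, lod_mu = lod_mu,
                 lod_sd = lod_sd, n_controls = n_controls),
            class = "sim_config")
}

pooled_dosage_variance <- function(freqs, sizes) {
  w <- sizes / sum(sizes)
  qbar <- sum(w * freqs)
  2 * qbar * (1 - qbar) + 2 * sum(w * (freqs - qbar)^2)
}

#' Closed-form expected cross-platform correlation
#'
#' For a protein block with shared-abundance variance `sigma_U^2`
#' (cis, trans-hub and covariate contributions plus the residual
#' shared variance), PAV effects `delta_A`, `delta_B`, PAV dosage
#' variance `v_G`, and platform noise variances, the expected Pearson
#' correlation of the two platform measures is
#'
#' unadjusted:
#' `(sigma_U^2 + delta_A delta_B v_G) /
#'  sqrt((sigma_U^2 + delta_A^2 v_G + sigma_eA^2)
#'       (sigma_U^2 + delta_B^2 v_G + sigma_eB^2))`
#'
#' and after PAV adjustment:
#' `sigma_U^2 / sqrt((sigma_U^2 + sigma_eA^2)(sigma_U^2 + sigma_eB^2))`.
#'
#' The PAV dosage variance under group structure is
#' `2 qbar (1 - qbar) + 2 Var_w(q)` over the per-group frequencies; a
#' block with frequencies drawn at simulation time should pass the
#' realized frequencies from the cohort truth table.
#'
#' @param cfg A [sim_config()].
#' @param protein Index of the protein block (default 1).
#' @param adjusted Expected correlation after PAV adjustment?
#' @param pav_freqs,cis_freqs Realized per-group frequencies; default
#'   to the block's fixed values (`pav_freqs` field, or constant
#'   `cis_freq`/`pav_freq` when the block's fst is 0; a non-zero fst
#'   without realized frequencies uses the Balding-Nichols expectation
#'   `2 p0 (1 - p0)(1 + fst)`).
#' @return Expected Pearson correlation.
#' @export
expected_cross_platform_r <- function(cfg, protein = 1, adjusted = FALSE,
                                      pav_freqs = NULL, cis_freqs = NULL) {
  b <- cfg$proteins[[protein]]
  sizes <- cfg$groups
  K <- length(sizes)
  vg_of <- function(freqs, p0, fst) {
    if (!is.null(freqs)) return(pooled_dosage_variance(freqs, sizes))
    if (fst == 0) return(2 * p0 * (1 - p0))
    2 * p0 * (1 - p0) * (1 + fst)
  }
  v_cis <- vg_of(cis_freqs, b$cis_freq, b$cis_fst)
  sigma_U2 <- b$beta_cis^2 * v_cis + cfg$age_beta^2 * cfg$age_sd^2 +
    cfg$sex_beta^2 * 0.25 + b$sigma_shared2
  if (!is.null(cfg$trans_hub) && b$uniprot %in% cfg$trans_hub$targets) {
    hub <- cfg$trans_hub
    hfst <- if (is.null(hub$fst)) 0 else hub$fst
    sigma_U2 <- sigma_U2 + hub$beta^2 * vg_of(NULL, hub$freq, hfst)
  }
  if (adjusted || !b$pav)
    return(sigma_U2 / sqrt((sigma_U2 + b$sigma_eA2) *
                             (sigma_U2 + b$sigma_eB2)))
  v_g <- vg_of(if (!is.null(pav_freqs)) pav_freqs else b$pav_freqs,
               b$pav_freq, b$pav_fst)
  (sigma_U2 + b$delta_A * b$delta_B * v_g) /
    sqrt((sigma_U2 + b$delta_A^2 * v_g + b$sigma_eA2) *
           (sigma_U2 + b$delta_B^2 * v_g + b$sigma_eB2))
}

#' Simulate a two-platform proteogenomic cohort
#'
#' Generates genotypes under Hardy-Weinberg equilibrium within each
#' ancestry group (`Binomial(2, q_k)` with group frequencies from the
#' Balding-Nichols model or fixed per block), shared protein
#' abundances `U = beta_cis G_cis (+ hub) + covariates + noise`,
#' platform measures `M_A = U + delta_A G_PAV + e_A` and
#' `M_B = U + delta_B G_PAV + e_B`, phenotypes linked to the first
#' protein's shared abundance, and negative-control measures. The same
#' seed reproduces the cohort exactly.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `sim_cohort` with elements `genotypes`
#'   ([genotype_data()]), `raw_A`, `raw_B` ([protein_matrix()], raw
#'   layer), `samples` ([sample_table()]), `probes` ([probe_map()]),
#'   `controls` ([negative_control_table()]), and `truth` (realized
#'   per-variant group frequencies, per-protein planted parameters,
#'   and the config).
#' @export
simulate_cohort <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  sizes <- cfg$groups
  K <- length(sizes)
  glabels <- names(sizes)
  n_assigned <- sum(sizes)
  n <- n_assigned + cfg$n_unassigned
  ancestry <- c(rep(glabels, times = sizes), rep("unassigned", cfg$n_unassigned))
  sample_id <- sprintf("S%05d", seq_len(n))

  variants <- list()
  freqs <- list()   # variant_id -> K-vector of group freqs
  add_variant <- function(id, chrom, pos, class = "none", gene = NA_character_,
                          fq) {
    variants[[length(variants) + 1]] <<- data.frame(
      variant_id = id, chrom = chrom, pos = pos, ref = "A", alt = "G",
      consequence_class = class, consequence_gene = gene,
      stringsAsFactors = FALSE)
    freqs[[id]] <<- fq
  }

  truth_rows <- list()
  for (i in seq_along(cfg$proteins)) {
    b <- cfg$proteins[[i]]
    cid <- sprintf("cis%d", i)
    cfq <- if (b$cis_fst == 0) rep(b$cis_freq, K)
           else draw_subpop_freqs(b$cis_freq, b$cis_fst, K)
    add_variant(cid, b$chrom, b$tss + 50000, fq = cfq)
    pid <- NA_character_
    if (b$pav) {
      pid <- sprintf("pav%d", i)
      pfq <- if (!is.null(b$pav_freqs)) {
        fq <- b$pav_freqs
        if (!is.null(names(fq))) fq <- fq[glabels]
        unname(fq)
      } else draw_subpop_freqs(b$pav_freq, b$pav_fst, K)
      add_variant(pid, b$chrom, b$tss + 10000, class = "missense",
                  gene = b$gene, fq = pfq)
    }
    if (b$n_cis_neutral > 0) {
      pos <- b$tss + round(seq(-9e5, 9e5, length.out = b$n_cis_neutral))
      pos <- pmax(pos, 1)
      for (k in seq_len(b$n_cis_neutral))
        add_variant(sprintf("neu%d_%d", i, k), b$chrom, pos[k],
                    fq = rep(b$neutral_freq, K))
    }
    truth_rows[[i]] <- data.frame(
      uniprot = b$uniprot, gene = b$gene, probe_A = sprintf("apt.%04d.1", i),
      probe_B = b$gene, cis_variant = cid, pav_variant = pid,
      beta_cis = b$beta_cis, delta_A = b$delta_A, delta_B = b$delta_B,
      sigma_shared2 = b$sigma_shared2, sigma_eA2 = b$sigma_eA2,
      sigma_eB2 = b$sigma_eB2, stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$trans_hub)) {
    hub <- cfg$trans_hub
    hfst <- if (is.null(hub$fst)) 0 else hub$fst
    hfq <- if (hfst == 0) rep(hub$freq, K)
           else draw_subpop_freqs(hub$freq, hfst, K)
    add_variant("hub1", as.character(hub$chrom), hub$pos, fq = hfq)
  }
  if (cfg$n_null_variants > 0) {
    p0 <- stats::runif(cfg$n_null_variants, 0.05, 0.95)
    for (k in seq_len(cfg$n_null_variants))
      add_variant(sprintf("null%d", k), "20", 1e6 * k,
                  fq = draw_subpop_freqs(p0[k], cfg$null_fst, K))
  }
  variants <- do.call(rbind, variants)

  grp_index <- match(ancestry, glabels)   # NA for unassigned
  dosages <- matrix(NA_real_, n, nrow(variants),
                    dimnames = list(sample_id, variants$variant_id))
  for (j in seq_len(nrow(variants))) {
    fq <- freqs[[variants$variant_id[j]]]
    q <- ifelse(is.na(grp_index), mean(fq), fq[grp_index])
    dosages[, j] <- stats::rbinom(n, 2, q)
  }
  g <- genotype_data(dosages, variants)

  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- stats::rbinom(n, 1, 0.5)
  site <- sample(paste0("site", seq_len(cfg$n_sites)), n, replace = TRUE)
  plate <- sample(paste0("plate", seq_len(cfg$n_plates)), n, replace = TRUE)

  np <- length(cfg$proteins)
  MA <- MB <- matrix(NA_real_, n, np)
  U1 <- NULL
  for (i in seq_len(np)) {
    b <- cfg$proteins[[i]]
    U <- b$beta_cis * dosages[, sprintf("cis%d", i)] +
      cfg$age_beta * (age - cfg$age_mean) +
      cfg$sex_beta * (sex - 0.5) +
      stats::rnorm(n, 0, sqrt(b$sigma_shared2))
    if (!is.null(cfg$trans_hub) && b$uniprot %in% cfg$trans_hub$targets)
      U <- U + cfg$trans_hub$beta * dosages[, "hub1"]
    gpav <- if (b$pav) dosages[, sprintf("pav%d", i)] else 0
    MA[, i] <- U + b$delta_A * gpav + stats::rnorm(n, 0, sqrt(b$sigma_eA2))
    MB[, i] <- U + b$delta_B * gpav + stats::rnorm(n, 0, sqrt(b$sigma_eB2))
    if (i == 1) U1 <- U
  }
  truth_tab <- do.call(rbind, truth_rows)
  colnames(MA) <- truth_tab$probe_A
  colnames(MB) <- truth_tab$probe_B
  rownames(MA) <- rownames(MB) <- sample_id

  bmi <- 28 + cfg$bmi_link * U1 + stats::rnorm(n, 0, 4)
  t2d <- stats::rbinom(n, 1, stats::plogis(-2 + cfg$t2d_link * U1))

  st <- sample_table(sample_id, age = age, sex = sex, site = site,
                     plate = plate, ancestry = ancestry, bmi = bmi, t2d = t2d,
                     groups = glabels)

  probes <- probe_map(
    probe_id = c(truth_tab$probe_A, truth_tab$probe_B),
    platform = rep(c("A", "B"), each = np),
    uniprot_id = rep(truth_tab$uniprot, 2),
    gene_symbol = rep(truth_tab$gene, 2),
    chrom = rep(vapply(cfg$proteins, `[[`, character(1), "chrom"), 2),
    tss = rep(vapply(cfg$proteins, `[[`, numeric(1), "tss"), 2))

  controls <- negative_control_table(stats::setNames(
    lapply(seq_len(np), function(i)
      stats::rnorm(cfg$n_controls, cfg$lod_mu, cfg$lod_sd)),
    truth_tab$probe_B))

  freq_tab <- do.call(rbind, lapply(names(freqs), function(v)
    data.frame(variant_id = v, group = glabels, freq = freqs[[v]],
               stringsAsFactors = FALSE)))

  structure(list(
    genotypes = g,
    raw_A = protein_matrix(MA + 7, "A", "raw"),
    raw_B = protein_matrix(MB + 3, "B", "raw"),
    samples = st, probes = probes, controls = controls,
    truth = list(config = cfg, proteins = truth_tab,
                 variant_freqs = freq_tab, seed = seed)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort: %d samples, %d variants, %d protein target(s)>\n",
              nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              nrow(x$truth$proteins)))
  invisible(x)
}

#' Scenario catalogue for pipeline testing
#'
#' Named study conditions exercising each qualitative regime of the
#' analysis:
#' * `"A"` — concordant cis-pQTL, no PAV;
#' * `"B"` — PAV affecting platform A only;
#' * `"C"` — shared pleiotropic trans hub (one variant driving six
#'   proteins on both platforms);
#' * `"D"` — the discordant archetype: a missense PAV with opposite
#'   platform effects (`delta_A = -1`, `delta_B = +0.5`) and a strongly
#'   African-enriched frequency contrast (common in one group, rare in
#'   the others, as for Duffy-null-like variants);
#' * `"E"` — null protein (noise only).
#'
#' @param scenario One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param n Total cohort size, split equally over 4 ancestry groups
#'   (default 2000).
#' @return A [sim_config()].
#' @export
scenario_config <- function(scenario = c("A", "B", "C", "D", "E"), n = 2000) {
  scenario <- match.arg(scenario)
  groups <- c(AFR = n %/% 4, AMR = n %/% 4, EAS = n %/% 4,
              EUR = n - 3 * (n %/% 4))
  base <- function(...) sim_config(groups = groups, ...)
  switch(scenario,
    A = base(proteins = list(protein_block(
      uniprot = "P10001", gene = "GENA", chrom = "7", tss = 100e6,
      beta_cis = 0.5))),
    B = base(proteins = list(protein_block(
      uniprot = "P10002", gene = "GENB", chrom = "7", tss = 100e6,
      beta_cis = 0.5, pav = TRUE, delta_A = -1, delta_B = 0,
      pav_freqs = rep(0.3, 4)))),
    C = base(proteins = lapply(1:6, function(i) protein_block(
      uniprot = sprintf("P2000%d", i), gene = sprintf("GENC%d", i),
      chrom = as.character(i), tss = 60e6 + 5e6 * i, beta_cis = 0.4,
      n_cis_neutral = 4)),
      trans_hub = list(chrom = "9", pos = 136131322, freq = 0.35,
                       beta = 0.6,
                       targets = sprintf("P2000%d", 1:6))),
    D = base(proteins = list(protein_block(
      uniprot = "P30001", gene = "GEND", chrom = "7", tss = 100e6,
      beta_cis = 0.5, pav = TRUE, delta_A = -1, delta_B = 0.5,
      pav_freqs = c(AFR = 0.45, AMR = 0.05, EAS = 0.02, EUR = 0.05)))),
    E = base(proteins = list(protein_block(
      uniprot = "P40001", gene = "GENE", chrom = "7", tss = 100e6,
      beta_cis = 0))))
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the genotypes as VCF, both platform matrices, the sample
#' table, probe map, negative controls and truth tables as TSV.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_matrix_tsv(cohort$raw_A, file.path(dir, "platform_A.tsv"))
  write_matrix_tsv(cohort$raw_B, file.path(dir, "platform_B.tsv"))
  write_result_table(as.data.frame(cohort$samples),
                     file.path(dir, "samples.tsv"))
  write_result_table(as.data.frame(cohort$probes),
                     file.path(dir, "probes.tsv"))
  ctrl <- do.call(rbind, lapply(names(cohort$controls$controls), function(p)
    data.frame(probe_id = p, value = cohort$controls$controls[[p]],
               stringsAsFactors = FALSE)))
  write_result_table(ctrl, file.path(dir, "negative_controls.tsv"))
  write_result_table(cohort$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  write_result_table(cohort$truth$variant_freqs,
                     file.path(dir, "truth_variant_freqs.tsv"))
  invisible(dir)
}
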