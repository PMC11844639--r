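#' Pipeline configuration
#'
#' Collects every threshold and toggle the pipeline uses; all of them
#' are logged at run time so an analysis is auditable.
#'
#' @param cis_threshold,trans_threshold pQTL significance thresholds
#'   (defaults 5e-8 and 1e-11).
#' @param ld_r2 LD threshold for credible-set deduplication and the
#'   newly-associated rule (default 0.1).
#' @param pleio_min_proteins,pleio_max_other Pleiotropy region rules
#'   (defaults 5 and 1).
#' @param diff_quantile Ancestry-differentiation quantile (default
#'   0.75).
#' @param alpha Family-wise error rate for Bonferroni thresholds
#'   (default 0.05).
#' @param half_window Half-width of trans-pleiotropy sentinel windows
#'   in bp (default 5e5: a 1 Mb window around the sentinel).
#' @param int_offset Rank-INT offset (default 0.5).
#' @param n_protein_pcs,n_genotype_pcs Principal components included
#'   in the residualization design. Defaults are 0: with the small
#'   probe panels this package targets, protein PCs would absorb the
#'   signal itself; on a panel of thousands of probes set
#'   `n_protein_pcs = 10` to match common pQTL practice.
#' @param W,max_signals Fine-mapper prior variance and round cap.
#' @param adjust_auto Auto-detect PAVs to adjust from discordant pairs
#'   (default TRUE).
#' @param pav_list Optional explicit list: uniprot id -> PAV variant
#'   id to adjust.
#' @param stages Stage toggles, subset of
#'   `c("preprocess", "concordance", "pqtl", "crossplat", "adjust",
#'   "epi")`.
#' @param scan_trans Whether pQTL mapping scans the trans universe
#'   (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cis_threshold = 5e-8, trans_threshold = 1e-11,
                            ld_r2 = 0.1, pleio_min_proteins = 5,
                            pleio_max_other = 1, diff_quantile = 0.75,
                            alpha = 0.05, half_window = 5e5,
                            int_offset = 0.5, n_protein_pcs = 0,
                            n_genotype_pcs = 0, W = 0.04, max_signals = 5,
                            adjust_auto = TRUE, pav_list = NULL,
                            stages = c("preprocess", "concordance", "pqtl",
                                       "crossplat", "adjust", "epi"),
                            scan_trans = TRUE) {
  stopifnot(cis_threshold > 0, cis_threshold < 1,
            trans_threshold > 0, trans_threshold < 1,
            ld_r2 >= 0, ld_r2 <= 1, alpha > 0, alpha < 1,
            diff_quantile > 0, diff_quantile < 1,
            pleio_min_proteins >= 1, half_window > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Load a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory with `genotypes.vcf`, `platform_A.tsv`,
#'   `platform_B.tsv`, `samples.tsv`, `probes.tsv`,
#'   `negative_controls.tsv`.
#' @return A list with the same elements as a `sim_cohort` (without
#'   the truth tables).
#' @export
load_cohort <- function(dir) {
  sm <- read_result_table(file.path(dir, "samples.tsv"))
  st <- sample_table(sm$sample_id, age = sm$age, sex = sm$sex,
                     site = sm$site, plate = sm$plate,
                     ancestry = sm$ancestry, bmi = sm$bmi, t2d = sm$t2d)
  g <- read_genotype_vcf(file.path(dir, "genotypes.vcf"),
                         samples = st$sample_id)
  pr <- read_result_table(file.path(dir, "probes.tsv"))
  probes <- probe_map(pr$probe_id, pr$platform, pr$uniprot_id,
                      pr$gene_symbol, pr$chrom, pr$tss)
  ctrl <- read_result_table(file.path(dir, "negative_controls.tsv"))
  list(genotypes = g,
       raw_A = read_matrix_tsv(file.path(dir, "platform_A.tsv"), "A"),
       raw_B = read_matrix_tsv(file.path(dir, "platform_B.tsv"), "B"),
       samples = st, probes = probes,
       controls = negative_control_table(split(ctrl$value, ctrl$probe_id)))
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  invisible(msg)
}

#' Run the full cross-platform concordance and pQTL pipeline
#'
#' Executes, in order: preprocessing (rank-INT and covariate
#' residualization per platform), cross-platform concordance with
#' ancestry heterogeneity, cis/trans pQTL mapping with credible sets
#' per platform, cross-platform signal classification with
#' ancestry-differentiation scoring and trans-pleiotropy regions, PAV
#' adjustment with pre/post quantification, and epidemiological
#' models with limit-of-detection summaries. Each stage writes a TSV
#' under `out_dir`, and `pipeline.log` records the thresholds used
#' and per-stage counts. The pipeline is deterministic: rerunning on
#' the same inputs reproduces identical outputs.
#'
#' @param cohort A `sim_cohort` (from [simulate_cohort()]) or the list
#'   returned by [load_cohort()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(logcon))
  log_line(logcon, "xpqtl version ", as.character(utils::packageVersion("xpqtl")))
  for (key in c("cis_threshold", "trans_threshold", "ld_r2",
                "pleio_min_proteins", "pleio_max_other", "diff_quantile",
                "alpha", "half_window", "int_offset", "n_protein_pcs",
                "n_genotype_pcs", "W", "max_signals"))
    log_line(logcon, "config ", key, " = ", format(config[[key]]))

  st <- cohort$samples
  g <- cohort$genotypes
  probes <- cohort$probes
  res <- list(config = config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # preprocessing always runs: every later stage consumes its layers
  {
    res$prep_A <- run_stage("preprocess", {
      gpc <- if (config$n_genotype_pcs > 0)
        principal_components(g$dosages,
                             n_components = config$n_genotype_pcs)$scores
      else NULL
      prepare_protein_matrix(cohort$raw_A, st, genotype_pcs = gpc,
                             n_protein_pcs = config$n_protein_pcs,
                             int_offset = config$int_offset)
    })
    res$prep_B <- run_stage("preprocess", {
      gpc <- if (config$n_genotype_pcs > 0)
        principal_components(g$dosages,
                             n_components = config$n_genotype_pcs)$scores
      else NULL
      prepare_protein_matrix(cohort$raw_B, st, genotype_pcs = gpc,
                             n_protein_pcs = config$n_protein_pcs,
                             int_offset = config$int_offset)
    })
    log_line(logcon, "preprocess: ", ncol(cohort$raw_A$values), " A probes, ",
             ncol(cohort$raw_B$values), " B probes transformed/residualized")
  }

  if ("concordance" %in% config$stages) {
    res$concordance <- run_stage("concordance",
      concordance_table(res$prep_A$transformed, res$prep_B$transformed,
                        probes, st))
    m <- nrow(res$concordance)
    res$bonferroni <- bonferroni_threshold(config$alpha, max(m, 1))
    write_result_table(res$concordance, file.path(out_dir, "concordance.tsv"))
    log_line(logcon, "concordance: ", m, " probe pairs; Bonferroni threshold ",
             format(res$bonferroni), " (alpha ", config$alpha, " / m ", m, ")")
  }

  if ("pqtl" %in% config$stages) {
    res$sets_A <- run_stage("pqtl",
      map_pqtl(res$prep_A$residualized, g, probes,
               cis_threshold = config$cis_threshold,
               trans_threshold = config$trans_threshold,
               scan_trans = config$scan_trans,
               W = config$W, max_signals = config$max_signals))
    res$sets_B <- run_stage("pqtl",
      map_pqtl(res$prep_B$residualized, g, probes,
               cis_threshold = config$cis_threshold,
               trans_threshold = config$trans_threshold,
               scan_trans = config$scan_trans,
               W = config$W, max_signals = config$max_signals))
    write_result_table(credible_sets_table(res$sets_A),
                       file.path(out_dir, "credible_sets_A.tsv"))
    write_result_table(credible_sets_table(res$sets_B),
                       file.path(out_dir, "credible_sets_B.tsv"))
    log_line(logcon, "pqtl: ", length(res$sets_A), " credible sets on A, ",
             length(res$sets_B), " on B (cis p < ",
             format(config$cis_threshold), ", trans p < ",
             format(config$trans_threshold), ")")
  }

  if ("crossplat" %in% config$stages && !is.null(res$sets_A)) {
    res$pairs <- run_stage("crossplat",
      classify_all_pairs(res$sets_A, res$sets_B, probes, g$variants))
    write_result_table(res$pairs, file.path(out_dir, "signal_pairs.tsv"))
    res$differentiation <- run_stage("crossplat",
      ancestry_differentiation(g, st, quantile = config$diff_quantile))
    write_result_table(res$differentiation,
                       file.path(out_dir, "ancestry_differentiation.tsv"))
    log_line(logcon, "crossplat: ", nrow(res$pairs), " signal pairs; ",
             "differentiation threshold (q", config$diff_quantile, ") = ",
             format(attr(res$differentiation, "threshold")))
    sent <- do.call(rbind, lapply(c(res$sets_A, res$sets_B), function(s) {
      if (s$kind != "trans" || !s$significant) return(NULL)
      i <- match(s$lead$variant_id, g$variants$variant_id)
      data.frame(platform = s$platform, probe_id = s$probe_id,
                 chrom = g$variants$chrom[i], pos = g$variants$pos[i],
                 stringsAsFactors = FALSE)
    }))
    res$pleio_regions <- run_stage("crossplat",
      if (is.null(sent))
        trans_regions(data.frame(platform = character(),
                                 probe_id = character(), chrom = character(),
                                 pos = numeric()))
      else trans_regions(sent, half_window = config$half_window,
                         min_proteins = config$pleio_min_proteins,
                         max_other = config$pleio_max_other))
    write_result_table(res$pleio_regions,
                       file.path(out_dir, "pleiotropy_regions.tsv"))
    log_line(logcon, "crossplat: ", nrow(res$pleio_regions),
             " trans region(s)")
  }

  if ("adjust" %in% config$stages && !is.null(res$pairs)) {
    res$adjustment <- run_stage("adjust",
      adjust_stage(res, cohort, config))
    write_result_table(res$adjustment$report,
                       file.path(out_dir, "adjustment_report.tsv"))
    write_result_table(res$adjustment$signal_changes,
                       file.path(out_dir, "adjustment_signals.tsv"))
    log_line(logcon, "adjust: ", nrow(res$adjustment$report),
             " protein/PAV adjustment(s)")
  }

  if ("epi" %in% config$stages) {
    res$pheno_assoc <- run_stage("epi", rbind(
      phenotype_association_table(res$prep_A$transformed, st),
      phenotype_association_table(res$prep_B$transformed, st)))
    write_result_table(res$pheno_assoc,
                       file.path(out_dir, "phenotype_associations.tsv"))
    res$lod <- run_stage("epi", lod_table(cohort$raw_B, cohort$controls))
    write_result_table(res$lod, file.path(out_dir, "lod.tsv"))
    log_line(logcon, "epi: ", nrow(res$pheno_assoc),
             " phenotype associations; ", nrow(res$lod), " LOD records")
  }

  invisible(res)
}

# Selects PAVs to adjust (explicit list, or leads/shared members of
# discordant pairs annotated as protein-altering for the target gene),
# then quantifies pre/post correlations and remaps cis signals with the
# PAV as covariate, applying the residual-LD filter for newly-associated
# calls.
adjust_stage <- function(res, cohort, config) {
  st <- cohort$samples
  g <- cohort$genotypes
  probes <- cohort$probes
  targets <- list()   # uniprot -> pav variant id
  if (!is.null(config$pav_list)) {
    targets <- as.list(config$pav_list)
  } else if (isTRUE(config$adjust_auto)) {
    disc <- res$pairs[res$pairs$category == "overlapping_discordant", ,
                      drop = FALSE]
    for (i in seq_len(nrow(disc))) {
      up <- disc$uniprot_id[i]
      gene <- probes$gene_symbol[match(up, probes$uniprot_id)]
      cand <- disc$compared_variant[i]
      is_pav <- function(v) {
        j <- match(v, g$variants$variant_id)
        !is.na(j) && g$variants$consequence_class[j] %in% pav_classes() &&
          identical(g$variants$consequence_gene[j], gene)
      }
      if (!is.na(cand) && is_pav(cand)) {
        targets[[up]] <- cand
      } else {
        sa <- Filter(function(s) s$probe_id == disc$probe_id_A[i] &&
                       s$signal_index == disc$signal_A[i], res$sets_A)
        sb <- Filter(function(s) s$probe_id == disc$probe_id_B[i] &&
                       s$signal_index == disc$signal_B[i], res$sets_B)
        if (length(sa) && length(sb)) {
          shared <- intersect(sa[[1]]$members, sb[[1]]$members)
          pavs <- Filter(is_pav, shared)
          if (length(pavs)) targets[[up]] <- pavs[[1]]
        }
      }
    }
  }
  report <- list()
  changes <- list()
  for (up in names(targets)) {
    pav <- targets[[up]]
    pa <- probes[probes$uniprot_id == up & probes$platform == "A", ]
    pb <- probes[probes$uniprot_id == up & probes$platform == "B", ]
    if (nrow(pa) == 0 || nrow(pb) == 0) next
    x_a <- res$prep_A$transformed$values[, pa$probe_id[1]]
    x_b <- res$prep_B$transformed$values[, pb$probe_id[1]]
    dosage <- g$dosages[, pav]
    rep_ <- adjustment_report(x_a, x_b, dosage, st)
    row <- data.frame(uniprot_id = up, pav_id = pav, r_pre = rep_$r_pre,
                      r_post = rep_$r_post, delta = rep_$delta,
                      Q_pre = rep_$Q_pre, Q_post = rep_$Q_post,
                      p_het_pre = rep_$p_het_pre,
                      p_het_post = rep_$p_het_post,
                      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(rep_$by_group))) {
      gp <- rep_$by_group$group[k]
      row[[paste0("r_pre_", gp)]] <- rep_$by_group$r_pre[k]
      row[[paste0("r_post_", gp)]] <- rep_$by_group$r_post[k]
    }
    report[[length(report) + 1]] <- row
    for (plat in c("A", "B")) {
      pm <- if (plat == "A") res$prep_A$residualized else
        res$prep_B$residualized
      sets_pre <- Filter(function(s)
        s$kind == "cis" &&
          s$probe_id == (if (plat == "A") pa$probe_id[1] else pb$probe_id[1]),
        if (plat == "A") res$sets_A else res$sets_B)
      pid <- if (plat == "A") pa$probe_id[1] else pb$probe_id[1]
      pr <- probes[probes$probe_id == pid & probes$platform == plat, ]
      win <- cis_window(g$variants, pr$chrom, pr$tss)
      sets_post <- finemap(pm$values[, pid], g, win$cis, kind = "cis",
                           probe_id = pid, platform = plat,
                           threshold = config$cis_threshold, W = config$W,
                           max_signals = config$max_signals,
                           covariates = matrix(dosage, ncol = 1))
      sets_post <- dedup_credible_sets(sets_post, g,
                                       ld_threshold = config$ld_r2)
      cmp <- compare_signals_post_adjustment(sets_pre, sets_post, g,
                                             ld_threshold = config$ld_r2)
      if (nrow(cmp)) {
        cmp$uniprot_id <- up
        cmp$pav_id <- pav
        changes[[length(changes) + 1]] <- cmp
      }
    }
  }
  empty_report <- data.frame(uniprot_id = character(), pav_id = character(),
                             r_pre = numeric(), r_post = numeric(),
                             delta = numeric(), Q_pre = numeric(),
                             Q_post = numeric(), p_het_pre = numeric(),
                             p_het_post = numeric())
  list(report = if (length(report)) do.call(rbind, report) else empty_report,
       signal_changes = if (length(changes)) do.call(rbind, changes) else
         data.frame(probe_id = character(), platform = character(),
                    phase = character(), signal_index = integer(),
                    lead_variant = character(), lead_p = numeric(),
                    matched_pre_signal = integer(), label = character(),
                    uniprot_id = character(), pav_id = character()))
}
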