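test_that("signal pairs classify by shared-sentinel effect direction", {
  sA <- make_set(c("v1", "v2"), "v1", 0.5, 1e-20, platform = "A")
  sB <- make_set(c("v1", "v3"), "v1", 0.3, 1e-15, platform = "B")
  expect_equal(classify_pair(sA, sB)$category, "overlapping_concordant")

  # opposite-direction missense archetype (aptamer down, antibody up)
  sA2 <- make_set(c("v1", "v2"), "v1", -1.34, 1e-300, platform = "A")
  sB2 <- make_set(c("v1", "v3"), "v1", 0.92, 1e-300, platform = "B")
  out <- classify_pair(sA2, sB2)
  expect_equal(out$category, "overlapping_discordant")
  expect_equal(out$compared_variant, "v1")

  # shared member but neither lead contained in the other set
  sA3 <- make_set(c("v1", "v2"), "v2", 0.5, 1e-20, platform = "A")
  sB3 <- make_set(c("v1", "v3"), "v3", 0.3, 1e-15, platform = "B")
  expect_equal(classify_pair(sA3, sB3)$category, "overlapping_uncompared")

  expect_equal(classify_pair(sA, NULL)$category, "A_only")
  expect_equal(classify_pair(NULL, sB)$category, "B_only")
  expect_error(classify_pair(NULL, NULL), "absent")
})

test_that("classification is symmetric under platform swap", {
  set.seed(71)
  for (i in 1:20) {
    mA <- sample(sprintf("v%d", 1:6), 3)
    mB <- sample(sprintf("v%d", 1:6), 3)
    sA <- make_set(mA, mA[1], rnorm(1), 1e-12, platform = "A")
    sB <- make_set(mB, mB[1], rnorm(1), 1e-12, platform = "B")
    ab <- classify_pair(sA, sB)$category
    ba <- classify_pair(sB, sA)$category
    swap <- c(A_only = "B_only", B_only = "A_only",
              overlapping_concordant = "overlapping_concordant",
              overlapping_discordant = "overlapping_discordant",
              overlapping_uncompared = "overlapping_uncompared",
              non_overlapping = "non_overlapping")
    expect_equal(ba, unname(swap[ab]))
  }
})

test_that("PAV membership requires a protein-altering class on the target gene", {
  v <- data.frame(variant_id = c("v1", "v2", "v3"),
                  consequence_class = c("missense", "missense", "other"),
                  consequence_gene = c("GENE1", "GENE2", "GENE1"))
  s <- make_set(c("v1", "v3"), "v1", 0.5, 1e-10)
  expect_true(contains_pav(s, v, "GENE1"))
  s2 <- make_set(c("v2"), "v2", 0.5, 1e-10)
  expect_false(contains_pav(s2, v, "GENE1"))
  s3 <- make_set(c("v3"), "v3", 0.5, 1e-10)
  expect_false(contains_pav(s3, v, "GENE1"))
})

test_that("per-group EAF counts observed alleles only", {
  st <- make_samples(6, groups = c(G1 = 3, G2 = 3))
  d <- cbind(v1 = c(0, 1, 2, 0, 0, 0), v2 = c(2, 2, NA, 1, 1, 1))
  rownames(d) <- st$sample_id
  g <- make_genotypes(d)
  eaf <- eaf_by_group(g, st)
  expect_equal(eaf$eaf[eaf$variant_id == "v1" & eaf$group == "G1"], 0.5)
  expect_equal(eaf$eaf[eaf$variant_id == "v1" & eaf$group == "G2"], 0)
  # missing dosage drops from the denominator
  expect_equal(eaf$total_alleles[eaf$variant_id == "v2" & eaf$group == "G1"], 4)
  expect_equal(eaf$eaf[eaf$variant_id == "v2" & eaf$group == "G1"], 1)
})

test_that("simulated group EAFs track the planted frequencies", {
  cfg <- sim_config(groups = c(AFR = 300, AMR = 300, EAS = 300, EUR = 300),
                    n_null_variants = 0,
                    proteins = list(protein_block(
                      pav = TRUE, delta_A = -1,
                      pav_freqs = c(0.45, 0.05, 0.02, 0.05),
                      n_cis_neutral = 0)))
  co <- simulate_cohort(cfg, seed = 13)
  eaf <- eaf_by_group(co$genotypes, co$samples)
  truth <- co$truth$variant_freqs
  for (i in seq_len(nrow(truth))) {
    row <- eaf[eaf$variant_id == truth$variant_id[i] &
                 eaf$group == truth$group[i], ]
    se <- sqrt(truth$freq[i] * (1 - truth$freq[i]) / row$total_alleles)
    expect_lt(abs(row$eaf - truth$freq[i]), 3 * se + 1e-9)
  }
})

test_that("allele-count chi-square matches hand arithmetic and the oracle", {
  eq <- eaf_chi_square(c(20, 20), c(100, 100))
  expect_equal(eq$x2, 0)
  expect_equal(eq$p, 1)

  out <- eaf_chi_square(c(10, 30), c(100, 100))
  expect_equal(out$x2, 12.5, tolerance = 1e-12)
  expect_equal(out$df, 1L)
  expect_equal(out$p, 4.07e-4, tolerance = 0.01)

  # brute-force contingency oracle over random small instances
  set.seed(72)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    tot <- sample(5:20, k, replace = TRUE) * 2
    alt <- vapply(tot, function(t) sample(1:(t - 1), 1), integer(1))
    mine <- eaf_chi_square(alt, tot)
    oracle <- suppressWarnings(
      chisq.test(cbind(alt, tot - alt), correct = FALSE))
    expect_equal(mine$x2, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(mine$df, as.integer(oracle$parameter))
    expect_equal(mine$p, unname(oracle$p.value), tolerance = 1e-12)
  }

  deg <- eaf_chi_square(c(0, 0), c(50, 50))
  expect_true(deg$degenerate)
  expect_equal(deg$x2, 0)
  expect_equal(deg$p, 1)
})

test_that("the published-scale chi-square statistic maps to its tail p", {
  expect_equal(chi_square_p(230.7, 3), 9.49e-50, tolerance = 0.03)
})

test_that("differentiation threshold is the interpolated 75th percentile", {
  out <- differentiation_flags(1:100)
  expect_equal(out$threshold, 75.25)
  expect_true(out$flags[80])
  expect_false(out$flags[75])

  none <- differentiation_flags(rep(5, 10))
  expect_false(any(none$flags))   # strict inequality

  # duplicating the max can only raise the threshold; values above the new
  # threshold stay flagged
  withdup <- differentiation_flags(c(1:100, 100))
  expect_gte(withdup$threshold, out$threshold)
  expect_true(all(withdup$flags[1:100] == (1:100 > withdup$threshold)))
  expect_error(differentiation_flags(c(1, 2, 3)), ">= 4")
})

test_that("trans regions merge windows and apply the pleiotropy rules", {
  sent <- data.frame(platform = c("A", "A"), probe_id = c("p1", "p2"),
                     chrom = "9", pos = c(5.0e6, 5.8e6))
  reg <- trans_regions(sent)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 4.5e6)
  expect_equal(reg$end, 6.3e6)
  expect_gte(reg$end - reg$start, 1e6)

  mk <- function(nA, nB) data.frame(
    platform = rep(c("A", "B"), c(nA, nB)),
    probe_id = c(sprintf("a%d", seq_len(nA)), sprintf("b%d", seq_len(nB))),
    chrom = "1", pos = 2e6)
  expect_equal(trans_regions(mk(6, 0))$category, "A_specific")
  expect_equal(trans_regions(mk(0, 6))$category, "B_specific")
  expect_equal(trans_regions(mk(5, 2))$category, "not_pleiotropic")
  expect_equal(trans_regions(mk(5, 5))$category, "shared_pleiotropic")
  expect_equal(trans_regions(mk(6, 1))$category, "A_specific")
})

test_that("region merging is idempotent and order-independent", {
  set.seed(73)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    sent <- data.frame(platform = sample(c("A", "B"), k, replace = TRUE),
                       probe_id = sprintf("p%d", sample(1:6, k, replace = TRUE)),
                       chrom = sample(c("1", "2"), k, replace = TRUE),
                       pos = sample(1e6:2e7, k))
    a <- trans_regions(sent)
    b <- trans_regions(sent[sample(k), ])
    expect_equal(a, b)
    # feeding the merged regions' midpoints back in cannot split regions
    again <- xpqtl:::merge_intervals(a$chrom, a$start, a$end)
    expect_equal(nrow(again), nrow(a))
    expect_equal(again$start, a$start)
    expect_equal(again$end, a$end)
  }
})

test_that("external sentinel overlap honors gene match and sign conflicts", {
  ext <- sentinel_table(
    source = c("eqtl", "eqtl", "eqtl", "eqtl"),
    variant_id = c("v1", "v1", "v2", "v2"),
    gene = c("GENE1", "GENE1", "GENE1", "GENE1"),
    context = c("liver", "blood", "liver", "blood"),
    sign = c(1, 1, 1, -1))
  genes <- c(pr1 = "GENE1", pr2 = "GENE2")
  s_match <- make_set(c("v1", "vx"), "v1", 0.4, 1e-12)
  out <- sentinel_overlap(list(s_match), ext, genes)
  expect_true(out$matched)
  expect_true(out$concordant)

  s_conflict <- make_set(c("v2"), "v2", 0.4, 1e-12)
  out2 <- sentinel_overlap(list(s_conflict), ext, genes)
  expect_true(out2$matched)
  expect_true(out2$excluded_conflict)
  expect_true(is.na(out2$concordant))

  s_other_gene <- make_set(c("v1"), "v1", 0.4, 1e-12, probe = "pr2")
  out3 <- sentinel_overlap(list(s_other_gene), ext, genes)
  expect_false(out3$matched)

  s_none <- make_set(c("vz"), "vz", 0.4, 1e-12)
  expect_false(sentinel_overlap(list(s_none), ext, genes)$matched)
})
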