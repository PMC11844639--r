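# Small in-code fixtures shared across test files.

# genotype_data from a plain dosage matrix, all variants on one chromosome
make_genotypes <- function(dosages, chrom = "1", pos = NULL,
                           consequence_class = NULL,
                           consequence_gene = NULL) {
  m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("v%d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_data(dosages, data.frame(
    variant_id = colnames(dosages), chrom = chrom, pos = pos,
    ref = "A", alt = "G",
    consequence_class = if (is.null(consequence_class)) "none"
    else consequence_class,
    consequence_gene = if (is.null(consequence_gene)) NA_character_
    else consequence_gene,
    stringsAsFactors = FALSE))
}

make_samples <- function(n, groups = c(G1 = n %/% 2, G2 = n - n %/% 2)) {
  sample_table(sprintf("S%03d", seq_len(n)),
               age = seq(40, 70, length.out = n),
               sex = rep_len(0:1, n),
               site = rep_len(c("s1", "s2", "s2", "s1", "s2"), n),
               plate = rep_len(c("p1", "p2", "p3"), n),
               ancestry = rep(names(groups), times = groups),
               bmi = seq(20, 35, length.out = n),
               t2d = rep_len(c(0, 0, 1), n),
               groups = names(groups))
}

# manual credible set (internal constructor) for rule-based tests
make_set <- function(members, lead_id, lead_beta, lead_p, probe = "pr1",
                     platform = "A", signal = 1L, kind = "cis",
                     lead_se = 0.1) {
  xpqtl:::new_credible_set(
    probe_id = probe, platform = platform, signal_index = signal,
    members = members, pip = rep(1 / length(members), length(members)),
    lead = list(variant_id = lead_id, beta = lead_beta, se = lead_se,
                p = lead_p),
    kind = kind, significant = TRUE)
}
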