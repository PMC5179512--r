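# Truth-known benchmark cohort designs shared across tests.
#
# Effect sizes were fixed by an a-priori variance-budget/power analysis (see
# the methods vignette): planted effects are parameterized on a target
# t-score scale so the grid spans from well below to well above the
# detection boundary of the permutation-FDR scan at n = 240.

# 300 null + 20 planted features; alternating presence/abundance carriers
# and signs; target t-scores 0.5..5 SE.
fdr_benchmark_config <- function(seed) {
  tg <- seq(0.5, 5, length.out = 20)
  is_binary <- rep(c(TRUE, FALSE), 10)
  sgn <- rep(c(1, -1), 10)
  cohort_config(
    n_samples = 240, n_otus = 320, n_causal = 20,
    prevalence_range = c(0.3, 0.8), abundance_logmean_sd = c(0, 1.2),
    beta1_values = ifelse(is_binary, 0.117 * tg * sgn, 0),
    beta2_values = ifelse(is_binary, 0, 0.078 * tg * sgn),
    seed = seed)
}

# top tercile of the planted effects, by design t-score
fdr_benchmark_strong <- function(truth) truth$otu_id[14:20]

# abundance-effect recovery: 5 causal OTUs with beta2 = 0.2
recovery_benchmark_config <- function(seed, beta2 = 0.2) {
  cohort_config(n_samples = 240, n_otus = 50, n_causal = 5,
                prevalence_range = c(0.5, 0.9),
                beta1_values = rep(0, 5), beta2_values = rep(beta2, 5),
                seed = seed)
}

# compact panel whose 4 planted abundance effects contribute 20% of trait
# variance analytically: var = sum(beta2^2 * pi_j), E[pi] = 0.775, so
# |beta2| = sqrt(0.25 * 0.58^2 / (4 * 0.775))
variance20_benchmark_config <- function(seed) {
  b <- sqrt(0.25 * 0.58^2 / (4 * 0.775))
  cohort_config(n_samples = 240, n_otus = 20, n_causal = 4,
                prevalence_range = c(0.6, 0.95),
                beta1_values = rep(0, 4),
                beta2_values = b * c(1, -1, 1, -1),
                sex_effect = 0, bw_effect = 0, seed = seed)
}

null_benchmark_config <- function(seed, n_otus = 20) {
  cohort_config(n_samples = 240, n_otus = n_otus, sex_effect = 0,
                bw_effect = 0, seed = seed)
}

# counts -> filtered-free relative abundances + adjusted trait + features
prepare_cohort <- function(cohort, min_present = 10) {
  ab <- to_relative_abundance(cohort$counts)
  y <- adjust_trait(cohort$phenotypes$trait, cohort$phenotypes$sex,
                    cohort$phenotypes$body_weight,
                    sample_ids = cohort$phenotypes$sample_id)
  list(ab = ab, y = y, features = two_part_features(ab, min_present))
}
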