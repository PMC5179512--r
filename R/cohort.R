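#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated 16S cohort: a sample x OTU
#' count table with zero-inflated abundances (per-OTU presence probability
#' times a lognormal latent relative abundance), uniform library sizes, a sex
#' and body-weight covariate, and a quantitative fatness-like trait carrying a
#' sparse set of planted presence (`beta1`) and abundance (`beta2`) effects.
#'
#' Defaults emulate a porcine fatness cohort: ~240 animals, 500 OTUs, library
#' sizes 20,000--31,000 reads, trait mean 2.07 and residual SD 0.58 (leaf fat
#' weight, kg).
#'
#' @param n_samples Number of samples (animals).
#' @param n_otus Number of OTUs in the table.
#' @param n_causal Number of OTUs with planted trait effects.
#' @param library_size_range Integer pair; per-sample read depths are drawn
#'   uniformly over this range.
#' @param prevalence_range Pair of probabilities in (0,1); each OTU's presence
#'   probability is drawn uniformly over this range.
#' @param abundance_logmean_sd Pair `(meanlog, sdlog)` of the lognormal latent
#'   relative abundance of an OTU in the samples where it is present.
#' @param beta1_sd SD of planted presence effects (trait units); ignored when
#'   `beta1_values` is given.
#' @param beta2_sd SD of planted abundance effects, in trait units per 1 SD of
#'   standardized log abundance; ignored when `beta2_values` is given.
#' @param beta1_values,beta2_values Optional numeric vectors of length
#'   `n_causal` fixing the planted effects exactly.
#' @param trait_mean Trait intercept (trait units).
#' @param trait_sd_resid Residual trait SD (>= 0; 0 gives a noiseless trait).
#' @param sex_effect Additive effect of sex (coded 0/1) on the trait.
#' @param bw_mean_sd Pair `(mean, sd)` of body weight in kg.
#' @param bw_effect Trait units per kg of body weight.
#' @param seed Integer seed; the generator is fully reproducible under it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 240, n_otus = 500, n_causal = 20,
                          library_size_range = c(20000L, 31000L),
                          prevalence_range = c(0.05, 0.95),
                          abundance_logmean_sd = c(0, 2),
                          beta1_sd = 0.1, beta2_sd = 0.05,
                          beta1_values = NULL, beta2_values = NULL,
                          trait_mean = 2.07, trait_sd_resid = 0.58,
                          sex_effect = 0.2, bw_mean_sd = c(60, 10),
                          bw_effect = 0.02, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_otus = as.integer(n_otus),
              n_causal = as.integer(n_causal),
              library_size_range = as.integer(library_size_range),
              prevalence_range = prevalence_range,
              abundance_logmean_sd = abundance_logmean_sd,
              beta1_sd = beta1_sd, beta2_sd = beta2_sd,
              beta1_values = beta1_values, beta2_values = beta2_values,
              trait_mean = trait_mean, trait_sd_resid = trait_sd_resid,
              sex_effect = sex_effect, bw_mean_sd = bw_mean_sd,
              bw_effect = bw_effect, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 2) stop_("n_samples must be >= 2")
  if (cfg$n_otus < 1) stop_("n_otus must be >= 1")
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_otus)
    stop_("n_causal must lie in [0, n_otus]")
  if (length(cfg$library_size_range) != 2 || diff(cfg$library_size_range) < 0 ||
      cfg$library_size_range[1] < 1)
    stop_("library_size_range must be an ordered pair of positive integers")
  pr <- cfg$prevalence_range
  if (length(pr) != 2 || pr[1] > pr[2] || pr[1] <= 0 || pr[2] >= 1)
    stop_("prevalence_range must be an ordered pair inside (0, 1)")
  if (length(cfg$abundance_logmean_sd) != 2 || cfg$abundance_logmean_sd[2] < 0)
    stop_("abundance_logmean_sd must be (meanlog, sdlog) with sdlog >= 0")
  if (cfg$trait_sd_resid < 0) stop_("trait_sd_resid must be >= 0")
  for (nm in c("beta1_values", "beta2_values")) {
    v <- cfg[[nm]]
    if (!is.null(v) && length(v) != cfg$n_causal)
      stop_("%s must have length n_causal (%d)", nm, cfg$n_causal)
  }
  if (length(cfg$bw_mean_sd) != 2 || cfg$bw_mean_sd[2] < 0)
    stop_("bw_mean_sd must be (mean, sd) with sd >= 0")
  invisible(cfg)
}

#' Generate a synthetic cohort with planted microbiome effects
#'
#' For each OTU j a presence probability `pi_j` is drawn uniformly over
#' `prevalence_range`; presence indicators are Bernoulli(`pi_j`) and the
#' latent abundance of a present OTU is lognormal with the configured
#' `(meanlog, sdlog)`.  Per-sample latent abundances are normalized to
#' proportions and read counts are drawn multinomially at the sample's
#' library size, which induces additional sampling zeros for rare OTUs.
#'
#' The trait is
#' `y = trait_mean + sex_effect*sex + bw_effect*bw + sum_causal(beta1*b + beta2*z(q)) + N(0, trait_sd_resid)`
#' where `z(q)` is the standardized natural-log latent abundance among present
#' samples (0 where absent) -- the same transformation the association scan
#' applies, so planted `beta2` values are recoverable on their own scale.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `counts`
#'   (integer sample x OTU matrix), `phenotypes` (data.frame with sample_id,
#'   sex, body_weight, trait), `truth` (data.frame otu_id, beta1, beta2 for
#'   the causal OTUs), `microbiome_value` (per-sample planted contribution)
#'   and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_otus
  sample_ids <- sprintf("S%03d", seq_len(n))
  otu_ids <- sprintf("OTU%04d", seq_len(m))

  lib <- sample(seq(config$library_size_range[1], config$library_size_range[2]),
                n, replace = TRUE)
  pi_j <- stats::runif(m, config$prevalence_range[1], config$prevalence_range[2])
  B <- matrix(stats::rbinom(n * m, 1L, rep(pi_j, each = n)), nrow = n)
  lat <- matrix(exp(stats::rnorm(n * m, config$abundance_logmean_sd[1],
                                 config$abundance_logmean_sd[2])), nrow = n)
  A <- B * lat
  # a sample with no present OTU cannot be normalized; force its most
  # prevalent OTU present (vanishingly rare under realistic configs)
  empty <- rowSums(A) == 0
  if (any(empty)) {
    jmax <- which.max(pi_j)
    B[empty, jmax] <- 1L
    A[empty, jmax] <- lat[empty, jmax]
  }
  P <- A / rowSums(A)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1L, lib[i], P[i, ])[, 1L],
                     integer(m)))
  dimnames(counts) <- list(sample_ids, otu_ids)
  storage.mode(counts) <- "integer"

  if (config$n_causal > 0) {
    causal <- sort(sample.int(m, config$n_causal))
    beta1 <- config$beta1_values %||% stats::rnorm(config$n_causal, 0, config$beta1_sd)
    beta2 <- config$beta2_values %||% stats::rnorm(config$n_causal, 0, config$beta2_sd)
    # the abundance carrier is the standardized log *relative* abundance --
    # the same scale the association scan regresses on, so beta2 is
    # recoverable up to multinomial counting noise
    Z <- vapply(causal, function(j) {
      z <- numeric(n)
      pres <- B[, j] == 1L
      if (sum(pres) >= 2) {
        lq <- log(P[pres, j])
        s <- stats::sd(lq)
        if (s > 0) z[pres] <- (lq - mean(lq)) / s
      }
      z
    }, numeric(n))
    micro <- drop(B[, causal, drop = FALSE] %*% beta1 + Z %*% beta2)
    truth <- data.frame(otu_id = otu_ids[causal], beta1 = beta1, beta2 = beta2,
                        stringsAsFactors = FALSE)
  } else {
    micro <- numeric(n)
    truth <- data.frame(otu_id = character(0), beta1 = numeric(0),
                        beta2 = numeric(0), stringsAsFactors = FALSE)
  }

  sex <- stats::rbinom(n, 1L, 0.5)
  bw <- stats::rnorm(n, config$bw_mean_sd[1], config$bw_mean_sd[2])
  y <- config$trait_mean + config$sex_effect * sex + config$bw_effect * bw +
    micro + stats::rnorm(n, 0, config$trait_sd_resid)

  structure(list(
    counts = counts,
    phenotypes = data.frame(sample_id = sample_ids, sex = sex,
                            body_weight = bw, trait = y,
                            stringsAsFactors = FALSE),
    truth = truth,
    microbiome_value = stats::setNames(micro, sample_ids),
    library_sizes = stats::setNames(lib, sample_ids),
    config = config
  ), class = "synthetic_cohort")
}

#' Generate a cohort with no planted effects (pure null)
#'
#' Identical to [generate_cohort()] with `n_causal` forced to 0: the trait is
#' independent of every OTU given the covariates.  Used as a type-I-error and
#' FDR-calibration test bed.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort` with an empty truth table.
#' @export
generate_null_cohort <- function(config) {
  config$n_causal <- 0L
  config$beta1_values <- NULL
  config$beta2_values <- NULL
  generate_cohort(config)
}

#' Write a synthetic cohort to tab-delimited files
#'
#' Writes `counts.tsv` (first column `sample_id`, remaining columns OTU IDs),
#' `phenotypes.tsv`, `truth.tsv` and a `metadata.txt` recording the seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             metadata = file.path(dir, "metadata.txt"))
  write_count_table(cohort$counts, paths["counts"])
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("seed\t%d", cohort$config$seed),
               sprintf("n_samples\t%d", cohort$config$n_samples),
               sprintf("n_otus\t%d", cohort$config$n_otus),
               sprintf("n_causal\t%d", cohort$config$n_causal)),
             paths["metadata"])
  invisible(paths)
}
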