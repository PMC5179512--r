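check_div_input <- function(counts, min_total = 1) {
  if (any(counts < 0)) stop_("counts must be non-negative")
  if (sum(counts) < min_total)
    stop_("total count must be >= %d", min_total)
  invisible(counts)
}

#' Observed species richness
#'
#' @param counts Non-negative integer vector of per-species read counts.
#' @return Number of species with count > 0.
#' @export
observed_species <- function(counts) {
  check_div_input(counts)
  sum(counts > 0)
}

#' Bias-corrected chao1 richness estimator
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1`/`F2` are the numbers of
#' singleton and doubleton species.  The bias-corrected form is defined even
#' when there are no doubletons.
#'
#' @inheritParams observed_species
#' @return Estimated richness (>= observed).
#' @export
chao1 <- function(counts) {
  check_div_input(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sum(counts > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Abundance-based coverage estimator (ACE)
#'
#' Splits species into rare (count <= `rare_cutoff`) and abundant groups and
#' estimates richness as
#' `S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2`, with sample coverage
#' `C_ace = 1 - F1 / N_rare` and squared coefficient of variation
#' `gamma^2 = max(S_rare * sum(i (i-1) F_i) / (C_ace N_rare (N_rare - 1)) - 1, 0)`.
#' When every rare read is a singleton the coverage is 0 and the function
#' falls back to [chao1()] with a warning.
#'
#' @inheritParams observed_species
#' @param rare_cutoff Count threshold separating rare from abundant species
#'   (default 10).
#' @return Estimated richness.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  check_div_input(counts)
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warn_("ACE coverage is 0 (all rare reads are singletons); falling back to chao1")
    return(chao1(counts))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  ssum <- sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fi)
  gamma2 <- if (n_rare > 1)
    max(s_rare * ssum / (c_ace * n_rare * (n_rare - 1)) - 1, 0) else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i log p_i)` over nonzero proportions `p_i = count_i / total`.
#'
#' @inheritParams observed_species
#' @return Shannon entropy in nats.
#' @export
shannon <- function(counts) {
  check_div_input(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Unbiased Simpson diversity
#'
#' Reported as diversity, `1 - sum(n_i (n_i - 1)) / (N (N - 1))` (the
#' complement of the small-sample-unbiased dominance), so that higher values
#' mean more diverse communities.
#'
#' @inheritParams observed_species
#' @return Simpson diversity in \[0, 1\].
#' @export
simpson <- function(counts) {
  check_div_input(counts, min_total = 2)
  n <- sum(counts)
  1 - sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Per-sample alpha-diversity profile
#'
#' @param counts Sample x species count matrix (e.g. a rarefied OTU table).
#' @param rare_cutoff Passed to [ace()].
#' @return Data.frame with one row per sample: observed, chao1, ace, shannon,
#'   simpson.
#' @export
alpha_diversity <- function(counts, rare_cutoff = 10) {
  check_count_matrix(counts)
  data.frame(
    sample_id = rownames(counts),
    observed = apply(counts, 1, observed_species),
    chao1 = apply(counts, 1, chao1),
    ace = apply(counts, 1, ace, rare_cutoff = rare_cutoff),
    shannon = apply(counts, 1, shannon),
    simpson = apply(counts, 1, simpson),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-group comparison of a diversity index
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between independent
#' groups: exact enumeration for small tie-free samples (< 8 per group),
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param valuesA,valuesB Numeric vectors (>= 2 observations each).
#' @return Two-sided p-value.
#' @export
compare_groups <- function(valuesA, valuesB) {
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop_("both groups need >= 2 observations")
  if (length(unique(c(valuesA, valuesB))) == 1L) return(1)
  ties <- any(duplicated(c(valuesA, valuesB)))
  use_exact <- !ties && min(length(valuesA), length(valuesB)) < 8
  stats::wilcox.test(valuesA, valuesB, alternative = "two.sided",
                     exact = use_exact, correct = TRUE)$p.value
}

#' Compare alpha-diversity indices between two groups of samples
#'
#' @param profile Data.frame from [alpha_diversity()].
#' @param groups Factor/vector of two group labels aligned with the profile
#'   rows.
#' @return Data.frame: index, group medians and Wilcoxon rank-sum p-value.
#' @export
compare_diversity <- function(profile, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop_("exactly two groups required")
  idx <- c("observed", "chao1", "ace", "shannon", "simpson")
  g1 <- groups == levels(groups)[1]
  do.call(rbind, lapply(idx, function(i) {
    data.frame(index = i,
               median_A = stats::median(profile[[i]][g1]),
               median_B = stats::median(profile[[i]][!g1]),
               p_value = compare_groups(profile[[i]][g1], profile[[i]][!g1]),
               stringsAsFactors = FALSE)
  }))
}
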