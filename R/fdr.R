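#' Permute an adjusted trait across samples
#'
#' Shuffles the trait values uniformly at random across sample IDs; the
#' multiset of values (and the names) is preserved exactly.
#'
#' @param y Named numeric adjusted-trait vector.
#' @param seed Optional integer seed.
#' @return Permuted vector with the original names.
#' @export
permute_trait <- function(y, seed = NULL) {
  if (length(y) < 2) stop_("need at least 2 observations to permute")
  if (!is.null(seed)) set.seed(seed)
  out <- y
  out[] <- y[sample.int(length(y))]
  out
}

default_cutoff_grid <- function(observed = NULL) {
  g <- 10^seq(-6, 0, length.out = 61)
  sort(unique(c(g, observed[is.finite(observed)])), decreasing = TRUE)
}

#' Permutation-based FDR curve for a two-part association scan
#'
#' For each of `n_perms` permutations the trait is shuffled and the full
#' two-part scan is recomputed on the permuted trait (one shared permutation
#' stream across all features).  At every p-value cutoff `c`, `N1(c)` is the
#' number of real features with final p <= c, `N0_mean(c)` the average such
#' count over the permuted scans, and `FDR(c) = N0_mean(c) / N1(c)` (capped
#' at 1, undefined where `N1(c) = 0`).  The chosen cutoff is the largest `c`
#' with `FDR(c) <= target_fdr` and `N1(c) > 0`.
#'
#' @param real_results Scan of the observed trait (from [associate()]).
#' @param y The observed adjusted trait used for that scan.
#' @param features The [two_part_features()] the scan was run on.
#' @param n_perms Number of permutations (default 1000).
#' @param cutoffs Descending p-value grid; defaults to a 61-point logarithmic
#'   grid over \[1e-6, 1\] augmented with the observed final p-values.
#' @param seed Optional integer seed for the permutation stream.
#' @param target_fdr FDR threshold defining the chosen cutoff (default 0.1).
#' @return Object of class `fdr_curve`: list with a `curve` data.frame
#'   (cutoff, N1, N0_mean, fdr), `chosen_cutoff` (NA when no cutoff meets the
#'   target), `target_fdr` and `n_perms`.
#' @export
build_fdr_curve <- function(real_results, y, features, n_perms = 1000,
                            cutoffs = NULL, seed = NULL, target_fdr = 0.1) {
  if (n_perms < 1) stop_("n_perms must be >= 1")
  cutoffs <- cutoffs %||% default_cutoff_grid(real_results$p_final)
  if (any(cutoffs <= 0) || any(cutoffs > 1)) stop_("cutoffs must lie in (0, 1]")
  cutoffs <- sort(cutoffs, decreasing = TRUE)

  count_at <- function(p, cuts) {
    sp <- sort(p[is.finite(p)])
    findInterval(cuts, sp)  # number of p-values <= each cutoff
  }
  n1 <- count_at(real_results$p_final, cutoffs)

  if (!is.null(seed)) set.seed(seed)
  n0 <- matrix(0L, nrow = n_perms, ncol = length(cutoffs))
  yv <- as.numeric(y)
  for (b in seq_len(n_perms)) {
    yp <- yv[sample.int(length(yv))]
    perm <- scan_twopart(yp, features)
    n0[b, ] <- count_at(perm$p_final, cutoffs)
  }
  n0_mean <- colMeans(n0)
  fdr <- ifelse(n1 > 0, pmin(n0_mean / n1, 1), NA_real_)
  ok <- !is.na(fdr) & fdr <= target_fdr & n1 > 0
  chosen <- if (any(ok)) max(cutoffs[ok]) else NA_real_
  structure(list(curve = data.frame(cutoff = cutoffs, N1 = n1,
                                    N0_mean = n0_mean, fdr = fdr),
                 chosen_cutoff = chosen, target_fdr = target_fdr,
                 n_perms = n_perms),
            class = "fdr_curve")
}

#' Features significant at the permutation-FDR threshold
#'
#' @param curve An [build_fdr_curve()] result.
#' @param real_results The observed association scan.
#' @return The rows of `real_results` with final p <= the chosen cutoff;
#'   zero rows when no cutoff met the FDR target.
#' @export
significant_set <- function(curve, real_results) {
  stopifnot(inherits(curve, "fdr_curve"))
  if (is.na(curve$chosen_cutoff))
    return(real_results[0, , drop = FALSE])
  real_results[real_results$p_final <= curve$chosen_cutoff, , drop = FALSE]
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("Permutation FDR curve (%d permutations, target %.3g)\n",
              x$n_perms, x$target_fdr))
  if (is.na(x$chosen_cutoff)) {
    cat("No cutoff attains the FDR target.\n")
  } else {
    at <- which(x$curve$cutoff == x$chosen_cutoff)[1]
    cat(sprintf("Chosen cutoff: p <= %.3g (N1 = %d, N0_mean = %.2f, FDR = %.3f)\n",
                x$chosen_cutoff, x$curve$N1[at], x$curve$N0_mean[at],
                x$curve$fdr[at]))
  }
  invisible(x)
}
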