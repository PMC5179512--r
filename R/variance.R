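#' Split sample IDs into discovery and validation sets
#'
#' @param sample_ids Character vector of IDs (n >= 10).
#' @param train_frac Fraction assigned to the discovery set (default 0.7).
#' @param seed Optional integer seed.
#' @return List with `discovery` and `validation` ID vectors: disjoint,
#'   exhaustive, with `round(train_frac * n)` discovery samples.
#' @export
split_cohort <- function(sample_ids, train_frac = 0.7, seed = NULL) {
  n <- length(sample_ids)
  if (n < 10) stop_("need at least 10 samples to split")
  if (train_frac <= 0 || train_frac >= 1) stop_("train_frac must be in (0, 1)")
  nd <- round(train_frac * n)
  if (nd < 2 || n - nd < 2) stop_("both sets must contain at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, nd)
  list(discovery = sample_ids[sort(idx)],
       validation = sample_ids[sort(setdiff(seq_len(n), idx))])
}

#' Additive microbiome risk score
#'
#' `r_m(i) = sum_j (beta1_j * b_ij + beta2_j * q_ij)` over the selected
#' features, where `b` is presence and `q` the standardized log abundance
#' (with standardization parameters fitted on the discovery set).  A term
#' whose component was undefined in the discovery scan contributes 0.
#'
#' @param selected Association results (rows of an [associate()] scan) for
#'   the selected features; `beta1`/`beta2` may be NA for undefined parts.
#' @param B,Q Presence and standardized-abundance matrices for the samples to
#'   score (e.g. from [standardize_abundance()] on the validation table).
#' @return Named numeric vector of risk scores with attribute `n_terms` (the
#'   number of selected features); all zeros when no feature is selected.
#' @export
risk_score <- function(selected, B, Q) {
  ids <- rownames(B)
  if (nrow(selected) == 0) {
    out <- stats::setNames(numeric(nrow(B)), ids)
    attr(out, "n_terms") <- 0L
    return(out)
  }
  missing <- setdiff(selected$feature_id, colnames(B))
  if (length(missing))
    stop_("selected feature(s) absent from the scoring table: %s",
          paste(missing, collapse = ", "))
  b1 <- ifelse(is.na(selected$beta1), 0, selected$beta1)
  b2 <- ifelse(is.na(selected$beta2), 0, selected$beta2)
  r <- drop(B[, selected$feature_id, drop = FALSE] %*% b1 +
              Q[, selected$feature_id, drop = FALSE] %*% b2)
  out <- stats::setNames(r, ids)
  attr(out, "n_terms") <- nrow(selected)
  out
}

#' Squared correlation between adjusted trait and risk score
#'
#' @param y_val Adjusted trait on the validation samples.
#' @param r Risk score vector aligned with `y_val`.
#' @return Squared Pearson correlation; 0 when the risk score has zero
#'   variance.
#' @export
r_squared <- function(y_val, r) {
  if (length(y_val) != length(r)) stop_("y_val and r must have equal length")
  if (length(y_val) < 3) stop_("need at least 3 observations")
  if (stats::var(r) == 0 || stats::var(y_val) == 0) return(0)
  stats::cor(y_val, r)^2
}

#' Configuration for cross-validated variance-explained estimation
#'
#' @param n_repeats Number of random splits (default 100).
#' @param train_frac Discovery fraction (default 0.7).
#' @param thresholds Ascending p-value selection grid; default
#'   `c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1)`.
#' @param min_present Passed to the discovery scan (default 10).
#' @param seed Master seed; per-repeat seeds are derived by counter offset.
#' @return Validated list of class `cv_config`.
#' @export
cv_config <- function(n_repeats = 100, train_frac = 0.7,
                      thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1),
                      min_present = 10, seed = 1L) {
  if (n_repeats < 1) stop_("n_repeats must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop_("train_frac must be in (0, 1)")
  if (is.unsorted(thresholds) || any(thresholds <= 0) || any(thresholds > 1))
    stop_("thresholds must be ascending and in (0, 1]")
  structure(list(n_repeats = as.integer(n_repeats), train_frac = train_frac,
                 thresholds = thresholds, min_present = min_present,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Cross-validated variance explained by the microbiome risk score
#'
#' Repeats `n_repeats` times: split the cohort into discovery and validation
#' sets; run the full two-part scan on the discovery set; for each selection
#' threshold keep the features with discovery final p <= threshold; build the
#' additive risk score on the validation samples using the discovery effect
#' estimates and discovery-fitted abundance standardization; record the
#' squared correlation between the validation adjusted trait and the score.
#' A repeat whose selection is empty scores R-squared 0 (the estimator stays
#' defined at strict thresholds); a repeat with no testable discovery
#' features at all is skipped.
#'
#' @param ab Filtered sample x feature relative-abundance matrix.
#' @param y Named adjusted-trait vector aligned with `rownames(ab)`.
#' @param config A [cv_config()].
#' @param trait_name Optional label for the output.
#' @return Data.frame of class `cv_result`, one row per threshold:
#'   trait, threshold, mean_r2, sd_r2, mean_n_selected, n_effective_repeats,
#'   mean_r2_discovery (in-sample counterpart, for overfitting diagnostics).
#' @export
cross_validate <- function(ab, y, config = cv_config(), trait_name = NULL) {
  stopifnot(inherits(config, "cv_config"))
  if (is.null(names(y)) || is.null(rownames(ab)))
    stop_("ab and y must carry sample IDs")
  if (!setequal(names(y), rownames(ab)))
    stop_("sample IDs of ab and y do not match")
  y <- y[rownames(ab)]
  th <- config$thresholds
  r2 <- matrix(NA_real_, nrow = config$n_repeats, ncol = length(th))
  r2_disc <- matrix(NA_real_, nrow = config$n_repeats, ncol = length(th))
  nsel <- matrix(NA_real_, nrow = config$n_repeats, ncol = length(th))
  for (r in seq_len(config$n_repeats)) {
    sp <- split_cohort(rownames(ab), config$train_frac,
                       seed = config$seed + r)
    fd <- two_part_features(ab[sp$discovery, , drop = FALSE],
                            min_present = config$min_present)
    scan <- scan_twopart(as.numeric(y[sp$discovery]), fd)
    scan <- scan[!is.na(scan$p_final), , drop = FALSE]
    if (nrow(scan) == 0) next  # no testable features this repeat
    val <- standardize_abundance(ab[sp$validation, , drop = FALSE],
                                 fd$q_mu, fd$q_sd)
    disc <- list(B = fd$B, Q = fd$Q)
    for (t in seq_along(th)) {
      sel <- scan[scan$p_final <= th[t], , drop = FALSE]
      nsel[r, t] <- nrow(sel)
      if (nrow(sel) == 0) {
        r2[r, t] <- 0
        r2_disc[r, t] <- 0
      } else {
        r2[r, t] <- r_squared(as.numeric(y[sp$validation]),
                              risk_score(sel, val$B, val$Q))
        r2_disc[r, t] <- r_squared(as.numeric(y[sp$discovery]),
                                   risk_score(sel, disc$B, disc$Q))
      }
    }
  }
  eff <- colSums(!is.na(r2))
  out <- data.frame(
    trait = trait_name %||% NA_character_,
    threshold = th,
    mean_r2 = colMeans(r2, na.rm = TRUE),
    sd_r2 = apply(r2, 2, stats::sd, na.rm = TRUE),
    mean_n_selected = colMeans(nsel, na.rm = TRUE),
    n_effective_repeats = as.integer(eff),
    mean_r2_discovery = colMeans(r2_disc, na.rm = TRUE),
    stringsAsFactors = FALSE)
  class(out) <- c("cv_result", "data.frame")
  out
}
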