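#' Build two-part features from a relative-abundance table
#'
#' Decomposes every feature into the two regressors of the hurdle model: a
#' presence indicator `b` and a quantitative carrier `q`, the natural-log
#' abundance standardized (mean 0, SD 1) over the samples where the feature
#' is present and 0 elsewhere.  The per-feature standardization parameters
#' (`q_mu`, `q_sd`) are retained so that held-out samples can be transformed
#' with parameters fitted on a discovery set (see [standardize_abundance()]).
#'
#' @param ab Sample x feature relative-abundance matrix (dimnames required).
#' @param min_present Minimum number of present samples for the quantitative
#'   part to be considered defined (default 10).
#' @return Object of class `two_part_features`: list with `feature_ids`,
#'   binary matrix `B`, standardized matrix `Q`, `n_present`, `q_mu`, `q_sd`,
#'   and `min_present`.
#' @export
two_part_features <- function(ab, min_present = 10) {
  if (!is.matrix(ab) || !is.numeric(ab)) stop_("ab must be a numeric matrix")
  if (is.null(rownames(ab)) || is.null(colnames(ab)))
    stop_("ab must carry sample and feature names")
  B <- (ab > 0) * 1
  n_present <- colSums(B)
  L <- ab
  pos <- L > 0
  L[pos] <- log(L[pos])
  L[!pos] <- 0
  mu <- ifelse(n_present > 0, colSums(L) / n_present, NA_real_)
  dev <- (L - rep(mu, each = nrow(ab))) * B
  ss <- colSums(dev^2)
  sd <- ifelse(n_present > 1, sqrt(ss / (n_present - 1)), NA_real_)
  Q <- dev / rep(ifelse(is.na(sd) | sd == 0, Inf, sd), each = nrow(ab))
  dimnames(Q) <- dimnames(ab)
  structure(list(feature_ids = colnames(ab), B = B, Q = Q,
                 n_present = stats::setNames(n_present, colnames(ab)),
                 q_mu = stats::setNames(mu, colnames(ab)),
                 q_sd = stats::setNames(sd, colnames(ab)),
                 min_present = min_present),
            class = "two_part_features")
}

#' Standardize abundances with externally fitted parameters
#'
#' Applies `z = (log(ab) - q_mu) / q_sd` to present entries (0 where absent),
#' using per-feature location/scale fitted elsewhere -- typically on a
#' discovery set, so validation-set risk scores do not leak information.
#'
#' @param ab Sample x feature relative-abundance matrix.
#' @param q_mu,q_sd Named per-feature mean and SD of log abundance among
#'   present samples (from [two_part_features()]).
#' @return List with binary matrix `B` and standardized matrix `Q`.
#' @export
standardize_abundance <- function(ab, q_mu, q_sd) {
  q_mu <- q_mu[colnames(ab)]
  q_sd <- q_sd[colnames(ab)]
  B <- (ab > 0) * 1
  L <- ab
  pos <- L > 0
  L[pos] <- log(L[pos])
  L[!pos] <- 0
  dev <- (L - rep(q_mu, each = nrow(ab))) * B
  Q <- dev / rep(ifelse(is.na(q_sd) | q_sd == 0, Inf, q_sd), each = nrow(ab))
  Q[is.na(Q)] <- 0
  dimnames(Q) <- dimnames(ab)
  list(B = B, Q = Q)
}

#' Presence/absence (binary) component of the two-part model
#'
#' Ordinary least squares of the adjusted trait on intercept + presence
#' indicator; the slope equals the difference in group means, and the
#' two-sided p-value comes from a t test with n - 2 degrees of freedom.
#'
#' @param y Numeric adjusted-trait vector.
#' @param b Binary presence vector (same length).
#' @return List: `beta1`, `se`, `t`, `df`, `p`, and `defined` (FALSE when the
#'   feature is absent or present in every sample, or n < 4).
#' @export
binary_test <- function(y, b) {
  n <- length(y)
  if (length(b) != n) stop_("y and b must have equal length")
  n1 <- sum(b == 1)
  if (n1 == 0 || n1 == n || n < 4)
    return(list(beta1 = NA_real_, se = NA_real_, t = NA_real_,
                df = NA_real_, p = NA_real_, defined = FALSE))
  m1 <- mean(y[b == 1]); m0 <- mean(y[b == 0])
  beta1 <- m1 - m0
  sse <- sum((y[b == 1] - m1)^2) + sum((y[b == 0] - m0)^2)
  df <- n - 2
  se <- sqrt(sse / df * (1 / n1 + 1 / (n - n1)))
  if (se == 0) {
    p <- if (beta1 == 0) 1 else 1e-300
    t <- if (beta1 == 0) 0 else sign(beta1) * Inf
  } else {
    t <- beta1 / se
    p <- max(2 * stats::pt(-abs(t), df), 1e-300)
  }
  list(beta1 = beta1, se = se, t = t, df = df, p = p, defined = TRUE)
}

#' Abundance-given-presence (quantitative) component of the two-part model
#'
#' Restricted to samples where the feature is present, ordinary least squares
#' of the adjusted trait on intercept + standardized log relative abundance.
#'
#' @param y Numeric adjusted-trait vector.
#' @param abundance Relative-abundance vector (zeros mark absent samples).
#' @param min_present Minimum present samples required (default 10).
#' @return List: `beta2` (trait units per SD of log abundance), `se`, `t`,
#'   `df`, `p`, `n_present`, `defined`.
#' @export
quantitative_test <- function(y, abundance, min_present = 10) {
  n <- length(y)
  if (length(abundance) != n) stop_("y and abundance must have equal length")
  pres <- abundance > 0
  np <- sum(pres)
  und <- list(beta2 = NA_real_, se = NA_real_, t = NA_real_, df = NA_real_,
              p = NA_real_, n_present = np, defined = FALSE)
  if (np < max(min_present, 3)) return(und)
  q <- log(abundance[pres])
  s <- stats::sd(q)
  if (s == 0) return(und)
  q <- (q - mean(q)) / s
  yp <- y[pres]
  sxx <- sum(q^2) - sum(q)^2 / np
  sxy <- sum(q * yp) - sum(q) * sum(yp) / np
  beta2 <- sxy / sxx
  sse <- max(sum((yp - mean(yp))^2) - beta2 * sxy, 0)
  df <- np - 2
  se <- sqrt(sse / df / sxx)
  if (se == 0) {
    p <- if (beta2 == 0) 1 else 1e-300
    t <- if (beta2 == 0) 0 else sign(beta2) * Inf
  } else {
    t <- beta2 / se
    p <- max(2 * stats::pt(-abs(t), df), 1e-300)
  }
  list(beta2 = beta2, se = se, t = t, df = df, p = p, n_present = np,
       defined = TRUE)
}

#' Convert a two-sided p-value to a directional one-tailed p-value
#'
#' Oriented so that a small one-tailed p is evidence of a positive effect:
#' `p/2` for a positive estimate, `1 - p/2` for a negative one, and 0.5 for a
#' zero effect.
#'
#' @param p_two_sided Two-sided p-value(s) in (0, 1].
#' @param beta_sign Sign(s) of the corresponding effect estimate.
#' @return One-tailed p-value(s).
#' @export
one_tailed <- function(p_two_sided, beta_sign) {
  ifelse(beta_sign > 0, p_two_sided / 2,
         ifelse(beta_sign < 0, 1 - p_two_sided / 2, 0.5))
}

#' Unweighted Z-score (Stouffer) meta-combination
#'
#' Each one-tailed p-value is transformed to a standard-normal deviate
#' `z_i = qnorm(1 - p_i)`; the combined statistic is `Z = sum(z_i) / sqrt(k)`
#' which is standard normal under the null, and the meta p-value is the
#' two-sided normal tail `2 * (1 - pnorm(|Z|))`.  With a single component the
#' two-sided meta p equals the component's two-sided p exactly.
#'
#' @param p_one_list Numeric vector of one-tailed p-values (the defined
#'   components; length k >= 1).
#' @return List: `z` (the combined Z), `p` (two-sided meta p-value), `k`.
#'   `k = 0` input returns NAs.
#' @export
meta_combine <- function(p_one_list) {
  k <- length(p_one_list)
  if (k == 0) return(list(z = NA_real_, p = NA_real_, k = 0L))
  z_i <- stats::qnorm(clamp_p(p_one_list), lower.tail = FALSE)
  z <- sum(z_i) / sqrt(k)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), k = k)
}

# Vectorized full scan: closed-form OLS for both components across all
# features at once (a handful of matrix products), so that the
# 1,000-permutation FDR loop is feasible.  Verified against stats::lm in the
# test suite.
scan_twopart <- function(y, features, min_present = features$min_present) {
  stopifnot(inherits(features, "two_part_features"))
  n <- length(y)
  if (n != nrow(features$B)) stop_("y length does not match feature table")
  B <- features$B
  Q <- features$Q
  n1 <- as.numeric(features$n_present)
  n0 <- n - n1

  sy <- sum(y); syy <- sum(y * y)
  s1 <- as.numeric(crossprod(B, y))
  ok_b <- n1 > 0 & n1 < n & n >= 4
  m1 <- ifelse(n1 > 0, s1 / n1, NA_real_)
  m0 <- ifelse(n0 > 0, (sy - s1) / n0, NA_real_)
  beta1 <- m1 - m0
  sse_b <- pmax(syy - ifelse(n1 > 0, n1 * m1^2, 0) -
                  ifelse(n0 > 0, n0 * m0^2, 0), 0)
  se1 <- sqrt(sse_b / (n - 2) * (1 / n1 + 1 / n0))
  t1 <- ifelse(se1 > 0, beta1 / se1, ifelse(beta1 == 0, 0, Inf * sign(beta1)))
  p_b <- pmax(2 * stats::pt(-abs(t1), n - 2), 1e-300)
  p_b[se1 == 0 & beta1 == 0] <- 1
  beta1[!ok_b] <- NA_real_; se1[!ok_b] <- NA_real_; p_b[!ok_b] <- NA_real_

  # quantitative part on present samples; Q is 0 off-present by construction
  sq <- colSums(Q)
  sqq <- colSums(Q^2)
  sqy <- as.numeric(crossprod(Q, y))
  syy_p <- as.numeric(crossprod(B, y^2))
  sxx <- sqq - ifelse(n1 > 0, sq^2 / n1, 0)
  sxy <- sqy - ifelse(n1 > 0, sq * s1 / n1, 0)
  ok_q <- n1 >= max(min_present, 3) & sxx > 1e-12
  beta2 <- ifelse(ok_q, sxy / sxx, NA_real_)
  sse_q <- pmax(syy_p - ifelse(n1 > 0, s1^2 / n1, 0) - beta2 * sxy, 0)
  df_q <- n1 - 2
  se2 <- sqrt(sse_q / df_q / sxx)
  t2 <- ifelse(se2 > 0, beta2 / se2, ifelse(beta2 == 0, 0, Inf * sign(beta2)))
  p_q <- pmax(2 * stats::pt(-abs(t2), df_q), 1e-300)
  p_q[!is.na(se2) & se2 == 0 & !is.na(beta2) & beta2 == 0] <- 1
  se2[!ok_q] <- NA_real_; p_q[!ok_q] <- NA_real_

  # unweighted Z meta over the defined components, oriented by effect sign
  p1_b <- one_tailed(clamp_p(p_b), sign(beta1))
  p1_q <- one_tailed(clamp_p(p_q), sign(beta2))
  z_b <- ifelse(ok_b, stats::qnorm(clamp_p(p1_b), lower.tail = FALSE), 0)
  z_q <- ifelse(ok_q, stats::qnorm(clamp_p(p1_q), lower.tail = FALSE), 0)
  k <- ok_b + ok_q
  z_meta <- ifelse(k > 0, (z_b + z_q) / sqrt(pmax(k, 1)), NA_real_)
  p_meta <- ifelse(k > 0, 2 * stats::pnorm(-abs(z_meta)), NA_real_)

  pmat <- cbind(binary = p_b, quantitative = p_q, meta = p_meta)
  p_final <- suppressWarnings(apply(pmat, 1, min, na.rm = TRUE))
  p_final[!is.finite(p_final)] <- NA_real_
  component <- apply(pmat, 1, function(r) {
    if (all(is.na(r))) NA_character_ else colnames(pmat)[which.min(r)]
  })

  data.frame(feature_id = features$feature_ids,
             n_present = as.integer(n1),
             beta1 = beta1, se1 = se1, p_binary = p_b,
             beta2 = beta2, se2 = se2, p_quant = p_q,
             z_meta = z_meta, p_meta = p_meta,
             p_final = p_final, component = component,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-part association scan of all features against a trait
#'
#' For every feature runs the binary and quantitative components (skipping
#' whichever is undefined), combines the defined components' one-tailed
#' p-values with the unweighted Z method, and takes the minimum of the
#' defined component p-values as the final association p-value.
#'
#' @param y Adjusted trait: named numeric vector (see [adjust_trait()]).
#'   Names, when present on both sides, are checked against the feature
#'   table's sample IDs.
#' @param features A [two_part_features()] object.
#' @param trait_name Optional label stored in the result.
#' @param min_present Override of the features object's `min_present`.
#' @return Data.frame of class `association_result` with one row per testable
#'   feature: feature_id, trait, n_present, beta1, se1, p_binary, beta2, se2,
#'   p_quant, z_meta, p_meta, p_final, component.  Features with no defined
#'   component are excluded and listed in the `untestable` attribute.
#' @export
associate <- function(y, features, trait_name = NULL,
                      min_present = features$min_present) {
  stopifnot(inherits(features, "two_part_features"))
  if (!is.null(names(y)) && !is.null(rownames(features$B))) {
    if (!identical(names(y), rownames(features$B))) {
      if (!setequal(names(y), rownames(features$B)))
        stop_("sample IDs of y and features do not match")
      y <- y[rownames(features$B)]
    }
  }
  res <- scan_twopart(as.numeric(y), features, min_present)
  untestable <- res$feature_id[is.na(res$p_final)]
  res <- res[!is.na(res$p_final), , drop = FALSE]
  res <- cbind(res[1], trait = trait_name %||% NA_character_,
               res[-1], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "untestable") <- untestable
  class(res) <- c("association_result", "data.frame")
  res
}
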