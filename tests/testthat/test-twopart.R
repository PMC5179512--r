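test_that("feature decomposition satisfies the hurdle invariants", {
  set.seed(5)
  ab <- matrix(rexp(400), 40, 10)
  ab[sample(400, 180)] <- 0
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(sprintf("s%d", 1:40), sprintf("o%d", 1:10))
  ft <- two_part_features(ab)
  expect_identical(unname(ft$B > 0), unname(ab > 0))
  for (j in which(ft$n_present >= 2)) {
    q <- ft$Q[ab[, j] > 0, j]
    expect_equal(mean(q), 0, tolerance = 1e-12)
    expect_equal(sd(q), 1, tolerance = 1e-12)
  }
  expect_true(all(ft$Q[ab == 0] == 0))
})

test_that("binary test matches the closed-form OLS contrast", {
  out <- binary_test(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(out$beta1, 2.0)
  expect_equal(out$t, 2 * sqrt(2), tolerance = 1e-4)
  expect_equal(out$p, 2 * pt(-2 * sqrt(2), 2), tolerance = 1e-10)
  expect_equal(out$p, 0.1056, tolerance = 1e-3)
  # equal group means -> zero effect, p = 1
  eq <- binary_test(c(1, -1, 1, -1), c(1, 1, 0, 0))
  expect_equal(eq$beta1, 0)
  expect_equal(eq$p, 1)
  # constant feature is undefined
  expect_false(binary_test(c(1, 2, 3, 4), c(1, 1, 1, 1))$defined)
})

test_that("quantitative test fits present samples only and matches lm", {
  set.seed(9)
  n <- 30
  abund <- ifelse(rbinom(n, 1, 0.6) == 1, exp(rnorm(n, -4, 1)), 0)
  y <- rnorm(n)
  pres <- abund > 0
  y[pres] <- y[pres] + 0.5 * scale(log(abund[pres]))[, 1]
  out <- quantitative_test(y, abund, min_present = 5)
  fit <- summary(lm(y[pres] ~ scale(log(abund[pres]))))
  expect_equal(out$beta2, unname(fit$coefficients[2, 1]), tolerance = 1e-10)
  expect_equal(out$p, unname(fit$coefficients[2, 4]), tolerance = 1e-10)
  expect_identical(out$n_present, sum(pres))
  # below min_present -> undefined
  expect_false(quantitative_test(y, abund, min_present = n + 1)$defined)
  # constant trait over present samples -> beta2 = 0, p = 1
  cons <- quantitative_test(rep(2, n), abund, min_present = 5)
  expect_equal(cons$beta2, 0)
  expect_equal(cons$p, 1)
})

test_that("one-tailed conversion orients by effect sign", {
  expect_equal(one_tailed(0.10, +1), 0.05)
  expect_equal(one_tailed(0.10, -1), 0.95)
  expect_equal(one_tailed(1, +1), 0.5)
  expect_equal(one_tailed(0.4, 0), 0.5)
})

test_that("unweighted Z meta-combination matches the normal-quantile oracle", {
  out <- meta_combine(c(0.05, 0.05))
  expect_equal(out$z, 2 * qnorm(0.95) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$z, 2.3262, tolerance = 1e-3)
  expect_equal(out$p, 2 * (1 - pnorm(2 * qnorm(0.95) / sqrt(2))),
               tolerance = 1e-12)
  expect_equal(out$p, 0.0200, tolerance = 1e-3)
  # antisymmetric cancellation and the null centre
  expect_equal(meta_combine(c(0.05, 0.95))$z, 0, tolerance = 1e-12)
  expect_equal(meta_combine(c(0.5, 0.5))$p, 1)
  expect_identical(meta_combine(numeric(0))$k, 0L)
})

test_that("meta-combination with one component reduces to its two-sided p", {
  # the negative-direction round trip stores 1 - p/2, whose floating-point
  # granularity near 1 limits recovery of very small p to ~1e-10 relative
  for (p in c(0.5, 0.2, 0.04, 1e-6)) {
    for (s in c(-1, 1)) {
      out <- meta_combine(one_tailed(p, s))
      expect_equal(out$p, p, tolerance = 1e-9)
    }
  }
})

test_that("the vectorized scan agrees with per-feature lm fits", {
  co <- generate_cohort(cohort_config(n_samples = 80, n_otus = 25,
                                      n_causal = 3, seed = 13))
  prep <- prepare_cohort(co, min_present = 8)
  res <- associate(prep$y, prep$features)
  yv <- as.numeric(prep$y)
  for (fid in sample(res$feature_id, 10)) {
    i <- which(res$feature_id == fid)
    b <- prep$ab[, fid] > 0
    if (!is.na(res$beta1[i])) {
      fit <- summary(lm(yv ~ b))
      expect_equal(res$beta1[i], unname(fit$coefficients[2, 1]), tolerance = 1e-9)
      expect_equal(res$p_binary[i], unname(fit$coefficients[2, 4]), tolerance = 1e-9)
    }
    if (!is.na(res$beta2[i])) {
      sc <- quantitative_test(yv, prep$ab[, fid], min_present = 8)
      expect_equal(res$beta2[i], sc$beta2, tolerance = 1e-9)
      expect_equal(res$p_quant[i], sc$p, tolerance = 1e-9)
    }
  }
})

test_that("the final p-value is the minimum defined component and is labelled", {
  co <- generate_cohort(cohort_config(n_samples = 100, n_otus = 40, seed = 17))
  prep <- prepare_cohort(co)
  res <- associate(prep$y, prep$features)
  pmat <- cbind(res$p_binary, res$p_quant, res$p_meta)
  expect_equal(res$p_final,
               apply(pmat, 1, function(r) min(r, na.rm = TRUE)))
  lab <- c("binary", "quantitative", "meta")
  expect_identical(res$component,
                   apply(pmat, 1, function(r) lab[which.min(r)]))
  expect_true(all(res$p_final > 0 & res$p_final <= 1))
})

test_that("a feature present in every sample is tested on its abundance only", {
  set.seed(19)
  ab <- matrix(runif(60, 0.01, 0.2), 30, 2)
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(sprintf("s%d", 1:30), c("full", "alsofull"))
  y <- setNames(rnorm(30), rownames(ab))
  res <- associate(y, two_part_features(ab, min_present = 5))
  expect_true(all(is.na(res$beta1)))
  # meta over k = 1 equals the quantitative two-sided p, so the final
  # p-value is quantitative-derived
  expect_equal(res$p_meta, res$p_quant, tolerance = 1e-10)
  expect_equal(res$p_final, res$p_quant, tolerance = 1e-10)
})

test_that("flipping the trait sign flips effects but not p-values", {
  co <- generate_cohort(cohort_config(n_samples = 90, n_otus = 30,
                                      n_causal = 5, seed = 23))
  prep <- prepare_cohort(co)
  res <- associate(prep$y, prep$features)
  flip <- associate(-prep$y, prep$features)
  expect_equal(flip$beta1, -res$beta1, tolerance = 1e-12)
  expect_equal(flip$beta2, -res$beta2, tolerance = 1e-12)
  expect_equal(flip$z_meta, -res$z_meta, tolerance = 1e-9)
  expect_equal(flip$p_binary, res$p_binary, tolerance = 1e-12)
  expect_equal(flip$p_quant, res$p_quant, tolerance = 1e-12)
  expect_equal(flip$p_final, res$p_final, tolerance = 1e-9)
})

test_that("rejection power increases with the planted abundance effect", {
  # closed-form quantitative test at n = 240, ~60% prevalence; alpha = 1e-4
  # keeps the top of the grid off the power ceiling so the curve is strict
  set.seed(31)
  grid <- c(0, 0.25, 0.5, 1.0)
  rej <- sapply(grid, function(beta) {
    mean(replicate(150, {
      b <- rbinom(240, 1, 0.6)
      if (sum(b) < 10) b[1:10] <- 1
      abund <- ifelse(b == 1, exp(rnorm(240, -5, 1.5)), 0)
      y <- rnorm(240)
      pres <- abund > 0
      y[pres] <- y[pres] + beta * scale(log(abund[pres]))[, 1]
      quantitative_test(y, abund)$p <= 1e-4
    }))
  })
  expect_true(all(diff(rej) > 0))
})

test_that("a strongly planted feature ranks first in most replicate cohorts", {
  top <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      n_samples = 240, n_otus = 40, n_causal = 1,
      prevalence_range = c(0.4, 0.7), abundance_logmean_sd = c(0, 1.2),
      beta1_values = 0.6, beta2_values = 0, seed = 500 + s))
    prep <- prepare_cohort(co)
    res <- associate(prep$y, prep$features)
    res$feature_id[which.min(res$p_final)] == co$truth$otu_id
  }, logical(1))
  expect_gte(mean(top), 0.95)
})
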