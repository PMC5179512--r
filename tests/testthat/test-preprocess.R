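toy_counts <- function(mat, samples = sprintf("s%d", seq_len(nrow(mat))),
                       otus = sprintf("o%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(samples, otus)
  storage.mode(mat) <- "integer"
  mat
}

test_that("rarefaction keeps whole samples at depth and drops shallow ones", {
  m <- toy_counts(rbind(c(12000L, 8000L), c(9000L, 6000L), c(4000L, 2000L)))
  expect_message(out <- rarefy(m, 20000, seed = 1), "dropped")
  # sample 1 has exactly 20,000 reads: subsample = the whole sample
  expect_identical(out["s1", ], m["s1", ])
  expect_identical(attr(out, "dropped"), c("s2", "s3"))
  expect_error(rarefy(m, 0), "depth")
  expect_error(rarefy(toy_counts(rbind(c(10L, 5L))), 100), "fewer")
})

test_that("rarefied row sums equal the depth exactly and never exceed input", {
  set.seed(42)
  m <- toy_counts(matrix(rpois(60, 800), nrow = 6))
  out <- rarefy(m, 5000, seed = 3)
  expect_true(all(rowSums(out) == 5000))
  expect_true(all(out <= m[rownames(out), ]))
  expect_identical(rarefy(m, 5000, seed = 3), out)  # seeded determinism
})

test_that("rarefaction subsampling matches hypergeometric moments", {
  # one sample [A: 6000, B: 4000] at depth 5000: A-count ~ Hypergeom,
  # E = 3000, SD = sqrt(5000 * .6 * .4 * 5000/9999) = 24.5; the mean of 200
  # draws has SD 1.73, so a 99% band is +/- 4.5
  m <- toy_counts(rbind(c(6000L, 4000L)))
  draws <- vapply(1:200, function(s) rarefy(m, 5000, seed = s)[1, 1], numeric(1))
  expect_lt(abs(mean(draws) - 3000), 5)
  expect_true(all(draws + vapply(1:200, function(s)
    rarefy(m, 5000, seed = s)[1, 2], numeric(1)) == 5000))
})

test_that("relative abundance normalizes rows and flags empty samples", {
  m <- toy_counts(rbind(c(10L, 30L), c(20000L, 0L)))
  ab <- to_relative_abundance(m)
  expect_equal(ab["s1", ], c(o1 = 0.25, o2 = 0.75))
  expect_equal(ab["s2", ], c(o1 = 1, o2 = 0))
  expect_equal(unname(rowSums(ab)), c(1, 1))
  bad <- toy_counts(rbind(c(5L, 5L), c(0L, 0L)))
  expect_error(to_relative_abundance(bad), "s2")
})

test_that("OTU filter removes only features failing both conditions", {
  # 200 samples; A: low abundance AND absent; B: abundant and ubiquitous;
  # C: low abundance, present in 0.5% of samples
  n <- 200
  ab <- cbind(A = rep(0, n),
              B = rep(0.002, n),
              C = c(0.09, rep(0, n - 1)))
  ab <- cbind(ab, filler = 1 - rowSums(ab))
  rownames(ab) <- sprintf("s%d", 1:n)
  out <- filter_otus(ab, 0.001, 0.01)
  expect_identical(colnames(out), c("B", "filler"))
  rep_ <- attr(out, "removal_report")
  expect_identical(rep_$otu_id[rep_$removed], c("A", "C"))
  # retained when only one condition fails: 0.05% mean but 50% prevalence
  ab2 <- cbind(D = c(rep(0.001, 100), rep(0, 100)), filler = 1)
  rownames(ab2) <- sprintf("s%d", 1:n)
  expect_true("D" %in% colnames(filter_otus(ab2, 0.001, 0.01)))
  # OR logic removes it
  expect_false("D" %in% colnames(filter_otus(ab2, 0.001, 0.01, logic = "or")))
})

test_that("filtering is idempotent", {
  set.seed(1)
  ab <- matrix(rexp(300), 30, 10)
  ab[sample(300, 150)] <- 0
  ab <- ab / pmax(rowSums(ab), 1e-9)
  dimnames(ab) <- list(sprintf("s%d", 1:30), sprintf("o%d", 1:10))
  once <- filter_otus(ab, 0.02, 0.3)
  twice <- filter_otus(once, 0.02, 0.3)
  expect_identical(colnames(twice), colnames(once))
  expect_equal(unclass(twice), unclass(once)[, colnames(twice)],
               ignore_attr = TRUE)
})

test_that("taxonomic aggregation sums member proportions and preserves rows", {
  ab <- rbind(s1 = c(0.2, 0.3, 0.5), s2 = c(0.6, 0.1, 0.3))
  colnames(ab) <- c("o1", "o2", "o3")
  tax <- data.frame(
    otu_id = c("o1", "o2", "o3"),
    lineage = c("k__Bacteria; p__Firmicutes; c__; o__; f__; g__Prevotella; s__",
                "k__Bacteria; p__Firmicutes; c__; o__; f__; g__Prevotella; s__",
                "k__Bacteria; p__Bacteroidetes; c__; o__; f__; g__Bacteroides; s__"))
  out <- aggregate_to_taxon(ab, tax, "genus")
  expect_identical(sort(colnames(out)), c("Bacteroides", "Prevotella"))
  expect_equal(out[, "Prevotella"], c(s1 = 0.5, s2 = 0.7))
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
  # hand-summed oracle at phylum level
  expect_equal(out[, "Bacteroides"], ab[, "o3"])
  # everything unclassified at species -> single column summing to 1
  sp <- aggregate_to_taxon(ab, tax, "species")
  expect_identical(colnames(sp), "unclassified")
  expect_equal(unname(sp[, 1]), c(1, 1))
  expect_error(aggregate_to_taxon(ab, tax, "kingdom"), "level")
  expect_error(aggregate_to_taxon(ab, tax, "strain"), "level")
})

test_that("trait adjustment returns OLS residuals orthogonal to covariates", {
  set.seed(8)
  n <- 50
  sex <- rbinom(n, 1, 0.5)
  bw <- rnorm(n, 60, 8)
  y <- 2 + 0.5 * sex + 0.03 * bw + rnorm(n, 0, 0.4)
  res <- adjust_trait(y, sex, bw)
  expect_lt(abs(sum(res)), 1e-8 * n * sd(y))
  expect_lt(abs(cor(res, sex)), 1e-10)
  expect_lt(abs(cor(res, bw)), 1e-10)
})

test_that("trait adjustment matches a closed-form normal-equations solve", {
  y <- c(2.1, 3.4, 1.9, 4.2, 2.8, 3.1)
  sex <- c(0, 1, 0, 1, 1, 0)
  bw <- c(55, 61, 48, 72, 66, 50)
  X <- cbind(1, sex, bw)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(adjust_trait(y, sex, bw)), drop(oracle),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("trait adjustment handles perfect fits and degenerate designs", {
  bw <- c(50, 55, 60, 65, 70)
  expect_equal(unname(adjust_trait(2 * bw, rep(0, 5), bw)), rep(0, 5),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_warning(res <- adjust_trait(c(1, 2, 3, 4, 5), rep(1, 5), rep(60, 5)),
                 "degenerate")
  expect_equal(unname(res), c(1, 2, 3, 4, 5) - 3, ignore_attr = TRUE)
  expect_message(
    res2 <- adjust_trait(c(1, 2, NA, 4, 5, 3), c(0, 1, 0, 1, 0, 1),
                         c(50, 60, 55, 58, 52, 61)),
    "dropped 1")
  expect_length(res2, 5)
})
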