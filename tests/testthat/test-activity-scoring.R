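test_that("rank weights reproduce the exponential weight formula", {
  rw <- rankWeights(c(g1 = 5, g2 = 1))
  expect_equal(unname(rw$ranks), c(1, 2))
  expect_equal(unname(rw$weights), c(1 * exp(0.5), 2 * exp(1)),
               tolerance = 1e-6)
  # decreasing-exponent variant
  rwn <- rankWeights(c(g1 = 5, g2 = 1), sign = -1)
  expect_equal(unname(rwn$weights), c(1 * exp(-0.5), 2 * exp(-1)),
               tolerance = 1e-6)
  # rank-based: any strictly monotone transform gives identical weights
  x <- c(a = 0.3, b = -1.2, c = 2.5, d = 0.9)
  expect_equal(rankWeights(x)$weights, rankWeights(exp(x))$weights)
  # ties share average ranks
  expect_equal(unname(rankWeights(c(1, 1, 0))$ranks), c(1.5, 1.5, 3))
  expect_error(rankWeights(5), "2 genes")
  expect_error(rankWeights(c(1, NA)), "finite")
})

test_that("feature activity is the in-set minus out-of-set weight contrast", {
  w <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(as.numeric(featureActivity(w, c("c", "d"))), 3.5 - 1.5)
  # equal weights give zero for any proper subset
  expect_equal(as.numeric(featureActivity(c(a = 2, b = 2, c = 2), "b")), 0)
  # complement identity: sPA(S)*|S| = -sPA(N\S)*|N\S|
  s <- c("a", "c"); comp <- c("b", "d")
  expect_equal(as.numeric(featureActivity(w, s)) * 2,
               -as.numeric(featureActivity(w, comp)) * 2, tolerance = 1e-12)
  # absent genes are dropped and counted
  fa <- featureActivity(w, c("c", "d", "zz"))
  expect_equal(attr(fa, "dropped"), 1L)
  expect_equal(as.numeric(fa), 2)
  expect_error(featureActivity(w, "zz"), "no feature genes")
  expect_error(featureActivity(w, names(w)), "complement")
})

test_that("normalization is a population z-score with a constant-row flag", {
  expect_equal(as.numeric(normalizeActivity(c(1, 3))), c(-1, 1))
  z <- normalizeActivity(rnorm(50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_false(attr(z, "constant"))
  zc <- normalizeActivity(rep(2, 5))
  expect_equal(as.numeric(zc), rep(0, 5))
  expect_true(attr(zc, "constant"))
  expect_error(normalizeActivity(1), "2 samples")
})

test_that("score_matrix equals a hand-computed oracle on a 5x3 toy", {
  m <- matrix(c(2.0, 5.0, 1.0, 4.0, 3.0,
                1.5, 0.5, 2.5, 3.5, 4.5,
                9.0, 7.0, 8.0, 6.0, 5.0), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  fs <- list(FeatureSet("set1", "subpathway", c("g1", "g2")),
             FeatureSet("gene_g3", "gene", "g3"))
  A <- scoreMatrix(m, fs)
  # independent oracle: direct elementwise evaluation of the formulas
  raw_oracle <- sapply(1:3, function(s) {
    r <- rank(-m[, s])
    w <- r * exp(r / 5)
    mean(w[c("g1", "g2")]) - mean(w[c("g3", "g4", "g5")])
  })
  expect_equal(unname(activityRaw(A)["set1", ]), raw_oracle, tolerance = 1e-12)
  z <- (raw_oracle - mean(raw_oracle)) /
    sqrt(mean((raw_oracle - mean(raw_oracle))^2))
  expect_equal(unname(activityNorm(A)["set1", ]), z, tolerance = 1e-12)
  # gene-level activity is the normalized expression row itself
  g3 <- m["g3", ]
  expect_equal(unname(activityRaw(A)["gene_g3", ]), unname(g3))
  expect_equal(unname(activityNorm(A)["gene_g3", ]),
               unname((g3 - mean(g3)) / sqrt(mean((g3 - mean(g3))^2))))
})

test_that("activity matrix structure is invariant to rank-preserving changes", {
  set.seed(3)
  m <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
  fs <- list(FeatureSet("f1", "subpathway", sprintf("g%02d", 1:5)),
             FeatureSet("f2", "subpathway", sprintf("g%02d", 6:12)))
  A <- scoreMatrix(m, fs)
  # per-sample monotone transform leaves the whole matrix unchanged
  A2 <- scoreMatrix(exp(m), fs)
  expect_equal(activityNorm(A), activityNorm(A2))
  # permuting sample order permutes columns only
  perm <- c(3, 1, 2, 6, 5, 4)
  A3 <- scoreMatrix(m[, perm], fs)
  expect_equal(activityNorm(A3), activityNorm(A)[, perm])
  # duplicating a feature duplicates its row
  A4 <- scoreMatrix(m, c(fs, list(FeatureSet("f1b", "subpathway",
                                             sprintf("g%02d", 1:5)))))
  expect_equal(unname(activityNorm(A4)["f1b", ]),
               unname(activityNorm(A4)["f1", ]))
})

test_that("random gene sets have mean raw activity near zero", {
  set.seed(11)
  m <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  w <- rankWeights(m[, 1])$weights
  draws <- replicate(1000, as.numeric(
    featureActivity(w, sample(rownames(m), 15))))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("degenerate scoring inputs are rejected", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(scoreMatrix(m, list(FeatureSet("f", "subpathway",
                                              c("a", "b")))), "universe")
  expect_error(scoreMatrix(m[, 1, drop = FALSE],
                           list(FeatureSet("f", "subpathway", "a"))),
               "2 samples")
})
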