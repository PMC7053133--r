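test_that("combination enumeration matches binomial counts", {
  c7 <- enumerateCombinations(sprintf("d%d", 1:7))
  expect_length(c7, 29L)  # 21 + 7 + 1
  expect_false(anyDuplicated(vapply(c7, paste, character(1),
                                    collapse = ",")) > 0)
  expect_length(enumerateCombinations(c("a", "b", "c"), sizes = 3), 1L)
  expect_length(enumerateCombinations(letters[1:4], sizes = c(2, 3)), 10L)
  expect_error(enumerateCombinations(c("a", "b"), sizes = 3), "exceeds")
})

test_that("ipScore is the mean negative log10 p-value", {
  expect_equal(ipScore(c(0.1, 0.01, 0.001)), 2)
  expect_equal(ipScore(rep(1, 4)), 0)
  expect_equal(ipScore(0.05), 1.30103, tolerance = 1e-5)
  # invariant to cohort ordering within a combination
  p <- c(0.2, 0.004, 0.9, 0.03)
  expect_equal(ipScore(p), ipScore(rev(p)))
  # extreme p-values are clipped, not infinite
  expect_true(is.finite(ipScore(1e-320)))
  expect_error(ipScore(numeric()), "at least one")
  expect_error(ipScore(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(ipScore(1.2), "\\(0, 1\\]")
})

test_that("top-k ranking is score-descending with lexicographic ties", {
  s <- c(f3 = 1.2, f1 = 3.0, f2 = 2.1)
  expect_identical(rankTopK(s, k = 2), c("f1", "f2"))
  # ties broken by id
  t <- c(zeta = 1, alpha = 1, mid = 2)
  expect_identical(rankTopK(t, k = 3), c("mid", "alpha", "zeta"))
  expect_warning(short <- rankTopK(s, k = 5), "returning all")
  expect_length(short, 3L)
})

test_that("serial cumulative sets are the 28 prefixes of sizes 3-30", {
  ranked <- sprintf("f%02d", 1:30)
  sets <- serialSets(ranked)
  expect_length(sets, 28L)
  expect_identical(lengths(sets), setNames(3:30, names(sets)))
  expect_identical(sets[[1]], ranked[1:3])
  expect_identical(sets[[28]], ranked)
  expect_warning(s2 <- serialSets(sprintf("f%02d", 1:10)), "< 30")
  expect_identical(lengths(s2), setNames(3:10, names(s2)))
})

test_that("set assessment on a cohort reduces to the 1-D split for singletons", {
  b <- makeTinyBundle(seed = 31)
  A <- scoreMatrix(b@expression[[1]], b@featureSets)
  surv <- b@survival[[1]]
  one <- assessSetOnCohort(b@plantedId, A, surv)
  a <- setNames(activityNorm(A)[b@plantedId, ], colnames(activityNorm(A)))
  # K-means on one standardized feature is the 1-D split of that feature
  g <- splitTwoGroups(a)
  expect_equal(one$p, logrankTest(g, surv)$p, tolerance = 1e-9)
  # multi-feature assessment returns a valid p and two groups
  multi <- assessSetOnCohort(names(b@featureSets)[1:5], A, surv)
  expect_true(multi$p > 0 && multi$p <= 1)
  expect_setequal(unique(multi$labels), c("high", "low"))
  expect_error(assessSetOnCohort("nope", A, surv), "not in activity")
})

test_that("frequency selection counts top-list membership", {
  lists <- c(replicate(29, c("always", "often"), simplify = FALSE))
  lists[[1]] <- c("always", "rare")
  fr <- frequencySelect(lists, cutoff = 20)
  expect_equal(fr$count[fr$feature == "always"], 29L)
  expect_equal(fr$count[fr$feature == "often"], 28L)
  expect_equal(fr$count[fr$feature == "rare"], 1L)
  expect_identical(fr$feature[fr$selected], c("always", "often"))
  # exclude-self variant counts the other lists only
  fr2 <- frequencySelect(lists, cutoff = 20, exclude_self = TRUE)
  expect_equal(fr2$count[fr2$feature == "always"], 28L)
  expect_error(frequencySelect(list()), "at least one")
})

test_that("hypergeometric relevance enrichment matches exact enumeration", {
  u <- sprintf("g%02d", 1:10)
  res <- relevanceEnrichment(u[1:4], u[1:5], u)
  expect_equal(res$p, 5 / 210, tolerance = 1e-9)
  expect_equal(res$overlap, 4L)
  expect_equal(relevanceEnrichment(character(), u[1:5], u)$p, 1)
  # p always in (0, 1]
  set.seed(2)
  for (i in 1:20) {
    p <- relevanceEnrichment(sample(u, sample(0:10, 1)),
                             sample(u, sample(1:10, 1)), u)$p
    expect_true(p > 0 && p <= 1)
  }
  expect_error(relevanceEnrichment("a", "b", character()), "empty")
})

test_that("shared-gene overlap utility reports intersections", {
  a <- FeatureSet("A", "subpathway", c("g1", "g2", "g3"))
  b <- FeatureSet("B", "pathway", c("g2", "g3", "g4", "g5"))
  ov <- sharedGenes(a, b)
  expect_setequal(ov$genes, c("g2", "g3"))
  expect_equal(ov$fraction_of_b, 0.5)
})

test_that("stronger planted effects never weaken the planted ipScore", {
  for (s in 1:3) {
    scores <- vapply(c(-0.3, -0.8), function(beta) {
      b <- makeTinyBundle(seed = 600 + s, n_cohorts = 3L,
                          samples_per_cohort = 200L,
                          planted_log_hr = beta)
      d <- runDiscovery(b, train_cohorts = names(b@expression),
                        test_cohorts = character(), sizes = c(2L, 3L),
                        top_k = 5L, cutoff = 3L, assess_serial = FALSE)
      mean(d$ipscores[b@plantedId, ])
    }, numeric(1))
    expect_gte(scores[2], scores[1])
  }
})
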