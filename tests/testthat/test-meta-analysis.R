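est3 <- data.frame(study = c("s1", "s2", "s3"),
                   loghr = c(-0.2, -0.3, -0.1), se = rep(0.1, 3))

test_that("fixed-effect pooling matches hand-computed inverse variance", {
  two <- data.frame(study = c("a", "b"), loghr = c(-0.2, -0.2),
                    se = c(0.1, 0.1))
  r <- poolFixed(two)
  expect_equal(r@logHR, -0.2, tolerance = 1e-12)
  expect_equal(r@se, 0.1 / sqrt(2), tolerance = 1e-9)
  r3 <- poolFixed(est3)
  expect_equal(r3@logHR, -0.2, tolerance = 1e-12)
  expect_equal(r3@se, sqrt(1 / 300), tolerance = 1e-9)
  expect_equal(sum(r3@weights), 1)
  # pooled value lies within the range of the study estimates
  set.seed(4)
  for (i in 1:10) {
    e <- data.frame(study = paste0("s", 1:5), loghr = rnorm(5),
                    se = runif(5, 0.05, 0.4))
    p <- poolFixed(e)@logHR
    expect_true(p >= min(e$loghr) && p <= max(e$loghr))
    # order invariance
    expect_equal(poolFixed(e[sample(5), ])@logHR, p)
  }
  expect_error(poolFixed(est3[1, ]), "at least 2")
})

test_that("heterogeneity statistics follow the Q and I2 definitions", {
  same <- data.frame(study = c("a", "b", "c"), loghr = rep(-0.2, 3),
                     se = rep(0.1, 3))
  h0 <- heterogeneity(same)
  expect_equal(h0$Q, 0)
  expect_equal(h0$I2, 0)
  h3 <- heterogeneity(est3)
  expect_equal(h3$Q, 2, tolerance = 1e-9)
  expect_equal(h3$df, 2L)
  expect_equal(h3$I2, 0)  # Q = df gives I2 = 0
  # opposed pair: Q = 200, I2 = (200-1)/200
  pair <- data.frame(study = c("a", "b"), loghr = c(-1, 1), se = c(0.1, 0.1))
  hp <- heterogeneity(pair)
  expect_equal(hp$Q, 200, tolerance = 1e-9)
  expect_equal(hp$I2, 99.5, tolerance = 1e-9)
  # direct check of the I2 formula at Q = 7, df = 2
  expect_equal(max(0, (7 - 2) / 7) * 100, 5 / 7 * 100)
})

test_that("automatic model choice switches on the I2 threshold", {
  rf <- poolAuto(est3)
  expect_identical(rf@model, "fixed")
  pair <- data.frame(study = c("a", "b"), loghr = c(-1, 1), se = c(0.1, 0.1))
  rr <- poolAuto(pair)
  expect_identical(rr@model, "random")
  expect_equal(rr@I2, 99.5, tolerance = 1e-9)
  expect_gte(rr@se, poolFixed(pair)@se)  # tau2 >= 0 widens the SE
  expect_true(rr@ci[1] <= exp(rr@logHR) && exp(rr@logHR) <= rr@ci[2])
})

test_that("pooling agrees with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(17)
  for (i in 1:5) {
    e <- data.frame(study = paste0("s", 1:6),
                    loghr = rnorm(6, -0.3, 0.3), se = runif(6, 0.08, 0.3))
    h <- heterogeneity(e)
    fe <- poolFixed(e)
    mf <- metafor::rma(yi = e$loghr, sei = e$se, method = "FE")
    expect_equal(fe@logHR, as.numeric(mf$beta), tolerance = 1e-8)
    expect_equal(fe@se, mf$se, tolerance = 1e-8)
    expect_equal(h$Q, mf$QE, tolerance = 1e-8)
    md <- metafor::rma(yi = e$loghr, sei = e$se, method = "DL")
    expect_equal(h$tau2, md$tau2, tolerance = 1e-8)
    re <- poolAuto(e, i2_threshold = 0)  # forces the DL random-effects path
    expect_equal(re@logHR, as.numeric(md$beta), tolerance = 1e-8)
    expect_equal(re@se, md$se, tolerance = 1e-8)
  }
})

test_that("leave-one-out analysis localizes an outlier study", {
  homog <- data.frame(study = paste0("s", 1:4), loghr = rep(-0.25, 4),
                      se = rep(0.1, 4))
  lo <- sensitivityLeaveOneOut(homog)
  expect_equal(lo$loghr, rep(-0.25, 4), tolerance = 1e-12)
  out <- data.frame(study = c("s1", "s2", "s3", "odd"),
                    loghr = c(-0.22, -0.2, -0.18, 1.0), se = rep(0.1, 4))
  lo2 <- sensitivityLeaveOneOut(out)
  expect_equal(lo2$omitted[which.min(lo2$I2)], "odd")
  expect_error(sensitivityLeaveOneOut(homog[1:2, ]), "3")
})

test_that("subgroup pooling reports per-subgroup and overall rows", {
  e <- data.frame(study = paste0("s", 1:5),
                  loghr = c(-0.4, -0.4, -0.4, 0.3, 0.3),
                  se = rep(0.1, 5),
                  subgroup = c("microarray", "microarray", "microarray",
                               "rnaseq", "rnaseq"))
  sg <- subgroupPool(e)
  expect_setequal(sg$subgroup, c("microarray", "rnaseq", "overall"))
  expect_equal(sg$I2[sg$subgroup == "microarray"], 0)
  expect_equal(sg$I2[sg$subgroup == "rnaseq"], 0)
  expect_gt(sg$I2[sg$subgroup == "overall"], 0)  # disjoint means disagree
  single <- subgroupPool(e[c(1, 2, 4), ])
  expect_identical(single$flag[single$subgroup == "rnaseq"], "single_study")
})

test_that("funnel data centers pseudo-CI bounds on the pooled value", {
  f <- funnelData(est3)
  expect_equal(f$bounds$lower[1], f$pooled)  # SE = 0 collapses to pooled
  expect_equal(f$bounds$upper[1], f$pooled)
  expect_equal(max(f$bounds$se), max(est3$se))
  expect_equal(min(f$bounds$se), 0)
  expect_equal(nrow(f$studies), 3L)
  # symmetric estimates fall evenly around the pooled value
  sym <- data.frame(study = paste0("s", 1:4),
                    loghr = c(-0.3, -0.1, -0.5, -0.3 + 0.2), se = rep(0.1, 4))
  fs <- funnelData(sym)
  expect_equal(sum(fs$studies$loghr > fs$pooled),
               sum(fs$studies$loghr < fs$pooled))
})

test_that("pooled per-cohort Cox estimates recover the planted log HR", {
  pooled <- vapply(1:3, function(s) {
    est <- do.call(rbind, lapply(1:4, function(ci) {
      b <- makeOneCohort(seed = 900 + 10 * s + ci, n = 400)
      r <- coxUnivariate(plantedActivity(b), b@survival[[1]])
      data.frame(study = paste0("c", ci), loghr = r$coef, se = r$se)
    }))
    poolAuto(est)@logHR
  }, numeric(1))
  expect_lt(abs(mean(pooled) - (-0.5)), 0.1)
})
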