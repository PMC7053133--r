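test_that("invalid configurations name the offending field", {
  expect_error(simulationConfig(censor_rate = 1.2), "censor_rate")
  expect_error(simulationConfig(planted_set_size = 2000), "planted_set_size")
  expect_error(simulationConfig(noise_sd = 0), "noise_sd")
  expect_error(simulationConfig(ic50_rho = -2), "ic50_rho")
  expect_error(simulationConfig(classical_fraction = 1.5),
               "classical_fraction")
})

test_that("identical config and seed give bit-identical bundles", {
  b1 <- makeTinyBundle(seed = 5)
  b2 <- makeTinyBundle(seed = 5)
  expect_identical(assay(b1@expression[[1]], "exprs"),
                   assay(b2@expression[[1]], "exprs"))
  expect_identical(b1@survival, b2@survival)
  expect_identical(b1@drugTable, b2@drugTable)
  expect_identical(b1@responseTable, b2@responseTable)
  b3 <- makeTinyBundle(seed = 6)
  expect_false(identical(assay(b1@expression[[1]], "exprs"),
                         assay(b3@expression[[1]], "exprs")))
  # generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(makeTinyBundle(seed = 5)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("bundle invariants hold: genes present, events binary, times positive", {
  b <- makeTinyBundle(seed = 12)
  expect_true(validObject(b))
  genes <- unique(unlist(lapply(b@featureSets, geneIds)))
  for (ex in b@expression)
    expect_true(all(genes %in% rownames(ex)))
  for (sv in b@survival) {
    expect_true(all(sv$event %in% c(0L, 1L)))
    expect_true(all(sv$time > 0))
  }
  expect_true(all(b@drugTable$ic50 > 0))
  expect_setequal(unique(b@responseTable$response),
                  c("CR", "PR", "SD", "PD"))
  # platform tags follow the config
  b2 <- makeTinyBundle(seed = 12, n_cohorts = 3L, rnaseq_cohorts = 3L)
  expect_identical(platformOf(b2@expression[[3]]), "rnaseq")
  expect_identical(platformOf(b2@expression[[1]]), "microarray")
  counts <- assay(b2@expression[[3]], "exprs")
  expect_true(all(counts == round(counts) & counts >= 0))
})

test_that("planted activity tracks the latent factor", {
  b <- makeTinyBundle(seed = 13, samples_per_cohort = 200L)
  a <- plantedActivity(b)
  rho <- cor(a, b@latentFactors[[1]], method = "spearman")
  # as-printed weights grow with rank, so activity is anti-correlated
  # with member-gene expression; the tracking magnitude is what matters
  expect_gt(abs(rho), 0.5)
})

test_that("a null planted effect yields a null Cox estimate", {
  b <- makeOneCohort(seed = 14, n = 500, planted_log_hr = 0)
  r <- coxUnivariate(plantedActivity(b), b@survival[[1]])
  expect_lt(abs(r$coef), 3 * r$se)
})

test_that("the protective planted effect is detected across replicates", {
  nseed <- 30L
  excl <- 0L
  coefs <- numeric(nseed)
  for (s in seq_len(nseed)) {
    b <- makeOneCohort(seed = 100 + s, n = 500)
    r <- coxUnivariate(plantedActivity(b), b@survival[[1]])
    coefs[s] <- r$coef
    if (r$ci_upper < 1) excl <- excl + 1L
  }
  expect_gte(excl / nseed, 0.9)           # CI excludes HR 1
  expect_lt(abs(mean(coefs) - (-0.5)), 0.1)  # parameter recovery
})

test_that("censoring fraction and IC50 correlation match their targets", {
  b <- makeOneCohort(seed = 15, n = 1000)
  expect_lt(abs(mean(b@survival[[1]]$event == 0) - 0.3), 0.05)
  b0 <- makeOneCohort(seed = 16, n = 200, censor_rate = 0)
  expect_true(all(b0@survival[[1]]$event == 1))
  # ~225 classical cell lines: empirical rho within 0.15 of the target
  bc <- makeTinyBundle(seed = 17, n_cell_lines = 450L,
                       classical_fraction = 0.5)
  d <- bc@drugTable[bc@drugTable$drug == "gemcitabine", ]
  A <- scoreMatrix(bc@cellLineExpression, bc@featureSets[bc@plantedId])
  a <- setNames(activityNorm(A)[1, ], colnames(activityNorm(A)))
  mask <- d$subtype == "classical"
  rho <- cor(a[d$cell_line][mask], log(d$ic50[mask]), method = "spearman")
  expect_lt(abs(rho - (-0.5)), 0.15)
})
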