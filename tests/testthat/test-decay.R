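test_that("mean normalization divides by the GV mean of each age group", {
  x <- make_experiment(rbind(a = c(2, 4, 1, 2)), c("GV", "GV", "MII", "MII"))
  nm <- meanNormalize(x)
  expect_equal(unname(SummarizedExperiment::assay(nm)[1, ]),
               c(2, 4, 1, 2) / 3)

  flat <- make_experiment(rbind(a = rep(7, 4)), c("GV", "GV", "MII", "MII"))
  expect_equal(unname(SummarizedExperiment::assay(meanNormalize(flat))[1, ]),
               rep(1, 4))

  z <- make_experiment(rbind(a = c(0, 0, 1, 1), b = c(1, 1, 1, 1)),
                       c("GV", "GV", "MII", "MII"))
  expect_warning(nz <- meanNormalize(z), "GV mean of 0")
  expect_identical(rownames(nz), "b")
})

test_that("every transcript's GV mean is exactly 1 after normalization", {
  set.seed(8)
  for (rep in 1:5) {
    values <- matrix(rexp(40 * 10, 1 / 50), nrow = 40)
    x <- make_experiment(values, rep(c("GV", "MII"), each = 5))
    nm <- meanNormalize(x)
    gv <- SummarizedExperiment::assay(nm)[, 1:5]
    expect_equal(unname(rowMeans(gv)), rep(1, 40), tolerance = 1e-12)
  }
})

test_that("the decay factor is forced by compositional algebra on a noise-free library", {
  # 100 transcripts; the 10 stable ones hold 50% of the GV mass, everything
  # else fully degrades by MII, so library renormalization exactly doubles
  # the stable transcripts' TPM.
  gv_tpm <- c(rep(5e4, 10), rep(5e5 / 90, 90))
  mii_tpm <- c(rep(1e5, 10), rep(0, 90))
  values <- cbind(gv_tpm, gv_tpm, mii_tpm, mii_tpm)
  x <- make_experiment(values, c("GV", "GV", "MII", "MII"))
  nm <- meanNormalize(x)
  res <- estimateDecayFactor(nm, threshold = 1, minStable = 5L)
  expect_setequal(res$stable_ids, paste0("tx", 1:10))
  expect_equal(res$factor, 2.0, tolerance = 1e-12)
})

test_that("the stable-set rules exclude high-variance and sub-threshold transcripts", {
  # tx1 stable (fold 2, tiny variance); tx2 fold 2 but replicate variance
  # above its fold change; tx3 decaying.
  gv <- rep(1, 3)
  mii1 <- c(2.0, 0.2, 0.1)
  mii2 <- c(2.0, 3.9, 0.1)
  x <- make_experiment(cbind(gv, gv, mii1, mii2), c("GV", "GV", "MII", "MII"))
  nm <- meanNormalize(x)
  res <- estimateDecayFactor(nm, 1, minStable = 1L)
  expect_identical(res$stable_ids, "tx1")

  empty <- estimateDecayFactor(nm, 5, minStable = 1L)
  expect_true(is.na(empty$factor))
  expect_identical(empty$n_stable, 0L)
})

test_that("the variance-trace inflection detector follows the hand rule", {
  # second differences of (0.9, 0.3, 0.28, 0.29) are (0.58, 0.03): the
  # curvature collapses at the third point, i.e. threshold index 3
  expect_identical(oocyteDecay:::.inflection_index(c(0.9, 0.3, 0.28, 0.29)), 3L)
  # an outright sign change is an inflection too
  expect_identical(oocyteDecay:::.inflection_index(c(0.9, 0.4, 0.25, 0.3, 0.2)), 4L)
  # steadily convex traces have none
  expect_true(is.na(oocyteDecay:::.inflection_index(c(1, 0.5, 0.26, 0.18))))
  expect_true(is.na(oocyteDecay:::.inflection_index(c(1, 0.9))))
})

test_that("threshold selection isolates a stable set from decoys", {
  # 30 true stable transcripts (fold ~2) against 70 decoys at fold 1.2;
  # the selected threshold must exclude the decoys and recover factor 2.
  set.seed(301)
  gv <- matrix(1, 100, 2)
  fold <- c(rep(2, 30), rep(1.2, 70))
  mii <- fold * matrix(exp(rnorm(200, 0, 0.01)), 100, 2)
  x <- make_experiment(cbind(gv, mii), c("GV", "GV", "MII", "MII"))
  nm <- meanNormalize(x)
  sel <- suppressWarnings(selectDecayThreshold(nm))
  expect_setequal(sel$result$stable_ids, paste0("tx", 1:30))
  expect_lt(abs(sel$result$factor - 2) / 2, 0.05)
})

test_that("threshold selection falls back when few thresholds are evaluable", {
  # stable folds near 1.6 leave only thresholds 1.0 and 1.5 with a stable
  # set, so the inflection detector cannot run
  set.seed(302)
  gv <- matrix(1, 60, 2)
  fold <- c(rep(1.6, 30), rep(0.1, 30))
  mii <- fold * matrix(exp(rnorm(120, 0, 0.02)), 60, 2)
  x <- make_experiment(cbind(gv, mii), c("GV", "GV", "MII", "MII"))
  nm <- meanNormalize(x)
  expect_warning(sel <- selectDecayThreshold(nm, minStable = 5L),
                 "fewer than 3 evaluable")
  expect_lt(abs(sel$result$factor - 1.6) / 1.6, 0.05)
  expect_identical(sum(!is.na(sel$trace$variance)), 2L)
})

test_that("applying a decay factor rescales MII only", {
  x <- make_experiment(rbind(a = c(1, 1, 2, 2)), c("GV", "GV", "MII", "MII"))
  nm <- meanNormalize(x)
  out <- applyDecayFactor(nm, 2)
  expect_equal(unname(SummarizedExperiment::assay(out)[1, ]), c(1, 1, 1, 1))
  idem <- applyDecayFactor(nm, 1)
  expect_equal(SummarizedExperiment::assay(idem),
               SummarizedExperiment::assay(nm))
})

test_that("the worked two-point decay case gives a 12 h half-life exactly", {
  fit <- fitDecay(c(0, 0, 0, 24, 24, 24), c(1, 1, 1, 0.25, 0.25, 0.25))
  expect_equal(fit$lambda, log(0.25) / 24, tolerance = 1e-12)
  expect_equal(fit$half_life_h, 12, tolerance = 1e-9)
  expect_equal(fit$sigma2, 0)
  expect_lt(fit$p_value, 1e-200)
  expect_gt(fit$p_value, 0)
})

test_that("constant abundance yields a zero slope and no half-life", {
  fit <- fitDecay(c(0, 0, 24, 24), c(3, 3, 3, 3) / 3)
  expect_equal(fit$lambda, 0)
  expect_true(is.na(fit$half_life_h))
  expect_equal(fit$p_value, 1)
  expect_error(fitDecay(c(5, 5, 5), c(1, 2, 3)), "distinct times")
  expect_error(fitDecay(c(0, 24), c(1, 0.5)), "3 observations")
})

test_that("slope, SE and t match the lm() oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    times <- sample(c(0, 6, 12, 24, 48), n, replace = TRUE)
    if (length(unique(times)) < 2) times[1:2] <- c(0, 24)
    values <- exp(rnorm(n, 0, 1))
    fit <- fitDecay(times, values)
    ref <- summary(stats::lm(log(values) ~ times))$coefficients
    expect_equal(fit$lambda, ref["times", "Estimate"], tolerance = 1e-10)
    expect_equal(fit$se_lambda, ref["times", "Std. Error"], tolerance = 1e-10)
    expect_equal(fit$t_stat, ref["times", "t value"], tolerance = 1e-10)
    expect_equal(fit$p_value, ref["times", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("fitAllDecay agrees with per-transcript fitDecay", {
  set.seed(17)
  values <- matrix(rlnorm(30 * 8, 0, 0.3), nrow = 30)
  x <- make_experiment(values, rep(c("GV", "MII"), each = 4))
  nm <- meanNormalize(x)
  all_fits <- fitAllDecay(nm)
  a <- SummarizedExperiment::assay(nm)
  times <- SummarizedExperiment::colData(nm)$time_h
  for (i in c(1, 7, 30)) {
    single <- fitDecay(times, a[i, ])
    expect_equal(all_fits$lambda[i], single$lambda, tolerance = 1e-12)
    expect_equal(all_fits$se_lambda[i], single$se_lambda, tolerance = 1e-12)
    expect_equal(all_fits$p_value[i], single$p_value, tolerance = 1e-12)
  }
  expect_identical(all_fits$decay_fit,
                   all_fits$lambda < 0 & all_fits$p_value < 0.05)
})

test_that("the decay-fit set at alpha = 1 is every negative slope", {
  set.seed(18)
  values <- matrix(rlnorm(20 * 6, 0, 0.5), nrow = 20)
  x <- make_experiment(values, rep(c("GV", "MII"), each = 3))
  fits <- fitAllDecay(meanNormalize(x), alpha = 1)
  expect_identical(fits$decay_fit, fits$lambda < 0)
})

test_that("the aging standard score follows Z = (lY - lA) / (SEy + SEa)", {
  fy <- make_fits("t1", -0.10, 0.01)
  fa <- make_fits("t1", -0.05, 0.015, age_group = "aged")
  comp <- compareAges(fy, fa)
  expect_equal(comp$z, -2.0, tolerance = 1e-12)
  expect_equal(comp$p_value, 2 * pnorm(-2), tolerance = 1e-12)

  # equal slopes: z = 0, Bonferroni p = 1
  same <- compareAges(make_fits("t1", -0.1, 0.01),
                      make_fits("t1", -0.1, 0.02, age_group = "aged"))
  expect_equal(same$z, 0)
  expect_equal(same$p_bonf, 1)

  quad <- compareAges(fy, fa, zDenominator = "quadrature")
  expect_equal(quad$z, -0.05 / sqrt(0.01^2 + 0.015^2), tolerance = 1e-12)
})

test_that("swapping young and aged flips the standard score exactly", {
  set.seed(4)
  ids <- paste0("t", 1:50)
  fy <- make_fits(ids, -runif(50, 0.02, 0.2), runif(50, 0.005, 0.02))
  fa <- make_fits(ids, -runif(50, 0.02, 0.2), runif(50, 0.005, 0.02), "aged")
  ab <- compareAges(fy, fa)
  ba <- compareAges(fa, fy)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  # Bonferroni monotonicity
  expect_true(all(ab$p_bonf >= ab$p_value))
  expect_true(all(ab$p_bonf <= 1))
})

test_that("change classification partitions by the 1-h rule", {
  comp <- make_comparisons(c(9.0, 9.1, 9.9), c(9.5, 8.0, 11.2))
  expect_identical(as.character(comp$category),
                   c("unchanged", "shorter_in_aged", "longer_in_aged"))

  # without significance, every compared transcript lands in one category
  set.seed(5)
  many <- make_comparisons(runif(200, 2, 20), runif(200, 2, 20))
  expect_false(anyNA(many$category))

  # with the significance requirement, non-significant changes are demoted
  ns <- classifyChange(make_comparisons(9.1, 8.0, significant = FALSE),
                       requireSignificance = TRUE)
  expect_identical(as.character(ns$category), "unchanged")
})
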