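test_that("regression metrics match hand-computed oracles", {
  ref <- c(120, 130, 110)
  m <- regression_metrics(ref, ref)
  expect_equal(unlist(m), c(r2 = 1, rmse = 0, mae = 0, me = 0, sd = 0))

  est <- c(122, 128, 111) # errors (2, -2, 1)
  m2 <- regression_metrics(est, ref)
  expect_equal(m2$me, 1 / 3)
  expect_equal(m2$mae, 5 / 3)
  expect_equal(m2$rmse, sqrt(3))
  expect_equal(m2$sd, sqrt(13 / 3)) # ((2-1/3)^2+(-2-1/3)^2+(1-1/3)^2)/2
  expect_equal(m2$r2, 1 - 9 / 200) # SS_tot around mean 120 is 200

  m3 <- regression_metrics(ref + 5, ref)
  expect_equal(m3$me, 5)
  expect_equal(m3$sd, 0)
  expect_equal(m3$mae, 5)
  expect_equal(m3$rmse, 5)
  expect_equal(m3$r2, 1 - 75 / 200)

  expect_true(is.na(regression_metrics(c(1, 2), c(5, 5))$r2))
  expect_error(regression_metrics(1, 1), class = "ppgbp_input_error")
})

test_that("RMSE dominates MAE and the error-variance decomposition holds", {
  withr::with_seed(31, {
    for (trial in 1:25) {
      n <- sample(3:50, 1)
      ref <- runif(n, 80, 180)
      est <- ref + rnorm(n, sd = runif(1, 0.1, 10)) + runif(1, -5, 5)
      m <- regression_metrics(est, ref)
      expect_gte(m$rmse, m$mae)
      expect_lt(abs(m$rmse^2 - (m$me^2 + (n - 1) / n * m$sd^2)), 1e-9)
    }
  })
})

test_that("bootstrap intervals are seeded, degenerate on constant errors, and CLT-calibrated", {
  ref <- rep(100, 10)
  est <- ref + 3 # all errors equal 3
  ci <- bootstrap_ci(function(e, r) mean(e - r), est, ref, seed = 1)
  expect_equal(unname(ci), c(3, 3))

  withr::with_seed(7, {
    ref2 <- runif(200, 90, 180)
    est2 <- ref2 + rnorm(200)
  })
  c1 <- bootstrap_ci(function(e, r) mean(e - r), est2, ref2, seed = 5)
  c2 <- bootstrap_ci(function(e, r) mean(e - r), est2, ref2, seed = 5)
  expect_identical(c1, c2)
  width <- c1[["hi"]] - c1[["lo"]]
  expect_lt(abs(width - 2 * 1.96 / sqrt(200)), 0.25 * 2 * 1.96 / sqrt(200))
})

test_that("the bootstrap interval for the mean error contains the point estimate", {
  withr::with_seed(13, {
    for (trial in 1:100) {
      n <- sample(10:40, 1)
      ref <- runif(n, 80, 180)
      est <- ref + rnorm(n, sd = 3)
      point <- mean(est - ref)
      ci <- bootstrap_ci(function(e, r) mean(e - r), est, ref,
                         n_boot = 200, seed = trial)
      expect_lte(ci[["lo"]], point)
      expect_gte(ci[["hi"]], point)
    }
  })
})

test_that("Bland-Altman bias and limits of agreement match closed forms", {
  ref <- c(100, 110)
  ba0 <- bland_altman(ref, ref, n_boot = 50, seed = 1)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  est <- c(99, 111) # d = (-1, 1)
  ba <- bland_altman(est, ref, n_boot = 50, seed = 1)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))

  withr::with_seed(3, {
    ref2 <- runif(40, 80, 180)
    est2 <- ref2 + rnorm(40, 1, 4)
  })
  ba2 <- bland_altman(est2, ref2, n_boot = 50, seed = 2)
  expect_equal(ba2$loa_high - ba2$loa_low, 2 * 1.96 * sd(est2 - ref2))
  expect_lte(ba2$loa_low, ba2$bias)
  expect_gte(ba2$loa_high, ba2$bias)
})

test_that("cumulative error percentages count inclusively and monotonically", {
  ref <- rep(100, 4)
  expect_equal(unname(cumulative_within(ref, ref)), c(100, 100, 100))
  est <- ref + c(3, 7, 12, 20)
  expect_equal(unname(cumulative_within(est, ref)), c(25, 50, 75))
  expect_equal(unname(cumulative_within(est, ref, thresholds = Inf)), 100)
  # inclusive boundary
  expect_equal(unname(cumulative_within(100 + 5, 100, thresholds = 5)), 100)
  withr::with_seed(17, {
    est2 <- 100 + rnorm(50, sd = 8)
    pct <- cumulative_within(est2, rep(100, 50))
    expect_true(all(diff(pct) >= 0))
  })
})

test_that("BHS grading enforces all thresholds of a grade and is monotone", {
  expect_identical(bhs_grade(c(91.08, 99.34, 99.95)), "A")
  expect_identical(bhs_grade(c(71.57, 83.92, 90.77)), "B") # 83.92 < 85 denies A
  expect_identical(bhs_grade(c(100, 100, 100)), "A")
  expect_identical(bhs_grade(c(60, 85, 95)), "A") # inclusive boundaries
  expect_identical(bhs_grade(c(59.99, 85, 95)), "B")
  expect_identical(bhs_grade(c(50, 75, 90)), "B")
  expect_identical(bhs_grade(c(40, 65, 85)), "C")
  expect_identical(bhs_grade(c(39, 65, 85)), "D")

  grade_rank <- function(g) match(g, c("D", "C", "B", "A"))
  withr::with_seed(23, {
    for (trial in 1:50) {
      p <- sort(runif(3, 0, 100))
      bump <- pmin(p + c(runif(1, 0, 20), 0, 0)[sample(3)], 100)
      bump <- sort(pmax(bump, p))
      expect_gte(grade_rank(bhs_grade(bump)), grade_rank(bhs_grade(p)))
    }
  })
})

test_that("AAMI verdicts use inclusive thresholds on |ME| and SD", {
  expect_true(aami_check(-0.01, 2.80)$passes)
  expect_true(aami_check(0, 0)$passes)
  expect_true(aami_check(5, 8)$passes)
  expect_false(aami_check(6, 2)$passes)
  expect_false(aami_check(-5.01, 2)$passes)
  expect_false(aami_check(0, 8.01)$passes)
})

test_that("percent improvement handles both orientations and degenerate inputs", {
  expect_equal(percent_improvement(0.38, 0.96, "higher_better"), 100 * 0.58 / 0.38)
  expect_equal(percent_improvement(10.78, 2.80, "lower_better"), 100 * 7.98 / 10.78)
  expect_equal(percent_improvement(4, 4, "higher_better"), 0)
  expect_equal(percent_improvement(4, 4, "lower_better"), 0)
  expect_warning(out <- percent_improvement(0, 1), "zero baseline")
  expect_true(is.na(out))
})

test_that("the full report assembles metrics, agreement, BHS and AAMI consistently", {
  withr::with_seed(41, {
    n <- 60
    preds <- tibble::tibble(
      sbp = runif(n, 90, 180), dbp = runif(n, 55, 110)
    )
    preds$sbp_hat <- preds$sbp + rnorm(n, 0, 2)
    preds$dbp_hat <- preds$dbp + rnorm(n, 0, 1.5)
  })
  rep <- evaluate_report(preds, n_boot = 100, seed = 3)
  g <- glance(rep)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$aami_pass))
  expect_true(all(g$bhs_grade %in% c("A", "B")))
  td <- tidy(rep)
  expect_true(all(td$lo <= td$value + 1e-9 | td$metric %in% c("rmse", "mae", "sd")))

  # perfect predictions
  perfect <- tibble::tibble(sbp = preds$sbp, dbp = preds$dbp,
                            sbp_hat = preds$sbp, dbp_hat = preds$dbp)
  rp <- evaluate_report(perfect, n_boot = 50, seed = 1)
  gp <- glance(rp)
  expect_equal(gp$rmse, c(0, 0))
  expect_equal(gp$r2, c(1, 1))
  expect_identical(gp$bhs_grade, c("A", "A"))
  expect_true(all(gp$aami_pass))

  # JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- read_report_json(path)
  expect_equal(glance(back), glance(rep), tolerance = 1e-12)
  expect_equal(tidy(back), tidy(rep), tolerance = 1e-12)

  expect_error(evaluate_report(preds[1, ]), class = "ppgbp_input_error")
})

test_that("report plots build without error", {
  withr::with_seed(2, {
    preds <- tibble::tibble(sbp = runif(30, 90, 180), dbp = runif(30, 55, 110))
    preds$sbp_hat <- preds$sbp + rnorm(30, 0, 3)
    preds$dbp_hat <- preds$dbp + rnorm(30, 0, 2)
  })
  rep <- evaluate_report(preds, n_boot = 50, seed = 1)
  p <- autoplot(rep, "sbp")
  expect_s3_class(p, "ggplot")
})
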