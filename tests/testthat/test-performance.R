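test_that("brier score, R2 and O/E match hand arithmetic", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c(1, 0)), 0.065)
  expect_error(brier_score(numeric(0), numeric(0)), "non-empty")

  expect_equal(cox_snell_r2(-100, -100, 50), 0)
  expect_equal(cox_snell_r2(-90, -100, 100), 1 - exp(-0.2), tolerance = 1e-12)
  expect_equal(nagelkerke_r2(-90, -100, 100),
               (1 - exp(-0.2)) / (1 - exp(-2)), tolerance = 1e-12)
  expect_lt(cox_snell_r2(-105, -100, 100), 0)  # worse-than-null allowed

  expect_equal(oe_ratio(c(0.4, 0.6), c(1, 0)), 1.0)
  expect_equal(oe_ratio(rep(0.2, 100), c(rep(1, 10), rep(0, 90))), 0.5)
  expect_error(oe_ratio(rep(0, 5), rep(0, 5)), "zero")
})

test_that("calibration intercept/slope behave under shift and scale", {
  set.seed(81)
  n <- 20000
  lp <- rnorm(n, -2, 1)
  y <- rbinom(n, 1, plogis(lp))
  expect_equal(calibration_in_the_large(lp, y), 0, tolerance = 0.06)
  expect_equal(calibration_slope(lp, y), 1, tolerance = 0.06)
  # shifting the lp down by c moves the intercept up by ~c
  expect_equal(calibration_in_the_large(lp - 0.7, y), 0.7, tolerance = 0.08)
  # doubling the lp halves the slope
  expect_equal(calibration_slope(2 * lp, y), 0.5, tolerance = 0.04)
  # overconfident (overdispersed) predictions give slope < 1
  expect_lt(calibration_slope(2.5 * lp + 1, y), 1)
  expect_error(calibration_in_the_large(rep(0.3, 10), rep(1, 10)),
               "degenerate")
  expect_error(calibration_slope(rep(1, 100), rbinom(100, 1, 0.5)),
               "constant")
})

test_that("ICI tracks a constant miscalibration shift", {
  set.seed(82)
  n <- 8000
  p <- runif(n, 0.05, 0.6)
  y <- rbinom(n, 1, p)
  expect_lt(ici(p, y), 0.02)                       # well calibrated
  p_shift <- pmin(pmax(p + 0.05, 0), 1)
  expect_lt(abs(ici(p_shift, y) - 0.05), 0.015)
  expect_lt(ici(rep(mean(y), n) + rnorm(n, 0, 1e-6), y), 0.01)
  expect_error(ici(runif(10), rbinom(10, 1, 0.5)), "n >= 20")
})

test_that("c_statistic equals brute-force pair counting", {
  expect_equal(c_statistic(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(c_statistic(rep(0.3, 10), c(1, 0, 0, 1, 0, 1, 0, 0, 1, 0)),
               0.5)
  set.seed(83)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    p <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(p, y), oracle_c_statistic(p, y),
                 tolerance = 1e-12)
  }
  expect_error(c_statistic(runif(5), rep(1, 5)), "classes")
})

test_that("bootstrap_metrics is deterministic, stable and consistent", {
  gen <- generate_cohort(table3_defaults(n = 600L), seed = 14)
  model <- motwani_anchor_model()
  r1 <- bootstrap_metrics(gen$cohort, model, bootstrap_config(200, seed = 1))
  r2 <- bootstrap_metrics(gen$cohort, model, bootstrap_config(200, seed = 1))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$metric,
                  c("r2_cox_snell", "r2_nagelkerke", "brier",
                    "calibration_in_the_large", "calibration_slope",
                    "oe_ratio", "ici", "c_statistic"))
  expect_true(all(r1$ci_low <= r1$ci_high))
  # bootstrap consistency for the Brier score: boot mean near point estimate
  brier_row <- r1[r1$metric == "brier", ]
  expect_equal(brier_row$boot_mean, brier_row$point, tolerance = 0.01)
  # seed stability: two seeds give similar CIs
  r3 <- bootstrap_metrics(gen$cohort, model, bootstrap_config(200, seed = 2))
  w1 <- r1$ci_high - r1$ci_low
  w3 <- r3$ci_high - r3$ci_low
  expect_true(all(abs(w1 - w3) < pmax(0.35 * w1, 0.02)))
})

test_that("fixed-coefficient evaluation reproduces the published failure modes", {
  # a cohort whose true risk is flatter and lower than the anchored model
  # predicts: O/E < 1 (overestimation) and slope < 1, CS R2 can go negative
  gen <- generate_cohort(table3_defaults(
    n = 4000L,
    true_params = true_outcome_params(intercept = log(0.05),
                                      beta_score = log(1.12))), seed = 15)
  perf <- bootstrap_metrics(gen$cohort, motwani_anchor_model(),
                            bootstrap_config(50, seed = 1))
  expect_lt(perf[perf$metric == "oe_ratio", "point"], 1)
  expect_lt(perf[perf$metric == "calibration_slope", "point"], 1)
})

test_that("optimism vanishes in expectation for a data-ignoring builder", {
  # a fixed model has zero expected optimism: per replicate the difference
  # C(boot) - C(original) is pure resampling noise with mean zero
  gen <- generate_cohort(table3_defaults(n = 1200L), seed = 16)
  fixed_builder <- function(cohort) {
    function(newcohort) predict_cohort(motwani_anchor_model(), newcohort)
  }
  res <- optimism_corrected_c(gen$cohort, fixed_builder,
                              bootstrap_config(400, seed = 1))
  expect_lt(abs(res$mean_optimism), 0.01)
  expect_equal(res$corrected_c, res$apparent_c - res$mean_optimism)
})

test_that("optimism grows when the model overfits small noisy designs", {
  overfit_builder <- function(cohort) {
    y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
    X <- cbind(score = cohort_score(cohort, 0),
               as.matrix(sapply(drug_flags()[1:6], function(fl)
                 as.numeric(cohort[[fl]]) + rnorm(nrow(cohort), 0, 0.01))))
    fit <- tryCatch(fit_logistic(X, y), error = function(e) NULL)
    if (is.null(fit)) stop("builder failed")
    co <- fit$coefficients
    function(newcohort) {
      Xn <- cbind(1, score = cohort_score(newcohort, 0),
                  as.matrix(sapply(drug_flags()[1:6], function(fl)
                    as.numeric(newcohort[[fl]]) +
                      rnorm(nrow(newcohort), 0, 0.01))))
      plogis(as.vector(Xn %*% co))
    }
  }
  big <- generate_cohort(table3_defaults(n = 1785L), seed = 17)$cohort
  small <- big[1:150, ]
  res_small <- optimism_corrected_c(small, overfit_builder,
                                    bootstrap_config(60, seed = 2))
  res_big <- optimism_corrected_c(big, build_updated_model,
                                  bootstrap_config(60, seed = 2))
  expect_gt(res_small$mean_optimism, res_big$mean_optimism)
})
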