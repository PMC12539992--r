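test_that("fit_logistic matches closed forms, glm and a grid oracle", {
  set.seed(71)
  y <- rbinom(50, 1, 0.3)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  f0 <- fit_logistic(NULL, y)
  expect_equal(unique(round(f0$fitted, 10)), round(mean(y), 10))
  expect_equal(unname(f0$coefficients), qlogis(mean(y)), tolerance = 1e-6)

  x <- rnorm(20)
  yb <- rbinom(20, 1, plogis(0.5 * x))
  if (length(unique(yb)) < 2) yb[1] <- 1 - yb[1]
  fit <- fit_logistic(cbind(x = x), yb)
  gr <- oracle_grid_logistic(x, yb)
  expect_equal(unname(fit$coefficients), gr, tolerance = 1e-4)
  gl <- glm(yb ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(gl)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(gl)), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(gl), tolerance = 1e-6)

  expect_error(fit_logistic(cbind(x = x), rep(1, 20)), "degenerate")
  expect_error(fit_logistic(cbind(a = x, b = 2 * x), yb), "rank deficient")
  xs <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(cbind(x = xs), xs), "separation")
})

test_that("fit_logistic log-likelihood trace is monotone non-decreasing", {
  set.seed(72)
  for (i in 1:10) {
    n <- 60
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- rbinom(n, 1, plogis(X %*% c(1, -2)))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(X, y)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    expect_true(fit$converged)
  }
})

test_that("nested-model AIC arithmetic identity holds", {
  set.seed(73)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x1))
  small <- fit_logistic(cbind(x1 = x1), y)
  big <- fit_logistic(cbind(x1 = x1, x2 = x2), y)
  gain <- big$loglik - small$loglik
  expect_gte(gain, -1e-8)  # larger nested model never fits worse
  expect_equal(big$aic, small$aic + 2 - 2 * gain, tolerance = 1e-8)
})

test_that("recalibrate_extend reduces to pure recalibration and catches collinearity", {
  gen <- generate_cohort(table3_defaults(n = 1500L), seed = 5)
  co <- gen$cohort
  y <- classify_aki(co$scr_baseline, co$scr_followup_max14d)$aki
  s <- cohort_score(co, 0)
  pure <- recalibrate_extend(s, NULL, y)
  expect_equal(names(pure$coefficients), c("(Intercept)", "score"))
  expect_error(recalibrate_extend(s, cbind(dup = s), y), "rank deficient")
  ext <- recalibrate_extend(s, cbind(no_mg = as.numeric(!co$mg_supplement)), y)
  expect_equal(names(ext$coefficients), c("(Intercept)", "score", "no_mg"))
})

test_that("delta AIC rule and score-point assignment follow the stated arithmetic", {
  expect_true(delta_aic_significant(1240.5, 1175.3))   # published Mg row
  expect_false(delta_aic_significant(1240.5, 1235.1))  # published S-1 row
  expect_false(delta_aic_significant(1000, 1000))

  a <- assign_score_points(3.91, 1.29)
  expect_equal(a$raw_ratio, 3.91 / 1.29, tolerance = 1e-12)
  expect_equal(a$points, 3.0)
  expect_equal(assign_score_points(1.29, 1.29)$points, 1.0)
  expect_equal(assign_score_points(2.0, 1.3)$points, 1.5)
  # tie exactly between grid points rounds away from zero
  expect_equal(assign_score_points(1.25, 1)$points, 1.5)
  expect_error(assign_score_points(-1, 1.3), "positive")
  # grid and monotonicity property
  ors <- seq(0.2, 8, by = 0.13)
  pts <- vapply(ors, function(o) assign_score_points(o, 1.29)$points, 0)
  expect_true(all(pts * 2 == round(pts * 2)))
  expect_true(all(diff(pts) >= 0))
})

test_that("candidate_scan includes the base row and flags degenerate candidates", {
  gen <- generate_cohort(table3_defaults(n = 1200L), seed = 8)
  co <- gen$cohort
  base_only <- candidate_scan(co, candidates = character(0))
  expect_equal(base_only$candidate, "None")
  scan <- candidate_scan(co, candidates = c("no_mg", "gem", "sh"))
  expect_setequal(scan$candidate, c("None", "no_mg", "gem", "sh"))
  expect_true(all(diff(scan$aic[!is.na(scan$aic)]) >= 0))  # sorted
  # a zero-variance candidate is flagged, not fitted
  co2 <- co
  co2$cpi <- rep(FALSE, nrow(co2))
  scan2 <- candidate_scan(co2, candidates = "cpi")
  expect_false(scan2[scan2$candidate == "cpi", "fitted"])
  expect_error(candidate_scan(co, candidates = "bogus"), "unknown candidate")
})

test_that("null candidates rarely move the AIC by more than chance", {
  # a candidate independent of outcome should give delta_aic <= 2 typically
  deltas <- vapply(1:10, function(s) {
    gen <- generate_cohort(table3_defaults(n = 3000L), seed = 300 + s)
    co <- gen$cohort
    scan <- candidate_scan(co, candidates = "dxr")  # dxr has no true effect
    scan[scan$candidate == "dxr", "delta_aic"]
  }, 0)
  expect_true(mean(deltas <= 2) >= 0.8)
  expect_true(all(deltas <= 10))
})

test_that("vif matches a least-squares oracle and flags collinearity", {
  set.seed(74)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- vif(X)
  # oracle: direct R^2 via lm for each column
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_true(all(v >= 1))
  # mutually orthogonal, mean-centred predictors give VIF 1
  Xo <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  colnames(Xo) <- c("a", "b", "c")
  expect_equal(unname(vif(Xo)), rep(1, 3), tolerance = 1e-8)
  # near-collinearity flagged large; exact collinearity infinite
  Xc <- cbind(a = X[, 1], b = X[, 1] + rnorm(n, sd = 1e-4))
  expect_true(all(vif(Xc) > 3))
  Xe <- cbind(a = X[, 1], b = 2 * X[, 1])
  expect_true(any(is.infinite(vif(Xe))))
})

test_that("updating a generated cohort keeps VIF below 3", {
  gen <- generate_cohort(table3_defaults(n = 2000L), seed = 12)
  co <- gen$cohort
  v <- vif(cbind(score = cohort_score(co, 0),
                 no_mg = as.numeric(!co$mg_supplement),
                 gem = as.numeric(co$gem)))
  expect_true(all(v < 3))
})
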