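test_that("reclassification tables conserve counts and diagonalise on identity", {
  set.seed(91)
  n <- 500
  p_old <- runif(n, 0, 0.4)
  p_new <- pmin(pmax(p_old + rnorm(n, 0, 0.05), 0), 1)
  y <- rbinom(n, 1, p_old)
  t_id <- reclassification_table(p_old, p_old, y)
  expect_true(all(t_id$events[upper.tri(t_id$events)] == 0))
  expect_true(all(t_id$events[lower.tri(t_id$events)] == 0))
  t2 <- reclassification_table(p_old, p_new, y)
  expect_equal(sum(t2$events), sum(y))
  expect_equal(sum(t2$nonevents), sum(1 - y))
  # constructed band pairs give exact cells
  t3 <- reclassification_table(c(0.05, 0.15, 0.25, 0.05),
                               c(0.15, 0.05, 0.25, 0.05),
                               c(1, 0, 1, 0))
  expect_equal(t3$events["low", "intermediate"], 1)
  expect_equal(t3$events["high", "high"], 1)
  expect_equal(t3$nonevents["intermediate", "low"], 1)
  expect_equal(t3$nonevents["low", "low"], 1)
})

test_that("NRI from the published tables equals 0.143 and obeys the formula", {
  res <- nri_from_table(published_reclassification())
  expect_equal(res$up_events, 46)
  expect_equal(res$down_events, 55)
  expect_equal(res$down_nonevents, 432)
  expect_equal(res$up_nonevents, 137)
  expect_equal(res$nri_events, -9 / 205, tolerance = 1e-12)
  expect_equal(res$nri_nonevents, 295 / 1580, tolerance = 1e-12)
  expect_equal(round(res$nri, 3), 0.143)
  expect_equal(res$nri, res$nri_events + res$nri_nonevents)

  # diagonal tables give 0
  d <- new_reclass_table(diag(c(5, 5, 5)), diag(c(9, 9, 9)))
  expect_equal(nri_from_table(d)$nri, 0)
  # all events up one category, non-events unchanged -> 1
  up1 <- matrix(0, 3, 3); up1[1, 2] <- 7; up1[2, 3] <- 3
  full <- nri_from_table(new_reclass_table(up1, diag(c(4, 4, 4))))
  expect_equal(full$nri, 1.0)
})

test_that("table NRI equals per-patient counting (round trip)", {
  set.seed(92)
  for (i in 1:10) {
    n <- 300
    p_old <- runif(n, 0, 0.5)
    p_new <- pmin(pmax(p_old + rnorm(n, 0, 0.08), 0), 1)
    y <- rbinom(n, 1, 0.15)
    if (length(unique(y)) < 2) next
    t <- reclassification_table(p_old, p_new, y)
    expect_equal(nri_from_table(t)$nri, oracle_nri(p_old, p_new, y),
                 tolerance = 1e-12)
  }
})

test_that("IDI matches hand arithmetic and is antisymmetric", {
  expect_equal(idi(c(0.1, 0.2), c(0.2, 0.1), c(1, 0)), 0.2)
  set.seed(93)
  p1 <- runif(50); p2 <- runif(50); y <- rbinom(50, 1, 0.4)
  expect_equal(idi(p1, p1, y), 0)
  expect_equal(idi(p1, p2, y), -idi(p2, p1, y), tolerance = 1e-12)
  expect_error(idi(p1, p2, rep(1, 50)), "classes")
})

test_that("NRI/IDI bootstrap CIs contain the point estimates", {
  gen <- generate_cohort(table3_defaults(n = 800L), seed = 18)
  co <- gen$cohort
  y <- classify_aki(co$scr_baseline, co$scr_followup_max14d)$aki
  p_old <- predict_cohort(motwani_anchor_model(), co)
  p_new <- build_updated_model(co)(co)
  res <- nri_idi_bootstrap(p_old, p_new, y,
                           config = bootstrap_config(200, seed = 4))
  expect_true(res$nri$ci_low <= res$nri$point &&
                res$nri$point <= res$nri$ci_high)
  expect_true(res$idi$ci_low <= res$idi$point &&
                res$idi$point <= res$idi$ci_high)
})

test_that("net benefit matches hand arithmetic and reference curves", {
  # treat-all at prevalence 0.115 and pt = 0.10
  y <- c(rep(1, 115), rep(0, 885))
  expect_equal(net_benefit(rep(1, 1000), y, 0.10),
               0.115 - 0.885 * (1 / 9), tolerance = 1e-12)
  # treat-none
  expect_equal(net_benefit(rep(0, 1000), y, 0.3), 0)
  # perfect predictions: NB = prevalence when no false positives
  p_perf <- ifelse(y == 1, 0.9, 0.01)
  expect_equal(net_benefit(p_perf, y, 0.5), 0.115)
  # treat-all crosses zero exactly at pt = prevalence
  expect_equal(net_benefit(rep(1, 1000), y, 0.115), 0, tolerance = 1e-12)
  expect_error(net_benefit(rep(0.5, 3), c(1, 0, 1), 1), "pt")
})

test_that("decision_curve produces tidy curves with reference behaviour", {
  set.seed(94)
  n <- 400
  p <- runif(n, 0, 0.5)
  y <- rbinom(n, 1, p)
  dc <- decision_curve(list(model = p), y, grid = seq(0.05, 0.6, by = 0.05))
  expect_named(dc, c("threshold", "nb_model", "nb_treat_all",
                     "nb_treat_none"))
  expect_true(all(dc$nb_treat_none == 0))
  # no events: treat-all is negative everywhere
  dc0 <- decision_curve(list(m = runif(50)), rep(0, 50),
                        grid = c(0.1, 0.3, 0.5))
  expect_true(all(dc0$nb_treat_all < 0))
  # the outcome indicator itself dominates both references
  dcp <- decision_curve(list(oracle = as.numeric(y)), y,
                        grid = seq(0.05, 0.95, by = 0.1))
  expect_true(all(dcp$nb_oracle >= dcp$nb_treat_all - 1e-12))
  expect_true(all(dcp$nb_oracle >= 0))
})

test_that("the true model stochastically dominates a misspecified one", {
  gen <- generate_cohort(table3_defaults(n = 20000L), seed = 19)
  co <- gen$cohort
  y <- classify_aki(co$scr_baseline, co$scr_followup_max14d)$aki
  p_true <- gen$true_p
  # misspecified: ignores magnesium and flattens the score effect
  p_mis <- plogis(log(0.08) + 0.5 * log(1.29) * cohort_score(co, 0))
  grid <- seq(0.02, 0.45, by = 0.01)
  dc <- decision_curve(list(true = p_true, mis = p_mis), y, grid)
  expect_gte(mean(dc$nb_true >= dc$nb_mis - 1e-12), 0.9)
})
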