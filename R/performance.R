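# Calibration/discrimination metric battery, bootstrap CIs and the
# optimism-corrected C-statistic.

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1 outcome.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary outcomes.
#' @return Value in `[0, 1]`.
#' @export
brier_score <- function(p, y) {
  y <- as.numeric(y)
  if (length(p) == 0 || length(p) != length(y))
    stop("invalid input: p and y must be non-empty and of equal length",
         call. = FALSE)
  if (any(p < 0 | p > 1)) stop("invalid input: p outside [0, 1]", call. = FALSE)
  mean((p - y)^2)
}

#' Cox-Snell and Nagelkerke pseudo-R-squared
#'
#' `CS = 1 - exp(-2 (ll_model - ll_null) / n)`;
#' `Nagelkerke = CS / (1 - exp(2 ll_null / n))`. When the evaluated model has
#' externally fixed coefficients (no refit), `ll_model` may fall below
#' `ll_null` and CS is legitimately negative.
#'
#' @param loglik_model,loglik_null log-likelihoods.
#' @param n number of observations.
#' @return Scalar value.
#' @export
cox_snell_r2 <- function(loglik_model, loglik_null, n) {
  stopifnot(n >= 1)
  1 - exp(-2 * (loglik_model - loglik_null) / n)
}

#' @rdname cox_snell_r2
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  cox_snell_r2(loglik_model, loglik_null, n) / (1 - exp(2 * loglik_null / n))
}

#' Calibration-in-the-large
#'
#' Intercept of a logistic fit of the outcomes with the model's linear
#' predictor as a fixed offset (slope pinned at 1); measures average
#' over- or under-prediction on the log-odds scale.
#'
#' @param lp linear predictors (log-odds).
#' @param y binary outcomes.
#' @return Intercept estimate.
#' @export
calibration_in_the_large <- function(lp, y) {
  fit <- fit_logistic(NULL, y, offset = lp)
  unname(fit$coefficients["(Intercept)"])
}

#' Calibration slope
#'
#' Slope of a logistic fit of the outcomes on the linear predictor with a
#' free intercept; below 1 indicates overfitted/overdispersed predictions.
#'
#' @inheritParams calibration_in_the_large
#' @return Slope estimate.
#' @export
calibration_slope <- function(lp, y) {
  if (stats::var(lp) == 0)
    stop("invalid input: constant linear predictor", call. = FALSE)
  fit <- fit_logistic(cbind(lp = lp), y)
  unname(fit$coefficients["lp"])
}

#' Observed/expected event ratio
#'
#' Sum of observed events over sum of predicted probabilities; below 1 means
#' the model overestimates risk.
#'
#' @inheritParams brier_score
#' @return Positive value.
#' @export
oe_ratio <- function(p, y) {
  if (sum(p) <= 0)
    stop("invalid input: expected event count is zero", call. = FALSE)
  sum(as.numeric(y)) / sum(p)
}

#' Integrated calibration index
#'
#' Mean absolute difference between predicted probabilities and a locally
#' weighted (loess, span 0.75, degree 1, tricube weights) regression of the
#' outcome on the predictions.
#'
#' @inheritParams brier_score
#' @param span loess span.
#' @return Non-negative value.
#' @export
ici <- function(p, y, span = 0.75) {
  if (length(p) < 20)
    stop("invalid input: ici needs n >= 20", call. = FALSE)
  fit <- stats::loess(as.numeric(y) ~ p, span = span, degree = 1)
  mean(abs(stats::fitted(fit) - p))
}

#' C-statistic (concordance)
#'
#' Probability that a randomly chosen event patient receives a higher
#' predicted risk than a randomly chosen non-event patient; ties count 0.5.
#' Computed via midranks in O(n log n).
#'
#' @inheritParams brier_score
#' @return Value in `[0, 1]`.
#' @export
c_statistic <- function(p, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0)
    stop("invalid input: both outcome classes must be present", call. = FALSE)
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (the study used 10,000; tests use
#'   a few hundred).
#' @param seed integer seed.
#' @param ci percentile interval level.
#' @return A `caki_bootconfig` list.
#' @export
bootstrap_config <- function(B = 10000L, seed = 1L, ci = 0.95) {
  stopifnot(B >= 1, ci > 0, ci < 1)
  structure(list(B = as.integer(B), seed = as.integer(seed), ci = ci),
            class = "caki_bootconfig")
}

# The full metric battery for a fixed (non-refit) model evaluated on (p, lp, y).
metric_battery <- function(p, lp, y) {
  n <- length(y)
  ll_model <- sum(ifelse(y == 1, log(clip_prob(p)), log(clip_prob(1 - p))))
  p_null <- mean(y)
  ll_null <- sum(ifelse(y == 1, log(clip_prob(p_null)),
                        log(clip_prob(1 - p_null))))
  c(r2_cox_snell = cox_snell_r2(ll_model, ll_null, n),
    r2_nagelkerke = nagelkerke_r2(ll_model, ll_null, n),
    brier = brier_score(p, y),
    calibration_in_the_large = calibration_in_the_large(lp, y),
    calibration_slope = calibration_slope(lp, y),
    oe_ratio = oe_ratio(p, y),
    ici = ici(p, y),
    c_statistic = c_statistic(p, y))
}

#' Bootstrap metric battery for a fixed score model on a cohort
#'
#' Point estimates of the full battery (pseudo-R-squared, Brier,
#' calibration-in-the-large, calibration slope, O/E ratio, ICI, C-statistic)
#' on the full cohort, plus bootstrap mean and percentile confidence interval
#' over `config$B` seeded patient resamples. The model's coefficients are
#' fixed throughout (no refitting), matching external-validation practice.
#' Replicates whose resample contains a single outcome class are skipped and
#' counted; a warning is issued if more than 1% are skipped.
#'
#' @param cohort a `caki_cohort`.
#' @param model a `caki_score_model`.
#' @param config a [bootstrap_config()].
#' @return A `caki_performance` data frame: one row per metric with `point`,
#'   `boot_mean`, `ci_low`, `ci_high`; attributes `B`, `seed`, `skipped`.
#' @export
bootstrap_metrics <- function(cohort, model, config = bootstrap_config()) {
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  pts <- cohort_score(cohort, model$mg_points)
  lp <- model$intercept + model$slope * pts
  p <- stats::plogis(lp)
  point <- metric_battery(p, lp, as.integer(y))

  set.seed(config$seed)
  n <- length(y)
  reps <- matrix(NA_real_, nrow = config$B, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(config$B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- as.integer(y[idx])
    if (length(unique(yb)) < 2L) next
    reps[b, ] <- tryCatch(metric_battery(p[idx], lp[idx], yb),
                          error = function(e) { rep(NA_real_, length(point)) })
  }
  skipped <- sum(is.na(reps[, 1]))  # one-class resamples and failed fits
  if (skipped > 0.01 * config$B)
    warning(sprintf("bootstrap_metrics: %d of %d replicates skipped",
                    skipped, config$B))
  alpha <- (1 - config$ci) / 2
  out <- data.frame(
    metric = names(point),
    point = unname(point),
    boot_mean = colMeans(reps, na.rm = TRUE),
    ci_low = apply(reps, 2, stats::quantile, probs = alpha, na.rm = TRUE),
    ci_high = apply(reps, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE))
  rownames(out) <- NULL
  structure(out, class = c("caki_performance", "data.frame"),
            B = config$B, seed = config$seed, skipped = skipped)
}

#' Optimism-corrected C-statistic by bootstrap
#'
#' The full model-building procedure is re-run on each bootstrap resample;
#' per replicate the C-statistic of the rebuilt model on its own resample
#' minus its C-statistic on the original cohort estimates the optimism. The
#' corrected value is the apparent C-statistic minus the mean optimism.
#'
#' @param cohort a `caki_cohort`.
#' @param model_builder function taking a cohort and returning a function
#'   that maps a cohort to predicted probabilities (the rebuilt model).
#' @param config a [bootstrap_config()].
#' @return List: `apparent_c`, `mean_optimism`, `corrected_c`, `B`, `seed`,
#'   `skipped`.
#' @export
optimism_corrected_c <- function(cohort, model_builder,
                                 config = bootstrap_config()) {
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  full_model <- model_builder(cohort)
  apparent <- c_statistic(full_model(cohort), y)
  set.seed(config$seed)
  n <- nrow(cohort)
  optimism <- rep(NA_real_, config$B)
  for (b in seq_len(config$B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort[idx, , drop = FALSE]
    attr(boot, "provenance") <- attr(cohort, "provenance")
    boot$id <- sprintf("B%06d", seq_len(n))  # keep ids unique
    yb <- y[idx]
    optimism[b] <- tryCatch({
      m <- model_builder(boot)
      c_statistic(m(boot), yb) - c_statistic(m(cohort), y)
    }, error = function(e) NA_real_)
  }
  skipped <- sum(is.na(optimism))
  mo <- mean(optimism, na.rm = TRUE)
  list(apparent_c = apparent, mean_optimism = mo,
       corrected_c = apparent - mo, B = config$B, seed = config$seed,
       skipped = skipped)
}

#' Default model builder: recalibration and extension with magnesium
#'
#' Re-runs the updating procedure on a cohort: fit outcome on the base score
#' and the no-magnesium indicator, returning a predictor function. Used by
#' [optimism_corrected_c()] for internal validation.
#'
#' @param cohort a `caki_cohort`.
#' @return Function mapping a cohort to predicted probabilities.
#' @export
build_updated_model <- function(cohort) {
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  fit <- recalibrate_extend(cohort_score(cohort, 0),
                            cbind(no_mg = as.numeric(!cohort$mg_supplement)),
                            y)
  co <- fit$coefficients
  function(newcohort) {
    stats::plogis(co[["(Intercept)"]] +
                    co[["score"]] * cohort_score(newcohort, 0) +
                    co[["no_mg"]] * as.numeric(!newcohort$mg_supplement))
  }
}
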