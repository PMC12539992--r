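# Motwani points table, updated score, logistic anchor and risk banding.

#' The Motwani points table
#'
#' Four binned factors summing to 0-9.5 points: age (<=60: 0, 61-70: 1.5,
#' >70: 2.5), serum albumin (>3.5 g/dL: 0, <=3.5: 2.0), first-course absolute
#' cisplatin dose (<=100 mg: 0, 101-150: 1.0, >150: 3.0) and hypertension
#' (yes: 2.0). All points lie on a 0.5 grid.
#'
#' @param age years.
#' @param albumin g/dL.
#' @param cddp_dose mg (absolute first-course dose).
#' @param hypertension logical.
#' @return Points in `{0, 0.5, ..., 9.5}`. Vectorised.
#' @examples
#' motwani_score(65, 3.2, 120, TRUE)  # 6.5
#' @export
motwani_score <- function(age, albumin, cddp_dose, hypertension) {
  age_pts <- ifelse(age <= 60, 0, ifelse(age <= 70, 1.5, 2.5))
  alb_pts <- ifelse(albumin > 3.5, 0, 2.0)
  dose_pts <- ifelse(cddp_dose <= 100, 0, ifelse(cddp_dose <= 150, 1.0, 3.0))
  ht_pts <- ifelse(hypertension, 2.0, 0)
  age_pts + alb_pts + dose_pts + ht_pts
}

#' Score a cohort with the base or updated points table
#'
#' @param cohort a `caki_cohort`.
#' @param mg_points points added when magnesium supplementation is absent;
#'   0 gives the base Motwani score.
#' @return Numeric points per patient.
#' @export
cohort_score <- function(cohort, mg_points = 0) {
  base <- motwani_score(cohort$age, cohort$albumin_gdl, cohort$cddp_dose_mg,
                        cohort$hypertension)
  base + ifelse(cohort$mg_supplement, 0, mg_points)
}

#' Updated score: base points plus the magnesium-supplementation extension
#'
#' Patients without magnesium supplementation receive 3.0 extra points,
#' extending the scale to 0-12.5.
#'
#' @param base_points Motwani points in `[0, 9.5]`.
#' @param mg_supplement logical; `FALSE` adds the extension points.
#' @param extension_points points for "no magnesium supplementation".
#' @return Updated points.
#' @export
updated_score <- function(base_points, mg_supplement, extension_points = 3.0) {
  base_points + ifelse(mg_supplement, 0, extension_points)
}

#' Logistic anchor coefficients from a published operating point
#'
#' Published points scores are usually reported as a probability at score 0
#' and an odds ratio per point; the implied logistic model has
#' `intercept = logit(p0)` and `slope = log(or_per_point)`. The Motwani anchor
#' (p0 = 0.04, OR = 1.49) gives intercept -3.178 and slope 0.399.
#'
#' @param p0 event probability at score 0, in (0, 1).
#' @param or_per_point odds ratio per score point, positive.
#' @return Named numeric `c(intercept, slope)` in log-odds units.
#' @export
coefficients_from_anchor <- function(p0, or_per_point) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("invalid input: p0 must lie strictly within (0, 1)", call. = FALSE)
  if (!is.finite(or_per_point) || or_per_point <= 0)
    stop("invalid input: or_per_point must be positive", call. = FALSE)
  c(intercept = stats::qlogis(p0), slope = log(or_per_point))
}

#' Construct a score model (points table plus logistic anchor)
#'
#' @param intercept log-odds at score 0.
#' @param slope log-odds per score point.
#' @param mg_points extension points for "no magnesium supplementation"
#'   (0 for the base model).
#' @return A `caki_score_model`.
#' @export
score_model <- function(intercept, slope, mg_points = 0) {
  stopifnot(is.finite(intercept), is.finite(slope), is.finite(mg_points))
  structure(list(intercept = unname(intercept), slope = unname(slope),
                 mg_points = mg_points),
            class = "caki_score_model")
}

#' @export
print.caki_score_model <- function(x, ...) {
  cat(sprintf("<caki_score_model> logit(p) = %.4f + %.4f * points",
              x$intercept, x$slope))
  if (x$mg_points > 0)
    cat(sprintf(" (no-Mg extension: +%.1f points)", x$mg_points))
  cat("\n")
  invisible(x)
}

#' The published Motwani anchor model
#'
#' @return `caki_score_model` with intercept `logit(0.04)` and slope
#'   `log(1.49)`.
#' @export
motwani_anchor_model <- function() {
  co <- coefficients_from_anchor(0.04, 1.49)
  score_model(co[["intercept"]], co[["slope"]], mg_points = 0)
}

#' Predicted event probability at a given score
#'
#' @param model a `caki_score_model`.
#' @param points score points.
#' @return `plogis(intercept + slope * points)`.
#' @export
predict_probability <- function(model, points) {
  stats::plogis(model$intercept + model$slope * points)
}

#' Probability for each patient of a cohort under a score model
#'
#' @param model a `caki_score_model`; its `mg_points` decides whether the
#'   base or extended score is used.
#' @param cohort a `caki_cohort`.
#' @return Probability per patient.
#' @export
predict_cohort <- function(model, cohort) {
  predict_probability(model, cohort_score(cohort, model$mg_points))
}

band_levels <- c("low", "intermediate", "high")

#' Risk band from score points
#'
#' Bands 0-3.5 (low), 4-6.5 (intermediate) and >=7 (high) on the updated
#' scale; points fall on a 0.5 grid so the boundaries are unambiguous.
#'
#' @param points score points, non-negative.
#' @param cutpoints lower bounds of the intermediate and high bands.
#' @return Ordered factor `low < intermediate < high`.
#' @export
score_band <- function(points, cutpoints = c(4.0, 7.0)) {
  cut_band(points, cutpoints)
}

#' Risk band from predicted probability
#'
#' Below 10% is low risk, 10-20% intermediate, 20% or more high; both
#' boundaries are assigned upward.
#'
#' @param p probability in `[0, 1]`.
#' @param cutpoints band boundaries.
#' @return Ordered factor `low < intermediate < high`.
#' @export
probability_band <- function(p, cutpoints = c(0.10, 0.20)) {
  cut_band(p, cutpoints)
}

cut_band <- function(x, cutpoints) {
  stopifnot(length(cutpoints) == 2L, cutpoints[1] < cutpoints[2])
  b <- ifelse(x < cutpoints[1], "low",
              ifelse(x < cutpoints[2], "intermediate", "high"))
  factor(b, levels = band_levels, ordered = TRUE)
}

#' Observed event incidence per score band
#'
#' @param cohort a `caki_cohort` (outcomes classified from its creatinine
#'   columns via [classify_aki()]).
#' @param score_fn function mapping a cohort to points per patient; defaults
#'   to the updated score with 3.0 magnesium points.
#' @param cutpoints score-band boundaries passed to [score_band()].
#' @return Data frame with one row per band: `band`, `n`, `events`, `rate`
#'   (`NA` for an empty band); `n` sums to the cohort size.
#' @export
band_incidence <- function(cohort,
                           score_fn = function(co) cohort_score(co, 3.0),
                           cutpoints = c(4.0, 7.0)) {
  bands <- score_band(score_fn(cohort), cutpoints)
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  n <- as.vector(table(bands))
  events <- as.vector(tapply(y, bands, sum, default = 0L))
  data.frame(band = band_levels, n = n, events = events,
             rate = ifelse(n > 0, events / n, NA_real_))
}
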