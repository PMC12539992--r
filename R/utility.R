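# Categorical reclassification (NRI), integrated discrimination improvement
# and decision curve analysis.

#' Paired 3x3 reclassification tables
#'
#' Cross-tabulates each patient's risk band under the old and new models
#' (rows = old, columns = new, order low/intermediate/high), separately for
#' events and non-events.
#'
#' @param p_old,p_new predicted probabilities under the two models.
#' @param y binary outcomes.
#' @param cutpoints probability-band boundaries (see [probability_band()]).
#' @return A `caki_reclass` list: `events` and `nonevents` 3x3 matrices,
#'   `n_events`, `n_nonevents`.
#' @export
reclassification_table <- function(p_old, p_new, y,
                                   cutpoints = c(0.10, 0.20)) {
  stopifnot(length(p_old) == length(p_new), length(p_old) == length(y))
  y <- as.logical(y)
  bo <- probability_band(p_old, cutpoints)
  bn <- probability_band(p_new, cutpoints)
  tab <- function(sel) {
    m <- table(old = bo[sel], new = bn[sel])
    matrix(as.vector(m), 3, 3, dimnames = list(old = band_levels,
                                               new = band_levels))
  }
  new_reclass_table(tab(y), tab(!y))
}

#' @rdname reclassification_table
#' @param events,nonevents 3x3 count matrices (rows = old band, columns =
#'   new band, order low/intermediate/high), e.g. transcribed from a printed
#'   reclassification table.
#' @export
new_reclass_table <- function(events, nonevents) {
  events <- as.matrix(events); nonevents <- as.matrix(nonevents)
  stopifnot(all(dim(events) == c(3, 3)), all(dim(nonevents) == c(3, 3)),
            all(events >= 0), all(nonevents >= 0))
  structure(list(events = events, nonevents = nonevents,
                 n_events = sum(events), n_nonevents = sum(nonevents)),
            class = "caki_reclass")
}

#' Categorical net reclassification improvement from paired tables
#'
#' Events moving to a higher band are correct reclassifications, to a lower
#' band incorrect; for non-events the directions are mirrored.
#' `NRI = (up_e - down_e)/n_events + (down_ne - up_ne)/n_nonevents`.
#'
#' @param t a `caki_reclass`.
#' @return List with the four movement counts, `nri_events`,
#'   `nri_nonevents` and `nri` (flagged `NA` for an empty outcome group).
#' @export
nri_from_table <- function(t) {
  stopifnot(inherits(t, "caki_reclass"))
  up <- function(m) sum(m[upper.tri(m)])
  down <- function(m) sum(m[lower.tri(m)])
  up_e <- up(t$events); down_e <- down(t$events)
  up_ne <- up(t$nonevents); down_ne <- down(t$nonevents)
  nri_e <- if (t$n_events > 0) (up_e - down_e) / t$n_events else NA_real_
  nri_ne <- if (t$n_nonevents > 0) (down_ne - up_ne) / t$n_nonevents
            else NA_real_
  list(up_events = up_e, down_events = down_e,
       up_nonevents = up_ne, down_nonevents = down_ne,
       nri_events = nri_e, nri_nonevents = nri_ne,
       nri = nri_e + nri_ne)
}

#' Integrated discrimination improvement
#'
#' Difference between the discrimination slopes of the new and old models:
#' `[mean(p_new | y=1) - mean(p_old | y=1)] -
#'  [mean(p_new | y=0) - mean(p_old | y=0)]`.
#'
#' @inheritParams reclassification_table
#' @return Scalar IDI.
#' @export
idi <- function(p_old, p_new, y) {
  stopifnot(length(p_old) == length(p_new), length(p_old) == length(y))
  y <- as.logical(y)
  if (!any(y) || all(y))
    stop("invalid input: both outcome classes must be present", call. = FALSE)
  (mean(p_new[y]) - mean(p_old[y])) - (mean(p_new[!y]) - mean(p_old[!y]))
}

#' Bootstrap percentile intervals for NRI and IDI
#'
#' Patient-level resampling with the same skipping rule as
#' [bootstrap_metrics()].
#'
#' @inheritParams reclassification_table
#' @param config a [bootstrap_config()].
#' @return List with `nri` and `idi`, each `(point, boot_mean, ci_low,
#'   ci_high)`, plus `B`, `seed`, `skipped`.
#' @export
nri_idi_bootstrap <- function(p_old, p_new, y, cutpoints = c(0.10, 0.20),
                              config = bootstrap_config()) {
  y <- as.logical(y)
  point_nri <- nri_from_table(
    reclassification_table(p_old, p_new, y, cutpoints))$nri
  point_idi <- idi(p_old, p_new, y)
  set.seed(config$seed)
  n <- length(y)
  reps <- matrix(NA_real_, config$B, 2)
  for (b in seq_len(config$B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (!any(yb) || all(yb)) next
    reps[b, 1] <- nri_from_table(
      reclassification_table(p_old[idx], p_new[idx], yb, cutpoints))$nri
    reps[b, 2] <- idi(p_old[idx], p_new[idx], yb)
  }
  skipped <- sum(is.na(reps[, 1]))
  if (skipped > 0.01 * config$B)
    warning(sprintf("nri_idi_bootstrap: %d of %d replicates skipped",
                    skipped, config$B))
  alpha <- (1 - config$ci) / 2
  summarise <- function(point, v) list(
    point = point, boot_mean = mean(v, na.rm = TRUE),
    ci_low = unname(stats::quantile(v, alpha, na.rm = TRUE)),
    ci_high = unname(stats::quantile(v, 1 - alpha, na.rm = TRUE)))
  list(nri = summarise(point_nri, reps[, 1]),
       idi = summarise(point_idi, reps[, 2]),
       B = config$B, seed = config$seed, skipped = skipped)
}

#' Net benefit at a threshold probability
#'
#' Patients with predicted risk at or above the threshold are "treated":
#' `NB = TP/n - (FP/n) * pt / (1 - pt)`. Treat-none has net benefit 0 at all
#' thresholds; treat-all corresponds to `p` identically 1.
#'
#' @inheritParams brier_score
#' @param pt threshold probability strictly inside (0, 1).
#' @return Scalar net benefit.
#' @export
net_benefit <- function(p, y, pt) {
  if (!is.finite(pt) || pt <= 0 || pt >= 1)
    stop("invalid input: pt must lie strictly within (0, 1)", call. = FALSE)
  y <- as.logical(y)
  n <- length(y)
  treated <- p >= pt
  tp <- sum(treated & y)
  fp <- sum(treated & !y)
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Decision curve analysis
#'
#' Net benefit of each model across a threshold grid, with treat-all and
#' treat-none reference curves, exported as a tidy table.
#'
#' @param p_models named list of probability vectors (one per model).
#' @param y binary outcomes.
#' @param grid threshold probabilities, all strictly inside (0, 1); default
#'   0.01 to 0.99 step 0.005.
#' @return A `caki_dca` data frame: `threshold`, one `nb_<model>` column per
#'   model, `nb_treat_all`, `nb_treat_none`.
#' @export
decision_curve <- function(p_models, y, grid = seq(0.01, 0.99, by = 0.005)) {
  stopifnot(is.list(p_models), length(p_models) >= 1,
            !is.null(names(p_models)), all(nzchar(names(p_models))))
  if (any(grid <= 0 | grid >= 1))
    stop("invalid input: grid must lie strictly within (0, 1)", call. = FALSE)
  y <- as.logical(y)
  out <- data.frame(threshold = grid)
  for (nm in names(p_models))
    out[[paste0("nb_", nm)]] <-
      vapply(grid, function(pt) net_benefit(p_models[[nm]], y, pt), 0)
  out$nb_treat_all <-
    vapply(grid, function(pt) net_benefit(rep(1, length(y)), y, pt), 0)
  out$nb_treat_none <- 0
  structure(out, class = c("caki_dca", "data.frame"))
}
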