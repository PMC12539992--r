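# Univariate screening battery: 2x2 odds ratios with Woolf intervals,
# Fisher's exact test, Mann-Whitney U and per-unit logistic odds ratios.

#' 2x2 contingency table of outcome by exposure
#'
#' @param event_exposed,event_unexposed,nonevent_exposed,nonevent_unexposed
#'   non-negative counts.
#' @return A `caki_2x2` list.
#' @export
two_by_two <- function(event_exposed, event_unexposed,
                       nonevent_exposed, nonevent_unexposed) {
  counts <- c(a = event_exposed, b = event_unexposed,
              c = nonevent_exposed, d = nonevent_unexposed)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("invalid input: counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "caki_2x2")
}

#' Odds ratio with a Woolf (log-normal) confidence interval
#'
#' `OR = (a d) / (b c)` with `a` = events among exposed, `b` = events among
#' unexposed, `c` = non-events among exposed, `d` = non-events among
#' unexposed; the CI is `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' A zero cell makes the estimate undefined and is flagged rather than
#' continuity-corrected, mirroring the "--" entries of published univariate
#' tables.
#'
#' @param t a `caki_2x2`.
#' @param ci_level confidence level.
#' @return An `caki_or` list: `or`, `ci_low`, `ci_high`, `p` (Fisher
#'   two-sided), `method`, `undefined` flag.
#' @export
odds_ratio_2x2 <- function(t, ci_level = 0.95) {
  stopifnot(inherits(t, "caki_2x2"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  p <- fisher_exact_two_sided(t)
  if (min(a, b, cc, d) == 0) {
    return(structure(list(or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = p, method = "woolf_2x2",
                          undefined = TRUE), class = "caki_or"))
  }
  or <- (a * d) / (b * cc)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  structure(list(or = or, ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se), p = p,
                 method = "woolf_2x2", undefined = FALSE),
            class = "caki_or")
}

#' Fisher's exact test, two-sided
#'
#' Probability-mass definition: with margins fixed, sum the hypergeometric
#' probabilities of all tables whose probability does not exceed that of the
#' observed table (up to a small relative tolerance for ties).
#'
#' @param t a `caki_2x2`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(t) {
  stopifnot(inherits(t, "caki_2x2"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  m <- a + cc           # exposed margin
  nn <- b + d           # unexposed margin
  k <- a + b            # events margin
  if (m == 0 || nn == 0 || k == 0 || cc + d == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Mann-Whitney U test with midranks and normal approximation
#'
#' U counts, for group A, the pairs `(x_A, x_B)` with `x_A > x_B` (ties 0.5).
#' The two-sided p-value uses the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @return List with `u` (for `group_a`) and `p`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0 || n2 == 0)
    stop("invalid input: both groups must be non-empty", call. = FALSE)
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u, p = 1))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-max(z, 0))))
}

#' Per-unit odds ratio for a continuous covariate
#'
#' Single-covariate maximum-likelihood logistic fit; the odds ratio is
#' `exp(slope)` with a Wald confidence interval.
#'
#' @param x continuous covariate.
#' @param y binary outcomes (0/1 or logical), same length, not constant.
#' @param ci_level confidence level.
#' @return An `caki_or` with `method = "logistic"`; `p` is the Wald test of
#'   zero slope.
#' @export
univariate_logistic_or <- function(x, y, ci_level = 0.95) {
  y <- as.integer(y)
  if (length(x) != length(y) || length(x) < 2)
    stop("invalid input: x and y must have equal length >= 2", call. = FALSE)
  if (stats::var(x) == 0)
    stop("fit error: x is constant", call. = FALSE)
  fit <- fit_logistic(cbind(x = x), y)
  beta <- fit$coefficients[["x"]]
  se <- sqrt(fit$vcov["x", "x"])
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(or = exp(beta), ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 method = "logistic", undefined = FALSE),
            class = "caki_or")
}

# Build the outcome-by-exposure 2x2 for a logical exposure vector.
exposure_2x2 <- function(exposed, y) {
  two_by_two(sum(y & exposed), sum(y & !exposed),
             sum(!y & exposed), sum(!y & !exposed))
}

#' Univariate screening table for a cohort
#'
#' One row per covariate: binary covariates get a Woolf odds ratio and a
#' Fisher two-sided p; continuous covariates a per-unit logistic odds ratio
#' and a Mann-Whitney p, with per-group medians and IQRs. Binary covariates
#' with a zero cell are flagged undefined (printed "--" in published tables);
#' drug columns with no exposed patients are omitted with a message. Derived
#' rows: `no_mg` (magnesium not given), `sh` (short hydration) and the base
#' prediction score treated as continuous.
#'
#' @param cohort a `caki_cohort`.
#' @return Data frame with columns `variable`, `type`, `or`, `ci_low`,
#'   `ci_high`, `p`, `method`, `undefined` and the per-group summaries
#'   (`med_event`/`med_nonevent` or `n_exposed`).
#' @export
univariate_table <- function(cohort) {
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  rows <- list()

  cont <- list(age = cohort$age, weight_kg = cohort$weight_kg,
               albumin_gdl = cohort$albumin_gdl,
               cddp_dose_mg = cohort$cddp_dose_mg,
               scr_baseline = cohort$scr_baseline,
               score = cohort_score(cohort, 0))
  for (nm in names(cont)) {
    x <- cont[[nm]]
    orr <- tryCatch(univariate_logistic_or(x, y), error = function(e) NULL)
    mw <- mann_whitney_u(x[y], x[!y])
    rows[[nm]] <- data.frame(
      variable = nm, type = "continuous",
      n_exposed = NA_integer_,
      med_event = stats::median(x[y]), med_nonevent = stats::median(x[!y]),
      or = if (is.null(orr)) NA_real_ else orr$or,
      ci_low = if (is.null(orr)) NA_real_ else orr$ci_low,
      ci_high = if (is.null(orr)) NA_real_ else orr$ci_high,
      p = mw$p, method = "logistic+mannwhitney", undefined = is.null(orr))
  }

  bin <- list(male = cohort$sex == "M",
              hypertension = cohort$hypertension,
              diabetes = cohort$diabetes,
              sh = short_hydration_flag(cohort$infusion_volume_l,
                                        cohort$infusion_duration_h),
              no_mg = !cohort$mg_supplement)
  for (fl in drug_flags()) bin[[fl]] <- cohort[[fl]]
  for (nm in names(bin)) {
    x <- bin[[nm]]
    if (nm %in% drug_flags() && sum(x) == 0) {
      message("univariate_table: omitting empty drug column '", nm, "'")
      next
    }
    orr <- odds_ratio_2x2(exposure_2x2(x, y))
    rows[[nm]] <- data.frame(
      variable = nm, type = "binary",
      n_exposed = sum(x), med_event = NA_real_, med_nonevent = NA_real_,
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      p = orr$p, method = "woolf+fisher", undefined = orr$undefined)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
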