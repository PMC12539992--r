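# Maximum-likelihood logistic fitting (IRLS with step-halving), the
# recalibration-and-extension updating procedure, AIC candidate scanning,
# VIF screening and score-point assignment.

logistic_loglik <- function(eta, y) {
  # numerically stable: log(p) = -log1p(exp(-eta)), log(1-p) = -log1p(exp(eta))
  sum(ifelse(y == 1, -log1p(exp(-eta)), -log1p(exp(eta))))
}

#' Maximum-likelihood logistic regression
#'
#' Iteratively reweighted least squares with step-halving so the
#' log-likelihood never decreases across iterations. Convergence requires a
#' relative log-likelihood change below `1e-10` or a gradient norm below
#' `1e-8`, within 100 iterations. Perfect separation and rank-deficient
#' designs raise errors rather than returning diverged coefficients.
#'
#' @param x predictor matrix (columns named), or `NULL` for an
#'   intercept-only fit. An intercept column is always added.
#' @param y binary outcome (0/1 or logical); both classes must be present.
#' @param offset optional fixed offset added to the linear predictor.
#' @param max_iter,tol_loglik,tol_grad convergence controls.
#' @return A `caki_logistic` list: `coefficients`, `vcov`, `loglik`, `aic`
#'   (`2k - 2 loglik`), `n`, `converged`, `iterations`, `loglik_trace`,
#'   `fitted`.
#' @export
fit_logistic <- function(x, y, offset = NULL, max_iter = 100L,
                         tol_loglik = 1e-10, tol_grad = 1e-8) {
  y <- as.integer(y)
  n <- length(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("invalid input: y must be binary", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: both classes must be present", call. = FALSE)
  if (is.null(offset)) offset <- rep(0, n)
  if (is.null(x)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    if (nrow(x) != n) stop("invalid input: nrow(x) != length(y)", call. = FALSE)
    X <- cbind(`(Intercept)` = 1, x)
  }
  if (qr(X)$rank < ncol(X))
    stop("design error: predictor matrix is rank deficient (collinearity)",
         call. = FALSE)

  beta <- numeric(ncol(X))
  eta <- as.vector(X %*% beta) + offset
  ll <- logistic_loglik(eta, y)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- as.vector(crossprod(X, y - p))
    H <- crossprod(X * w, X)
    delta <- tryCatch(solve(H, grad), error = function(e)
      stop("design error: information matrix is singular", call. = FALSE))
    # step-halving line search: never accept a decrease in log-likelihood
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- as.vector(X %*% beta_new) + offset
      ll_new <- logistic_loglik(eta_new, y)
      if (ll_new >= ll || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta_new; eta <- eta_new
    trace <- c(trace, ll_new)
    rel_change <- abs(ll_new - ll) / (abs(ll_new) + 1e-12)
    ll <- ll_new
    if (max(abs(grad)) < tol_grad || rel_change < tol_loglik) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  p <- stats::plogis(eta)
  if (all(abs(p - y) < 1e-8) || max(abs(beta)) > 1e3)
    stop("separation error: outcome is perfectly separated", call. = FALSE)
  if (!converged)
    stop("fit error: logistic fit did not converge in ", max_iter,
         " iterations", call. = FALSE)
  w <- pmax(p * (1 - p), 1e-12)
  H <- crossprod(X * w, X)
  vcov <- solve(H)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  k <- ncol(X)
  structure(list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
                 vcov = vcov, loglik = ll, aic = 2 * k - 2 * ll, n = n,
                 converged = converged, iterations = iter,
                 loglik_trace = trace, fitted = p),
            class = "caki_logistic")
}

#' @export
print.caki_logistic <- function(x, ...) {
  cat(sprintf("<caki_logistic> n = %d, loglik = %.3f, AIC = %.1f\n",
              x$n, x$loglik, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Recalibration-and-extension model update
#'
#' Fits `logit(p) = alpha + beta1 * score + sum(beta_j * extra_j)`: the
#' existing score enters as a single predictor whose internal component
#' coefficients are never re-estimated, and each extension predictor adds
#' one term.
#'
#' @param score per-patient points of the existing model.
#' @param extras matrix/data frame of extension predictors (may be `NULL` or
#'   zero columns for a pure recalibration).
#' @param y binary outcomes.
#' @return A `caki_logistic`.
#' @export
recalibrate_extend <- function(score, extras = NULL, y) {
  X <- cbind(score = score)
  if (!is.null(extras) && NCOL(extras) > 0) {
    extras <- as.matrix(extras)
    storage.mode(extras) <- "double"
    X <- cbind(X, extras)
  }
  fit_logistic(X, y)
}

#' Is an AIC drop significant?
#'
#' An improvement (drop) in AIC greater than 10 relative to the base model is
#' treated as significant.
#'
#' @param aic_base,aic_candidate finite AIC values.
#' @return Logical: `aic_base - aic_candidate > 10`.
#' @export
delta_aic_significant <- function(aic_base, aic_candidate) {
  stopifnot(is.finite(aic_base), is.finite(aic_candidate))
  (aic_base - aic_candidate) > 10
}

#' Scan candidate predictors added one at a time to the existing score
#'
#' Each candidate binary field is added individually to a logistic model of
#' outcome on the base score; the row records the apparent (training-data)
#' AUC and AIC of the extended model, the AIC drop versus the base model and
#' the significance flag (drop > 10). A `"None"` base row is included and
#' rows are sorted by AIC ascending. Zero-variance candidates are flagged and
#' not fitted.
#'
#' @param cohort a `caki_cohort`.
#' @param base_score per-patient points of the existing model; defaults to
#'   the base Motwani score of the cohort.
#' @param candidates character vector naming cohort fields or the derived
#'   fields `"no_mg"`, `"sh"`, `"male"`.
#' @return Data frame with columns `candidate`, `auc`, `aic`, `delta_aic`,
#'   `significant`, `fitted`.
#' @export
candidate_scan <- function(cohort, base_score = cohort_score(cohort, 0),
                           candidates) {
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  base_fit <- fit_logistic(cbind(score = base_score), y)
  rows <- list(data.frame(candidate = "None",
                          auc = c_statistic(base_fit$fitted, y),
                          aic = base_fit$aic, delta_aic = 0,
                          significant = FALSE, fitted = TRUE))
  for (nm in candidates) {
    x <- candidate_column(cohort, nm)
    if (stats::var(as.numeric(x)) == 0) {
      rows[[nm]] <- data.frame(candidate = nm, auc = NA_real_,
                               aic = NA_real_, delta_aic = NA_real_,
                               significant = FALSE, fitted = FALSE)
      next
    }
    fit <- fit_logistic(cbind(score = base_score, cand = as.numeric(x)), y)
    rows[[nm]] <- data.frame(
      candidate = nm, auc = c_statistic(fit$fitted, y), aic = fit$aic,
      delta_aic = base_fit$aic - fit$aic,
      significant = delta_aic_significant(base_fit$aic, fit$aic),
      fitted = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(is.na(out$aic), out$aic), , drop = FALSE]
}

candidate_column <- function(cohort, nm) {
  switch(nm,
    no_mg = !cohort$mg_supplement,
    sh = short_hydration_flag(cohort$infusion_volume_l,
                              cohort$infusion_duration_h),
    male = cohort$sex == "M",
    {
      if (!nm %in% names(cohort))
        stop("unknown candidate field: ", nm, call. = FALSE)
      cohort[[nm]]
    })
}

#' Assign score points to a new predictor
#'
#' The new predictor's odds ratio is divided by the odds ratio per one point
#' of the existing score and the quotient rounded to the nearest 0.5
#' increment (ties away from zero). The study's fitted ORs 3.91 / 1.29 give
#' 3.031, hence 3.0 points.
#'
#' @param or_new odds ratio of the new predictor, positive.
#' @param or_per_point odds ratio per existing score point, positive.
#' @return List: `or_new`, `or_per_point`, `raw_ratio`, `points` (0.5 grid).
#' @export
assign_score_points <- function(or_new, or_per_point) {
  if (!is.finite(or_new) || or_new <= 0 ||
      !is.finite(or_per_point) || or_per_point <= 0)
    stop("invalid input: odds ratios must be positive", call. = FALSE)
  raw <- or_new / or_per_point
  # round to nearest 0.5, half away from zero
  points <- sign(raw) * floor(abs(raw) * 2 + 0.5) / 2
  list(or_new = or_new, or_per_point = or_per_point,
       raw_ratio = raw, points = points)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the least-squares regression
#' of predictor j on all other predictors (with intercept). Exact
#' collinearity yields `Inf`.
#'
#' @param design numeric matrix/data frame with at least two named columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("invalid input: need >= 2 predictors", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((X[, j] - mean(X[, j]))^2)
    if (ss_tot == 0) stop("invalid input: constant predictor ", colnames(X)[j],
                          call. = FALSE)
    r2 <- 1 - ss_res / ss_tot
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
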