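# Orchestration of the full study: validate the existing score, update it,
# internally validate, and measure clinical usefulness.

#' Serialise / deserialise a score model as JSON
#'
#' @param model a `caki_score_model`.
#' @param path file path.
#' @return `read_score_model_json` returns a `caki_score_model`.
#' @export
write_score_model_json <- function(model, path) {
  jsonlite::write_json(list(intercept = model$intercept, slope = model$slope,
                            mg_points = model$mg_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model_json
#' @export
read_score_model_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_model(d$intercept, d$slope, d$mg_points)
}

#' Run configuration for the full analysis
#'
#' Exactly one of `input` (cohort CSV path) and `generator` (a
#' `caki_genconfig`) must be given.
#'
#' @param input path to a cohort CSV, or `NULL`.
#' @param generator a [generator_config()], or `NULL`.
#' @param seed root seed for every stochastic stage.
#' @param bootstrap_B bootstrap replicates for metric CIs and NRI/IDI.
#' @param optimism_B bootstrap replicates for the optimism correction.
#' @param candidates candidate predictor names for the AIC scan.
#' @param cutpoints_prob probability-band boundaries.
#' @param cutpoints_score score-band boundaries for band incidence.
#' @param dca_grid decision-curve threshold grid.
#' @param outdir output directory, or `NULL` for no file output.
#' @return A `caki_runconfig` list.
#' @export
run_config <- function(input = NULL, generator = NULL, seed = 1L,
                       bootstrap_B = 1000L, optimism_B = 200L,
                       candidates = c("no_mg", "sh", drug_flags()),
                       cutpoints_prob = c(0.10, 0.20),
                       cutpoints_score = c(4.0, 7.0),
                       dca_grid = seq(0.01, 0.99, by = 0.005),
                       outdir = NULL) {
  if (is.null(input) == is.null(generator))
    stop("config error: exactly one of input/generator must be given",
         call. = FALSE)
  structure(list(input = input, generator = generator, seed = as.integer(seed),
                 bootstrap_B = as.integer(bootstrap_B),
                 optimism_B = as.integer(optimism_B),
                 candidates = candidates, cutpoints_prob = cutpoints_prob,
                 cutpoints_score = cutpoints_score, dca_grid = dca_grid,
                 outdir = outdir),
            class = "caki_runconfig")
}

unclass_rec <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_rec) else x
}

# FNV-1a hash of the serialised config, for provenance.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_rec(config[setdiff(names(config), "outdir")]),
                        auto_unbox = TRUE, digits = 10, null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_log <- function(stage, t0) {
  message(sprintf("[cakiscore] %-22s %6.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full risk-score updating study
#'
#' Stages, in the study's order: univariate screening; performance of the
#' existing anchored model (fixed coefficients, bootstrap CIs); AIC candidate
#' scan and recalibration-and-extension with the best significant candidate;
#' score-point assignment and refit of the updated score's logistic anchor;
#' performance of the updated model; bootstrap optimism correction of the
#' updated model's C-statistic; reclassification (NRI), IDI and decision
#' curves comparing the two models; incidence per updated-score band.
#' Deterministic given `(config, seed)`. When `config$outdir` is set, the
#' tables are written as TSV/CSV and the full report as JSON.
#'
#' @param config a [run_config()].
#' @return A `caki_report` list with elements `univariate`, `candidate_scan`,
#'   `update` (fit, assignment, updated anchor), `performance_existing`,
#'   `performance_updated`, `optimism`, `reclass`, `nri_idi`, `dca`,
#'   `band_incidence`, `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "caki_runconfig"))
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$input)) {
    cohort <- read_cohort_csv(config$input)
  } else {
    cohort <- generate_cohort(config$generator, seed = config$seed)$cohort
  }
  y <- classify_aki(cohort$scr_baseline, cohort$scr_followup_max14d)$aki
  stage_log("load cohort", t0)

  uni <- univariate_table(cohort)
  stage_log("univariate", t0)

  existing <- motwani_anchor_model()
  perf_existing <- bootstrap_metrics(
    cohort, existing, bootstrap_config(config$bootstrap_B,
                                       seed = config$seed))
  stage_log("validate existing", t0)

  base_score <- cohort_score(cohort, 0)
  scan <- candidate_scan(cohort, base_score, config$candidates)
  cand_rows <- scan[scan$candidate != "None" & scan$fitted, , drop = FALSE]
  best <- if (nrow(cand_rows) && any(cand_rows$significant))
    cand_rows$candidate[which.max(cand_rows$delta_aic)] else NA_character_

  if (!is.na(best)) {
    xb <- as.numeric(candidate_column(cohort, best))
    fit <- recalibrate_extend(
      base_score, matrix(xb, ncol = 1, dimnames = list(NULL, best)), y)
    assignment <- assign_score_points(
      exp(fit$coefficients[[best]]), exp(fit$coefficients[["score"]]))
    ext_pts <- assignment$points
    upd_points <- base_score + ext_pts * xb
    anchor_fit <- fit_logistic(cbind(points = upd_points), y)
    updated <- score_model(anchor_fit$coefficients[["(Intercept)"]],
                           anchor_fit$coefficients[["points"]],
                           mg_points = if (best == "no_mg") ext_pts else 0)
    p_new <- stats::plogis(anchor_fit$coefficients[["(Intercept)"]] +
                             anchor_fit$coefficients[["points"]] * upd_points)
  } else {
    # no significant candidate: pure recalibration of the base score
    fit <- recalibrate_extend(base_score, NULL, y)
    assignment <- NULL
    anchor_fit <- fit
    updated <- score_model(fit$coefficients[["(Intercept)"]],
                           fit$coefficients[["score"]], mg_points = 0)
    upd_points <- base_score
    p_new <- fit$fitted
  }
  stage_log("model update", t0)

  perf_updated <- bootstrap_metrics(
    cohort, updated, bootstrap_config(config$bootstrap_B,
                                      seed = config$seed + 1L))
  stage_log("validate updated", t0)

  optimism <- optimism_corrected_c(
    cohort, build_updated_model,
    bootstrap_config(config$optimism_B, seed = config$seed + 2L))
  stage_log("optimism", t0)

  p_old <- predict_cohort(existing, cohort)
  reclass <- reclassification_table(p_old, p_new, y, config$cutpoints_prob)
  nri_idi <- nri_idi_bootstrap(
    p_old, p_new, y, config$cutpoints_prob,
    bootstrap_config(config$bootstrap_B, seed = config$seed + 3L))
  dca <- decision_curve(list(existing = p_old, updated = p_new), y,
                        config$dca_grid)
  bands <- band_incidence(cohort,
                          function(co) cohort_score(co, updated$mg_points),
                          config$cutpoints_score)
  stage_log("clinical utility", t0)

  report <- structure(list(
    univariate = uni, candidate_scan = scan,
    update = list(selected = best, fit = fit, assignment = assignment,
                  updated_model = updated),
    performance_existing = perf_existing,
    performance_updated = perf_updated,
    optimism = optimism,
    reclass = reclass, nri_idi = nri_idi, dca = dca,
    band_incidence = bands,
    provenance = list(seed = config$seed,
                      n = nrow(cohort),
                      package_version = as.character(
                        utils::packageVersion("cakiscore")),
                      config_hash = config_hash(config))),
    class = "caki_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "--", formatC(x, digits = digits, format = "f"))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a study report to an output directory
#'
#' TSV tables (ORs to 2 decimals, metrics to 3), a DCA curve CSV and a full
#' precision JSON report.
#'
#' @param report a `caki_report`.
#' @param outdir directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  uni <- report$univariate
  for (col in c("or", "ci_low", "ci_high")) uni[[col]] <- fmt_num(uni[[col]], 2)
  uni$p <- fmt_num(uni$p, 4)
  write_tsv(uni, file.path(outdir, "univariate.tsv"))

  scan <- report$candidate_scan
  for (col in c("auc", "delta_aic")) scan[[col]] <- fmt_num(scan[[col]], 3)
  scan$aic <- fmt_num(as.numeric(report$candidate_scan$aic), 1)
  write_tsv(scan, file.path(outdir, "candidate_scan.tsv"))

  perf <- function(p) {
    d <- as.data.frame(p)
    for (col in c("point", "boot_mean", "ci_low", "ci_high"))
      d[[col]] <- fmt_num(d[[col]], 3)
    d
  }
  write_tsv(perf(report$performance_existing),
            file.path(outdir, "performance_existing.tsv"))
  write_tsv(perf(report$performance_updated),
            file.path(outdir, "performance_updated.tsv"))

  rc <- rbind(cbind(group = "events", as.data.frame(report$reclass$events)),
              cbind(group = "nonevents",
                    as.data.frame(report$reclass$nonevents)))
  rc <- cbind(old_band = rep(band_levels, 2), rc)
  write_tsv(rc, file.path(outdir, "reclassification.tsv"))

  utils::write.csv(as.data.frame(report$dca),
                   file.path(outdir, "dca_curves.csv"), row.names = FALSE)
  write_tsv(report$band_incidence, file.path(outdir, "band_incidence.tsv"))

  json <- list(
    provenance = report$provenance,
    update = list(selected = report$update$selected,
                  coefficients = as.list(report$update$fit$coefficients),
                  assignment = report$update$assignment,
                  updated_model = unclass(report$update$updated_model)),
    performance_existing = as.data.frame(report$performance_existing),
    performance_updated = as.data.frame(report$performance_updated),
    optimism = report$optimism,
    nri_idi = report$nri_idi[c("nri", "idi", "B", "seed")],
    band_incidence = report$band_incidence)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(outdir)
}
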