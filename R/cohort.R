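# Cohort container, outcome classification and renal derivation rules.

#' Drug-exposure flags carried by a cohort
#'
#' Concomitant-medication flags recorded per patient, in the column order used
#' by the cohort CSV schema. `cpi` covers immune checkpoint inhibitors
#' (nivolumab, pembrolizumab); `vegf` covers VEGF inhibitors (bevacizumab).
#'
#' @return Character vector of flag column names.
#' @export
drug_flags <- function() {
  c("capecitabine", "gem", "mtx", "pem", "dxr", "s1", "vp16", "cpi", "vegf")
}

cohort_base_columns <- function() {
  c("id", "age", "sex", "weight_kg", "albumin_gdl", "cddp_dose_mg",
    "hypertension", "diabetes", "mg_supplement",
    "infusion_volume_l", "infusion_duration_h",
    "scr_baseline", "scr_followup_max14d")
}

cohort_columns <- function() c(cohort_base_columns(), drug_flags())

#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per patient and a fixed schema:
#' demographics (`age` in years, `sex` as `"M"`/`"F"`, `weight_kg`), labs
#' (`albumin_gdl`, `scr_baseline`, `scr_followup_max14d` in mg/dL), the
#' first-course absolute cisplatin dose (`cddp_dose_mg`), comorbidity and
#' supportive-care booleans, hydration (`infusion_volume_l`,
#' `infusion_duration_h`) and one logical column per [drug_flags()] entry.
#'
#' @param records data frame holding exactly the schema columns.
#' @param provenance `"observed"` or `"synthetic"`.
#' @param seed integer seed used to generate the cohort, or `NULL`.
#' @return A `caki_cohort` (data frame subclass) with `provenance` and `seed`
#'   attributes.
#' @export
new_cohort <- function(records, provenance = c("observed", "synthetic"),
                       seed = NULL) {
  provenance <- match.arg(provenance)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  validate_cohort(records)
  records <- records[, cohort_columns()]
  structure(records,
            class = c("caki_cohort", "data.frame"),
            provenance = provenance,
            seed = seed)
}

#' @export
print.caki_cohort <- function(x, ...) {
  cat(sprintf("<caki_cohort> %d patients (%s%s)\n",
              nrow(x), attr(x, "provenance"),
              if (is.null(attr(x, "seed"))) "" else
                paste0(", seed ", attr(x, "seed"))))
  NextMethod()
}

validate_cohort <- function(d) {
  missing_cols <- setdiff(cohort_columns(), names(d))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(d), cohort_columns())
  if (length(extra))
    stop("cohort schema error: unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$id))
    stop("cohort schema error: duplicate id ",
         d$id[anyDuplicated(d$id)], call. = FALSE)
  if (nrow(d) == 0L) return(invisible(d))

  check_col <- function(ok, col) {
    if (any(!ok)) stop(sprintf("cohort schema error: invalid %s at row %d",
                               col, which(!ok)[1L]), call. = FALSE)
  }
  check_col(!is.na(d$age) & d$age >= 20 & d$age == round(d$age), "age")
  check_col(d$sex %in% c("M", "F"), "sex")
  for (col in c("weight_kg", "albumin_gdl", "cddp_dose_mg",
                "scr_baseline", "scr_followup_max14d"))
    check_col(!is.na(d[[col]]) & d[[col]] > 0, col)
  for (col in c("infusion_volume_l", "infusion_duration_h"))
    check_col(!is.na(d[[col]]) & d[[col]] >= 0, col)
  for (col in c("hypertension", "diabetes", "mg_supplement", drug_flags()))
    check_col(is.logical(d[[col]]) & !is.na(d[[col]]), col)
  invisible(d)
}

#' Classify cisplatin-induced acute kidney injury
#'
#' C-AKI is a serum-creatinine rise of at least 0.3 mg/dL within 14 days of
#' the first cisplatin dose. AKIN severity is graded on the fold change of the
#' 14-day maximum over baseline: stage 1 below 2-fold, stage 2 from 2- to
#' 3-fold inclusive, stage 3 above 3-fold. Stage is only assigned when the
#' 0.3 mg/dL criterion is met.
#'
#' @param scr_baseline baseline serum creatinine, mg/dL (closest value within
#'   30 days before administration). Vectorised.
#' @param scr_followup_max14d maximum serum creatinine within 14 days after
#'   the first dose, mg/dL.
#' @return A data frame with columns `aki` (logical), `akin_stage` (ordered
#'   factor `none < 1 < 2 < 3`), `scr_increase` (mg/dL) and `fold_change`.
#' @examples
#' classify_aki(0.7, 1.0)  # stage 1
#' classify_aki(0.6, 1.5)  # 2.5-fold, stage 2
#' @export
classify_aki <- function(scr_baseline, scr_followup_max14d) {
  if (any(is.na(scr_baseline)) || any(is.na(scr_followup_max14d)) ||
      any(scr_baseline <= 0) || any(scr_followup_max14d <= 0))
    stop("invalid input: creatinine values must be positive", call. = FALSE)
  inc <- scr_followup_max14d - scr_baseline
  fold <- scr_followup_max14d / scr_baseline
  aki <- inc >= 0.3
  stage <- rep("none", length(inc))
  stage[aki & fold < 2.0] <- "1"
  stage[aki & fold >= 2.0 & fold <= 3.0] <- "2"
  stage[aki & fold > 3.0] <- "3"
  data.frame(aki = aki,
             akin_stage = factor(stage, levels = c("none", "1", "2", "3"),
                                 ordered = TRUE),
             scr_increase = inc,
             fold_change = fold)
}

#' Estimated creatinine clearance (Cockcroft-Gault)
#'
#' `((140 - age) * weight) / (72 * scr)`, multiplied by 0.85 for women.
#'
#' @param age years (must be below 140).
#' @param weight kg.
#' @param scr serum creatinine, mg/dL.
#' @param sex `"M"` or `"F"`.
#' @return Creatinine clearance in mL/min.
#' @export
cockcroft_gault_clcr <- function(age, weight, scr, sex) {
  if (any(age <= 0) || any(weight <= 0) || any(scr <= 0))
    stop("invalid input: age, weight and scr must be positive", call. = FALSE)
  if (any(age >= 140))
    stop("invalid input: age must be below 140 years", call. = FALSE)
  if (!all(sex %in% c("M", "F")))
    stop("invalid input: sex must be 'M' or 'F'", call. = FALSE)
  clcr <- ((140 - age) * weight) / (72 * scr)
  ifelse(sex == "F", 0.85 * clcr, clcr)
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, race-free)
#'
#' The 2009 CKD-EPI creatinine equation without the race coefficient:
#' `141 * min(scr/k, 1)^a * max(scr/k, 1)^-1.209 * 0.993^age`, with
#' `k = 0.7, a = -0.329` for women (times 1.018) and `k = 0.9, a = -0.411`
#' for men.
#'
#' @inheritParams cockcroft_gault_clcr
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(age, sex, scr) {
  if (any(age <= 0) || any(scr <= 0))
    stop("invalid input: age and scr must be positive", call. = FALSE)
  if (!all(sex %in% c("M", "F")))
    stop("invalid input: sex must be 'M' or 'F'", call. = FALSE)
  kappa <- ifelse(sex == "F", 0.7, 0.9)
  alpha <- ifelse(sex == "F", -0.329, -0.411)
  ratio <- scr / kappa
  egfr <- 141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) * 0.993^age
  ifelse(sex == "F", 1.018 * egfr, egfr)
}

#' Short-hydration flag
#'
#' Short hydration is a same-day infusion volume below 3 L given over less
#' than 5 h (a deviation from conventional high-volume hydration).
#'
#' @param infusion_volume_l litres, non-negative.
#' @param infusion_duration_h hours, non-negative.
#' @return Logical.
#' @export
short_hydration_flag <- function(infusion_volume_l, infusion_duration_h) {
  if (any(infusion_volume_l < 0) || any(infusion_duration_h < 0))
    stop("invalid input: infusion volume/duration must be non-negative",
         call. = FALSE)
  infusion_volume_l < 3 & infusion_duration_h < 5
}

#' Pre-existing chronic kidney disease flag
#'
#' CKD before cisplatin administration is defined as an eGFR strictly below
#' 60 mL/min/1.73 m^2.
#'
#' @param egfr mL/min/1.73 m^2, non-negative.
#' @return Logical.
#' @export
pre_existing_ckd <- function(egfr) {
  if (any(egfr < 0))
    stop("invalid input: egfr must be non-negative", call. = FALSE)
  egfr < 60
}

#' Read / write a cohort CSV
#'
#' The CSV schema has a header row and exactly the columns of
#' [cohort_columns()]: sex encoded `M`/`F`, booleans `0`/`1`, UTF-8, decimal
#' point. Unknown or missing columns, unparseable cells and duplicate ids are
#' rejected with an error naming the offending row/column; there is no
#' imputation pathway.
#'
#' @param path file path.
#' @return `read_cohort_csv` returns a `caki_cohort` with provenance
#'   `"observed"`; `write_cohort_csv` invisibly returns `path`.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  missing_cols <- setdiff(cohort_columns(), names(d))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(d), cohort_columns())
  if (length(extra))
    stop("cohort schema error: unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (col in c("hypertension", "diabetes", "mg_supplement", drug_flags())) {
    v <- d[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop(sprintf("cohort schema error: column %s must be 0/1 (row %d)",
                   col, which(!v %in% c(0L, 1L))[1L]), call. = FALSE)
    d[[col]] <- as.logical(v)
  }
  numeric_cols <- c("age", "weight_kg", "albumin_gdl", "cddp_dose_mg",
                    "infusion_volume_l", "infusion_duration_h",
                    "scr_baseline", "scr_followup_max14d")
  for (col in numeric_cols) {
    if (!is.numeric(d[[col]]))
      stop(sprintf("cohort schema error: column %s is not numeric", col),
           call. = FALSE)
  }
  new_cohort(d, provenance = "observed")
}

#' @rdname read_cohort_csv
#' @param cohort a `caki_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- as.data.frame(cohort)
  for (col in c("hypertension", "diabetes", "mg_supplement", drug_flags()))
    d[[col]] <- as.integer(d[[col]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
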