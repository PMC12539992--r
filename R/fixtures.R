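# Accessors for the packaged contingency-table fixtures transcribed from the
# study's printed univariate and reclassification tables.

#' Printed paired reclassification counts
#'
#' The published 3x3 cross-tabulations of existing-model versus updated-model
#' risk bands, split by C-AKI outcome (205 events, 1580 non-events).
#'
#' @return A `caki_reclass` (see [new_reclass_table()]).
#' @export
published_reclassification <- function() {
  d <- jsonlite::read_json(
    system.file("extdata", "reclassification_counts.json",
                package = "cakiscore"),
    simplifyVector = TRUE)
  new_reclass_table(d$events, d$nonevents)
}

#' Printed outcome-by-exposure counts from the univariate table
#'
#' 2x2 counts (events/non-events by exposure) for the binary rows of the
#' published univariate analysis of the 1785-patient cohort.
#'
#' @return Data frame with `variable` and the four cell counts.
#' @export
published_univariate_counts <- function() {
  utils::read.csv(system.file("extdata", "univariate_counts.csv",
                              package = "cakiscore"),
                  stringsAsFactors = FALSE)
}
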