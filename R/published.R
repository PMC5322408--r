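#' Published reference-survey summary tables
#'
#' Loads the per-event sampling summary, per-species diversity summary, or
#' pairwise F_ST table of the Lake Lucerne winter-spawning whitefish
#' reference survey, shipped with the package as plain CSV. These printed
#' summary values serve as inputs for worked-arithmetic checks (column
#' totals, overall rows, matrix means) and as calibration anchors for the
#' synthetic preset; they are not re-estimable from the package alone.
#'
#' @param which one of `"sampling"`, `"diversity"`, `"fst"`.
#' @return a tibble. Sampling coordinates are converted from DMS strings to
#'   decimal degrees (`lat`, `lon`).
#' @export
published_table <- function(which = c("sampling", "diversity", "fst")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("published_table",
                          match(which, c("sampling", "diversity", "fst")),
                          "_", which, ".csv"),
                   package = "depthcline", mustWork = TRUE)
  out <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  if (which == "sampling") {
    out$lat <- dms_to_decimal(out$lat)
    out$lon <- dms_to_decimal(out$lon)
  }
  out
}
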