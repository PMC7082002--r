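## Access to the packaged percent-dialect fixtures (transcribed published
## peak-proportion tables for the spider crab Maja brachydactyla).

#' Path to a packaged fixture
#' @param name one of `"table2_16s"`, `"table4_coi_adults"`,
#'   `"table5_coi_families_tissues"`.
#' @return file path.
#' @export
fixture_path <- function(name = c("table2_16s", "table4_coi_adults",
                                  "table5_coi_families_tissues")) {
  name <- match.arg(name)
  p <- system.file("extdata", paste0(name, ".csv"), package = "sangerhet")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' Load a packaged fixture as a call table
#' @inheritParams fixture_path
#' @param min_minor_fraction heteroplasmy threshold.
#' @return a [call_table()].
#' @export
load_fixture <- function(name, min_minor_fraction = 0.05) {
  read_percent_table(fixture_path(name), min_minor_fraction)
}

#' Combine call tables (e.g. loci of the same specimens)
#'
#' Row-binds validated call tables; the `locus` column keeps rows apart.
#' @param ... [call_table()]s.
#' @return a `call_table`.
#' @export
combine_call_tables <- function(...) {
  tabs <- list(...)
  stopifnot(all(vapply(tabs, inherits, logical(1), "call_table")))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("call_table", "data.frame")
  out
}
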