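#' Paths to bundled example data
#'
#' @param file File name within the package's `extdata` directory; when
#'   missing, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
fhupm_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fhupm")))
  }
  path <- system.file("extdata", file, package = "fhupm")
  if (!nzchar(path)) rlang::abort(paste0("no bundled file named ", file))
  path
}

#' Bundled worked-example transaction database
#'
#' A six-transaction, eight-item quantitative database with an external
#' utility table, small enough to verify every utility computation by
#' hand. For instance, transaction 5 holds (A:2)(C:6)(E:2)(G:5) with
#' external utilities A=5, C=1, E=3, G=1, so its transaction utility is
#' 2*5 + 6*1 + 2*3 + 5*1 = 27.
#'
#' @return An [ftdb()] database.
#' @export
worked_example_db <- function() {
  read_ftdb(fhupm_example("worked_example_transactions.csv"),
            dialect = "quantity_csv",
            items_path = fhupm_example("worked_example_items.csv"))
}

#' Bundled fuzzified demonstration database
#'
#' A fuzzy transaction database of 8 subjects over 14 clinical attribute
#' tags (`A01`..`A14`) whose quantities are 0–10 quantized membership
#' degrees and whose external utilities are all 1, so each transaction's
#' utility is simply the sum of its item utilities.
#'
#' @return An [ftdb()] database.
#' @export
fuzzy_demo_db <- function() {
  read_ftdb(fhupm_example("fuzzy_demo_transactions.csv"),
            dialect = "quantity_csv",
            items_path = fhupm_example("fuzzy_demo_items.csv"))
}

#' Bundled clinical reference ranges
#'
#' Reference ranges for 14 routine monitoring attributes (body mass index,
#' fasting blood glucose, liver enzymes, lipids, an overall health
#' assessment, ...), one row per attribute with tag, short name and the
#' lower/upper bound in the attribute's units.
#'
#' @return A tibble with columns `tag`, `name`, `lo`, `hi`.
#' @export
reference_ranges_demo <- function() {
  read_reference_ranges(fhupm_example("reference_ranges.csv"))
}

#' Bundled demonstration records
#'
#' Eight subjects' laboratory measurements over 13 attributes plus a 0/1
#' health-index label column, matching the first 13 rows of
#' [reference_ranges_demo()] by column order.
#'
#' @return A tibble.
#' @export
clinical_records_demo <- function() {
  readr::read_csv(fhupm_example("clinical_records_demo.csv"),
                  col_types = readr::cols(.default = readr::col_double()))
}
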