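#' Read a quantitative transaction database from disk
#'
#' Two plain-text dialects are supported:
#'
#' * `quantity_csv` — a transactions CSV with columns `tid,item,quantity`
#'   plus a companion items CSV with columns `item,external_utility`. This
#'   dialect round-trips an [ftdb()] exactly.
#' * `spmf_utility` — one transaction per line,
#'   `i1 i2 ... ik:TU:u1 u2 ... uk`, where `uj` is the utility of item `ij`
#'   in that transaction (internal times external utility already applied)
#'   and `TU` must equal the sum of the `uj` (validated). Databases read
#'   from this dialect carry the per-occurrence utilities as quantities with
#'   all external utilities set to 1, as is conventional for the format.
#'
#' @param path Path to the transactions file.
#' @param dialect `"quantity_csv"` or `"spmf_utility"`.
#' @param items_path For `quantity_csv`, path to the items CSV; when `NULL`
#'   every item gets external utility 1.
#' @return An [ftdb()] database. Transaction ids are taken from the file for
#'   `quantity_csv` and assigned 1..n in line order for `spmf_utility`.
#' @export
read_ftdb <- function(path, dialect = c("quantity_csv", "spmf_utility"),
                      items_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "fhupm_io_error")
  }
  if (dialect == "quantity_csv") {
    tx <- readr::read_csv(path, col_types = readr::cols(
      tid = readr::col_integer(),
      item = readr::col_character(),
      quantity = readr::col_double()
    ))
    items <- NULL
    if (!is.null(items_path)) {
      items <- readr::read_csv(items_path, col_types = readr::cols(
        item = readr::col_character(),
        external_utility = readr::col_double()
      ))
    }
    return(ftdb(tx, items))
  }
  read_spmf_utility(path)
}

read_spmf_utility <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(ftdb(tibble::tibble()))
  parsed <- purrr::imap(lines, function(line, lineno) {
    parts <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      rlang::abort(sprintf("line %d: expected 'items:TU:utilities' with 2 colons", lineno),
                   class = "fhupm_parse_error")
    }
    items <- strsplit(trimws(parts[[1]]), "\\s+")[[1]]
    utils_chr <- strsplit(trimws(parts[[3]]), "\\s+")[[1]]
    tu <- suppressWarnings(as.numeric(trimws(parts[[2]])))
    u <- suppressWarnings(as.numeric(utils_chr))
    if (is.na(tu) || anyNA(u)) {
      rlang::abort(sprintf("line %d: non-numeric utility", lineno),
                   class = "fhupm_parse_error")
    }
    if (length(items) != length(u)) {
      rlang::abort(sprintf("line %d: %d items but %d utilities",
                           lineno, length(items), length(u)),
                   class = "fhupm_parse_error")
    }
    if (any(u < 0)) {
      rlang::abort(sprintf("line %d: negative utility", lineno),
                   class = "fhupm_validation_error")
    }
    if (abs(sum(u) - tu) > 1e-9) {
      rlang::abort(sprintf("line %d: transaction utility %s does not match sum %s",
                           lineno, format(tu), format(sum(u))),
                   class = "fhupm_validation_error")
    }
    tibble::tibble(tid = lineno, item = items, quantity = u)
  })
  ftdb(dplyr::bind_rows(parsed))
}

fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Write a quantitative transaction database to disk
#'
#' Emits either dialect accepted by [read_ftdb()], with deterministic
#' (bit-stable) ordering: transactions in tid order, items within a
#' transaction in their stored order, item-table rows sorted by item.
#' Reading back a `quantity_csv` file reproduces the database exactly;
#' the `spmf_utility` dialect preserves per-occurrence utilities but folds
#' external utilities into them.
#'
#' @inheritParams read_ftdb
#' @param db An [ftdb()] database.
#' @return `path`, invisibly.
#' @export
write_ftdb <- function(db, path, dialect = c("quantity_csv", "spmf_utility"),
                       items_path = NULL) {
  assert_ftdb(db)
  dialect <- match.arg(dialect)
  if (dialect == "quantity_csv") {
    readr::write_csv(db$transactions, path)
    if (!is.null(items_path)) readr::write_csv(db$items, items_path)
    return(invisible(path))
  }
  e <- db_entries(db)
  lines <- purrr::map_chr(split(e, e$tid), function(g) {
    paste0(paste(g$item, collapse = " "), ":", fmt_num(sum(g$utility)), ":",
           paste(fmt_num(g$utility), collapse = " "))
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write and read mined itemsets
#'
#' Results are stored one itemset per line in the widely used
#' `ITEM1 ITEM2 #UTIL: value` convention, sorted lexicographically by
#' itemset so files diff cleanly.
#'
#' @param result A mining result (see [mine_hui()]) or any tibble with
#'   columns `itemset` and `utility`.
#' @param path Output file path.
#' @return `write_result()` returns `path` invisibly; `read_result()`
#'   returns a tibble with columns `itemset`, `items` and `utility`.
#' @export
write_result <- function(result, path) {
  stopifnot(all(c("itemset", "utility") %in% names(result)))
  res <- dplyr::arrange(tibble::as_tibble(result), .data$itemset)
  lines <- if (nrow(res)) paste0(res$itemset, " #UTIL: ", fmt_num(res$utility))
           else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(itemset = character(), items = list(),
                          utility = double()))
  }
  m <- regmatches(lines, regexec("^(.*) #UTIL: *([-0-9.eE+]+) *$", lines))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) {
    rlang::abort(sprintf("line %d: not a '<items> #UTIL: <value>' line", bad[[1]]),
                 class = "fhupm_parse_error")
  }
  tibble::tibble(
    itemset = vapply(m, function(x) trimws(x[[2]]), character(1)),
    items = lapply(m, function(x) strsplit(trimws(x[[2]]), "\\s+")[[1]]),
    utility = vapply(m, function(x) as.numeric(x[[3]]), numeric(1))
  )
}
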