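#' Build a quantitative transaction database
#'
#' A quantitative transaction database pairs a long table of
#' (transaction, item, quantity) entries with a per-item table of external
#' utilities (profits, weights, or clinical importance scores). The utility
#' of an item occurrence is its quantity (internal utility) times the item's
#' external utility; all higher-level quantities — transaction utility,
#' itemset utility, transaction-weighted utility (TWU) — derive from that
#' product.
#'
#' @param transactions A data frame with columns `tid` (positive integer
#'   transaction identifier), `item` (item identifier, coerced to character)
#'   and `quantity` (non-negative internal utility). Within one transaction
#'   an item may appear at most once. Row order within a transaction is
#'   preserved and used as the transaction's item order.
#' @param items Optional data frame with columns `item` and
#'   `external_utility` (non-negative). Every item referenced by
#'   `transactions` must be covered; items may carry entries even if they
#'   occur in no transaction. When `NULL`, every occurring item gets
#'   external utility 1.
#'
#' @return An object of class `ftdb`: a list with tibbles `$transactions`
#'   and `$items`.
#' @examples
#' db <- ftdb(
#'   tibble::tibble(tid = c(1, 1, 2), item = c("A", "B", "A"),
#'                  quantity = c(2, 1, 3)),
#'   tibble::tibble(item = c("A", "B"), external_utility = c(5, 2))
#' )
#' transaction_utility(db, 1)
#' @export
ftdb <- function(transactions, items = NULL) {
  if (!is.data.frame(transactions)) {
    rlang::abort("`transactions` must be a data frame")
  }
  tx <- tibble::as_tibble(transactions)
  if (nrow(tx) == 0L) {
    tx <- tibble::tibble(tid = integer(), item = character(), quantity = double())
  }
  missing_cols <- setdiff(c("tid", "item", "quantity"), names(tx))
  if (length(missing_cols)) {
    rlang::abort(paste0("`transactions` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  tx <- dplyr::select(tx, dplyr::all_of(c("tid", "item", "quantity")))
  tx$tid <- as.integer(tx$tid)
  tx$item <- as.character(tx$item)
  tx$quantity <- as.numeric(tx$quantity)
  if (anyNA(tx$tid) || any(tx$tid < 1L)) {
    rlang::abort("transaction ids must be positive integers",
                 class = "fhupm_validation_error")
  }
  if (anyNA(tx$quantity) || any(!is.finite(tx$quantity)) || any(tx$quantity < 0)) {
    rlang::abort("quantities must be finite and non-negative",
                 class = "fhupm_validation_error")
  }
  dup <- dplyr::filter(dplyr::count(tx, .data$tid, .data$item), .data$n > 1L)
  if (nrow(dup)) {
    rlang::abort(sprintf("duplicate item '%s' in transaction %d",
                         dup$item[[1]], dup$tid[[1]]),
                 class = "fhupm_validation_error")
  }
  if (is.null(items)) {
    it <- tibble::tibble(item = sort(unique(tx$item), method = "radix"),
                         external_utility = rep(1, dplyr::n_distinct(tx$item)))
  } else {
    if (!is.data.frame(items) || !all(c("item", "external_utility") %in% names(items))) {
      rlang::abort("`items` must have columns `item` and `external_utility`")
    }
    it <- tibble::as_tibble(items)[, c("item", "external_utility")]
    it$item <- as.character(it$item)
    it$external_utility <- as.numeric(it$external_utility)
    if (anyNA(it$external_utility) || any(it$external_utility < 0)) {
      rlang::abort("external utilities must be non-negative",
                   class = "fhupm_validation_error")
    }
    if (anyDuplicated(it$item)) {
      rlang::abort("duplicate entries in the item table",
                   class = "fhupm_validation_error")
    }
    uncovered <- setdiff(unique(tx$item), it$item)
    if (length(uncovered)) {
      rlang::abort(paste0("items without an external utility entry: ",
                          paste(uncovered, collapse = ", ")),
                   class = "fhupm_validation_error")
    }
    it <- dplyr::arrange(it, .data$item)
  }
  tx <- dplyr::arrange(tx, .data$tid, dplyr::row_number())
  structure(list(transactions = tx, items = it), class = "ftdb")
}

#' @export
print.ftdb <- function(x, ...) {
  cat(sprintf("<ftdb: %d transactions, %d items, total utility %s>\n",
              dplyr::n_distinct(x$transactions$tid), nrow(x$items),
              format(total_utility(x))))
  print(x$transactions, ...)
  invisible(x)
}

is_ftdb <- function(x) inherits(x, "ftdb")

assert_ftdb <- function(db) {
  if (!is_ftdb(db)) rlang::abort("expected an `ftdb` object")
  invisible(db)
}

# long table of entries with the per-occurrence utility column attached
db_entries <- function(db) {
  dplyr::mutate(
    dplyr::left_join(db$transactions, db$items, by = "item"),
    utility = .data$quantity * .data$external_utility
  )
}

#' Utility of a single item occurrence
#'
#' Returns the utility contributed by `item` in transaction `tid`:
#' internal utility (quantity) times the item's external utility. Absence of
#' the item from the transaction is an error, distinguishable from a genuine
#' zero utility (e.g. zero external utility).
#'
#' @param db An [ftdb()] database.
#' @param item Item identifier.
#' @param tid Transaction identifier.
#' @return A single number.
#' @export
item_utility <- function(db, item, tid) {
  assert_ftdb(db)
  row <- dplyr::filter(db$transactions, .data$tid == !!as.integer(tid),
                       .data$item == !!as.character(item))
  if (nrow(row) == 0L) {
    rlang::abort(sprintf("item '%s' is not present in transaction %s", item, tid),
                 class = "fhupm_item_absent")
  }
  eu <- db$items$external_utility[match(as.character(item), db$items$item)]
  row$quantity[[1]] * eu
}

#' Utility of an itemset within one transaction
#'
#' Sum of [item_utility()] over the members of `itemset` in transaction
#' `tid`. Every member must be present; otherwise a non-containment error is
#' signalled.
#'
#' @inheritParams item_utility
#' @param itemset Character vector of item identifiers (non-empty).
#' @return A single number.
#' @export
itemset_utility_in <- function(db, itemset, tid) {
  assert_ftdb(db)
  itemset <- unique(as.character(itemset))
  if (length(itemset) == 0L) rlang::abort("`itemset` must be non-empty")
  rows <- dplyr::filter(db_entries(db), .data$tid == !!as.integer(tid),
                        .data$item %in% itemset)
  if (nrow(rows) < length(itemset)) {
    rlang::abort(sprintf("transaction %s does not contain {%s}", tid,
                         paste(itemset, collapse = ", ")),
                 class = "fhupm_not_contained")
  }
  sum(rows$utility)
}

# tids of the transactions containing every member of `itemset`
tids_containing <- function(db, itemset) {
  itemset <- unique(as.character(itemset))
  hits <- dplyr::count(dplyr::filter(db$transactions, .data$item %in% itemset),
                       .data$tid)
  hits$tid[hits$n == length(itemset)]
}

#' Utility of an itemset in the whole database
#'
#' Sum of the itemset's per-transaction utility over every transaction that
#' contains all its members. An itemset contained nowhere (including one
#' referencing unknown items) has utility 0.
#'
#' @inheritParams itemset_utility_in
#' @return A single number.
#' @export
itemset_utility <- function(db, itemset) {
  assert_ftdb(db)
  itemset <- unique(as.character(itemset))
  if (length(itemset) == 0L) rlang::abort("`itemset` must be non-empty")
  tids <- tids_containing(db, itemset)
  if (length(tids) == 0L) return(0)
  e <- db_entries(db)
  sum(e$utility[e$tid %in% tids & e$item %in% itemset])
}

#' Transaction utilities
#'
#' `transaction_utilities()` returns the utility of every transaction as a
#' tibble; `transaction_utility()` returns the utility of one transaction
#' (0 for an empty or unknown transaction id).
#'
#' @inheritParams item_utility
#' @return A tibble with columns `tid` and `tu`, or a single number.
#' @export
transaction_utilities <- function(db) {
  assert_ftdb(db)
  dplyr::summarise(dplyr::group_by(db_entries(db), .data$tid),
                   tu = sum(.data$utility), .groups = "drop")
}

#' @rdname transaction_utilities
#' @export
transaction_utility <- function(db, tid) {
  assert_ftdb(db)
  e <- db_entries(db)
  sum(e$utility[e$tid == as.integer(tid)])
}

#' Support count of an itemset
#'
#' Number of transactions containing every member of the itemset.
#'
#' @inheritParams itemset_utility
#' @return A single integer.
#' @export
support_count <- function(db, itemset) {
  assert_ftdb(db)
  itemset <- unique(as.character(itemset))
  if (length(itemset) == 0L) rlang::abort("`itemset` must be non-empty")
  length(tids_containing(db, itemset))
}

#' Transaction-weighted utility (TWU)
#'
#' The TWU of an itemset is the sum of the full transaction utilities of the
#' transactions containing it. TWU over-estimates the itemset's exact
#' utility and is anti-monotone, which makes it the standard pruning bound:
#' if TWU(X) falls below the minimum-utility threshold, no superset of X can
#' be a high-utility itemset.
#'
#' @inheritParams itemset_utility
#' @return A single number.
#' @export
twu <- function(db, itemset) {
  assert_ftdb(db)
  itemset <- unique(as.character(itemset))
  if (length(itemset) == 0L) rlang::abort("`itemset` must be non-empty")
  tids <- tids_containing(db, itemset)
  if (length(tids) == 0L) return(0)
  tu <- transaction_utilities(db)
  sum(tu$tu[tu$tid %in% tids])
}

#' Per-item TWU table
#'
#' TWU of every item in the database (items occurring in no transaction get
#' TWU 0), as a tibble sorted ascending by TWU with lexicographic
#' tie-breaks — the canonical processing order of the miners.
#'
#' @inheritParams item_utility
#' @return A tibble with columns `item` and `twu`.
#' @export
item_twu <- function(db) {
  assert_ftdb(db)
  tu <- transaction_utilities(db)
  occ <- dplyr::distinct(db$transactions, .data$tid, .data$item)
  per <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(occ, tu, by = "tid"), .data$item),
    twu = sum(.data$tu), .groups = "drop"
  )
  out <- dplyr::left_join(db$items["item"], per, by = "item")
  out$twu[is.na(out$twu)] <- 0
  dplyr::arrange(out, .data$twu, .data$item)
}

#' Total utility of a database
#'
#' Sum of all transaction utilities; the base against which fractional
#' minimum-utility thresholds are resolved.
#'
#' @inheritParams item_utility
#' @return A single number.
#' @export
total_utility <- function(db) {
  assert_ftdb(db)
  sum(db_entries(db)$utility)
}

#' Reorganize a database for mining
#'
#' Removes every item whose TWU is below `min_util` (such items cannot take
#' part in any high-utility itemset) and sorts the items of every
#' transaction ascending by TWU, breaking ties lexicographically. The
#' resulting global item order is attached as an attribute and shared by
#' the tree and utility-list miners.
#'
#' @inheritParams item_utility
#' @param min_util Minimum utility threshold (absolute, `>= 0`). Items with
#'   TWU exactly equal to the threshold are kept.
#' @return An `ftdb` with additional class `ftdb_reorg` and attributes
#'   `item_order` (character vector, ascending TWU), `item_twu` (tibble) and
#'   `min_util`.
#' @export
reorganize <- function(db, min_util) {
  assert_ftdb(db)
  if (!is.numeric(min_util) || length(min_util) != 1L || min_util < 0) {
    rlang::abort("`min_util` must be a single non-negative number")
  }
  tw <- item_twu(db)
  tw <- dplyr::filter(tw, .data$twu >= min_util)
  item_order <- tw$item
  tx <- dplyr::filter(db$transactions, .data$item %in% item_order)
  if (nrow(tx)) {
    tx <- dplyr::arrange(dplyr::mutate(tx, .rank = match(.data$item, item_order)),
                         .data$tid, .data$.rank)
    tx$.rank <- NULL
  }
  out <- ftdb(tx, dplyr::filter(db$items, .data$item %in% item_order))
  class(out) <- c("ftdb_reorg", class(out))
  attr(out, "item_order") <- item_order
  attr(out, "item_twu") <- tw
  attr(out, "min_util") <- min_util
  out
}

#' @export
print.ftdb_reorg <- function(x, ...) {
  cat(sprintf("<reorganized ftdb: min_util %s, item order: %s>\n",
              format(attr(x, "min_util")),
              paste(attr(x, "item_order"), collapse = " < ")))
  NextMethod()
}

# ensure a reorganized database, reusing one if already supplied
as_reorg <- function(db, min_util) {
  if (inherits(db, "ftdb_reorg") && identical(attr(db, "min_util"), min_util)) {
    return(db)
  }
  reorganize(db, min_util)
}

# wide tid x item matrices of presence and per-occurrence utility;
# backbone of the brute-force oracle and candidate verification
utility_matrix <- function(db) {
  e <- db_entries(db)
  tids <- sort(unique(e$tid))
  items <- sort(unique(e$item), method = "radix")
  U <- matrix(0, nrow = length(tids), ncol = length(items),
              dimnames = list(as.character(tids), items))
  P <- matrix(FALSE, nrow = length(tids), ncol = length(items),
              dimnames = list(as.character(tids), items))
  ii <- cbind(match(e$tid, tids), match(e$item, items))
  U[ii] <- e$utility
  P[ii] <- TRUE
  list(U = U, P = P, tids = tids, items = items)
}

# amortized-growth accumulator for (itemset, value) emissions; avoids the
# cost of binding one-row tibbles inside the mining recursions
new_accumulator <- function() {
  e <- new.env(parent = emptyenv())
  e$items <- vector("list", 64L)
  e$value <- numeric(64L)
  e$n <- 0L
  e$add <- function(items, value) {
    n <- e$n + 1L
    if (n > length(e$items)) {
      length(e$items) <- 2L * length(e$items)
      length(e$value) <- 2L * length(e$value)
    }
    e$items[[n]] <- items
    e$value[[n]] <- value
    e$n <- n
  }
  e$collect <- function(value_col, with_size = FALSE) {
    items <- e$items[seq_len(e$n)]
    out <- tibble::tibble(
      itemset = vapply(items, paste, character(1), collapse = " "),
      items = items
    )
    if (with_size) out$size <- lengths(items)
    out[[value_col]] <- e$value[seq_len(e$n)]
    out
  }
  e
}

# exact utilities of many itemsets in one pass over the wide matrices
exact_utilities <- function(db, itemsets) {
  um <- utility_matrix(db)
  vapply(itemsets, function(its) {
    if (!all(its %in% um$items)) return(0)
    cols <- match(its, um$items)
    inside <- if (length(cols) == 1L) um$P[, cols] else
      rowSums(um$P[, cols, drop = FALSE]) == length(cols)
    if (!any(inside)) return(0)
    sum(um$U[inside, cols, drop = FALSE])
  }, numeric(1))
}
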