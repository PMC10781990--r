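#' @name utility_list
#' @title Utility lists
#'
#' @description
#' The one-phase miner represents each itemset vertically by a utility
#' list: one entry per containing transaction with the transaction id, the
#' itemset's exact utility there (`iutil`), and the remaining utility
#' (`rutil`) — the summed utility of the items ordered *after* the
#' itemset's last item in that transaction's ascending-TWU order. The sum
#' of `iutil` over the entries is the itemset's exact database utility, and
#' `sum(iutil) + sum(rutil)` bounds the utility of every extension, giving
#' the remaining-utility pruning rule.
NULL

new_utility_list <- function(itemset, entries, last_rank) {
  structure(list(itemset = itemset,
                 entries = entries,
                 last_rank = last_rank,
                 sum_iutils = sum(entries$iutil),
                 sum_rutils = sum(entries$rutil)),
            class = "utility_list")
}

#' @export
print.utility_list <- function(x, ...) {
  cat(sprintf("<utility_list {%s}: sum_iutils %s, sum_rutils %s>\n",
              paste(x$itemset, collapse = ","), fmt_num(x$sum_iutils),
              fmt_num(x$sum_rutils)))
  print(x$entries, ...)
  invisible(x)
}

#' Build single-item utility lists and the EUCS
#'
#' Second database scan of the one-phase miner: for every promising item
#' (those surviving [reorganize()]) an initial utility list is built under
#' the reorganized ascending-TWU order, and the estimated-utility
#' co-occurrence structure (EUCS) is filled. The EUCS maps each unordered
#' item pair to its pairwise TWU — the sum of transaction utilities over
#' the transactions containing both items; absent pairs mean 0.
#'
#' @param reorg A reorganized database from [reorganize()].
#' @return A list with `lists` (named list of `utility_list` objects in
#'   ascending-TWU order) and `eucs` (an `eucs` object, see
#'   [eucs_value()]).
#' @export
build_initial_lists <- function(reorg) {
  if (!inherits(reorg, "ftdb_reorg")) {
    rlang::abort("`reorg` must come from reorganize()")
  }
  item_order <- attr(reorg, "item_order")
  e <- db_entries(reorg)
  eucs <- new.env(parent = emptyenv())
  groups <- split(e, e$tid)
  per_item <- lapply(stats::setNames(item_order, item_order),
                     function(i) list(tid = integer(), iutil = double(),
                                      rutil = double()))
  for (g in groups) {
    u <- g$utility
    # utility of the items ordered after each position (ascending TWU order)
    rut <- rev(cumsum(rev(u))) - u
    tu <- sum(u)
    for (k in seq_len(nrow(g))) {
      it <- g$item[[k]]
      per_item[[it]]$tid <- c(per_item[[it]]$tid, g$tid[[k]])
      per_item[[it]]$iutil <- c(per_item[[it]]$iutil, u[[k]])
      per_item[[it]]$rutil <- c(per_item[[it]]$rutil, rut[[k]])
    }
    if (nrow(g) > 1L) {
      prs <- utils::combn(sort(g$item, method = "radix"), 2L)
      for (p in seq_len(ncol(prs))) {
        key <- paste(prs[1L, p], prs[2L, p], sep = "\r")
        eucs[[key]] <- (if (is.null(eucs[[key]])) 0 else eucs[[key]]) + tu
      }
    }
  }
  lists <- purrr::imap(per_item, function(v, it) {
    new_utility_list(it, tibble::tibble(tid = v$tid, iutil = v$iutil,
                                        rutil = v$rutil),
                     last_rank = match(it, item_order))
  })
  structure_eucs <- structure(list(pairs = eucs), class = "eucs")
  list(lists = lists, eucs = structure_eucs)
}

#' Pairwise co-occurrence utility (EUCS) lookups
#'
#' `eucs_value()` returns the pairwise TWU of an unordered item pair (0 for
#' never co-occurring pairs); `eucs_table()` lists all stored pairs as a
#' tibble; `eucp_check()` is the co-occurrence pruning rule: an extension
#' joining items `x` and `y` is worth attempting only if their pairwise TWU
#' reaches `min_util`, since that pairwise TWU bounds the utility of every
#' itemset containing both.
#'
#' @param eucs An `eucs` object from [build_initial_lists()].
#' @param x,y Item identifiers.
#' @param min_util Minimum utility threshold.
#' @return A number, a tibble, or a logical (`TRUE` = may extend).
#' @export
eucs_value <- function(eucs, x, y) {
  stopifnot(inherits(eucs, "eucs"))
  ab <- sort(c(as.character(x), as.character(y)), method = "radix")
  v <- eucs$pairs[[paste(ab[[1]], ab[[2]], sep = "\r")]]
  if (is.null(v)) 0 else v
}

#' @rdname eucs_value
#' @export
eucs_table <- function(eucs) {
  stopifnot(inherits(eucs, "eucs"))
  keys <- ls(eucs$pairs)
  if (length(keys) == 0L) {
    return(tibble::tibble(item_a = character(), item_b = character(),
                          twu = double()))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  dplyr::arrange(tibble::tibble(
    item_a = vapply(parts, `[[`, character(1), 1L),
    item_b = vapply(parts, `[[`, character(1), 2L),
    twu = vapply(keys, function(k) eucs$pairs[[k]], numeric(1))
  ), .data$item_a, .data$item_b)
}

#' @rdname eucs_value
#' @export
eucp_check <- function(eucs, x, y, min_util) {
  eucs_value(eucs, x, y) >= min_util
}

#' Join two utility lists
#'
#' Builds the utility list of itemset `P + {x, y}` from the lists of
#' `Px = P + {x}` and `Py = P + {y}`, where both share the prefix `P` and
#' `y` follows `x` in the global ascending-TWU order. Entries intersect on
#' transaction id; per shared transaction the new `iutil` is
#' `iutil(Px) + iutil(Py) - iutil(P)` (the prefix's utility would otherwise
#' be double-counted; 0 when `P` is empty) and the new `rutil` is taken
#' from `Py`, the later-ordered operand.
#'
#' @param px,py `utility_list` objects sharing all but their last item.
#' @param p Utility list of the shared prefix `P`, or `NULL` when the
#'   prefix is empty (k = 2 joins).
#' @return A `utility_list` for the joined itemset (possibly with zero
#'   entries when the tid sets are disjoint).
#' @export
join_lists <- function(px, py, p = NULL) {
  stopifnot(inherits(px, "utility_list"), inherits(py, "utility_list"))
  nx <- length(px$itemset); ny <- length(py$itemset)
  if (nx != ny || !identical(px$itemset[-nx], py$itemset[-ny]) ||
      py$last_rank <= px$last_rank) {
    rlang::abort("join requires lists sharing a prefix with y after x in TWU order",
                 class = "fhupm_contract_error")
  }
  ix <- match(px$entries$tid, py$entries$tid)
  keep <- which(!is.na(ix))
  tid <- px$entries$tid[keep]
  iut <- px$entries$iutil[keep] + py$entries$iutil[ix[keep]]
  if (!is.null(p)) {
    ip <- match(tid, p$entries$tid)
    iut <- iut - p$entries$iutil[ip]
  }
  new_utility_list(c(px$itemset, py$itemset[[ny]]),
                   tibble::new_tibble(list(tid = tid, iutil = iut,
                                           rutil = py$entries$rutil[ix[keep]]),
                                      nrow = length(tid)),
                   last_rank = py$last_rank)
}

#' Depth-first utility-list search
#'
#' The recursive core of the one-phase miner. For each extension list the
#' itemset is emitted when its exact utility (`sum_iutils`) reaches
#' `min_util`; the search descends into its extensions only when
#' `sum_iutils + sum_rutils` still reaches the threshold
#' (remaining-utility pruning) and, when an EUCS is supplied, the
#' co-occurrence check [eucp_check()] passes for the pair of items being
#' joined. Utilities are exact throughout — no verification phase is
#' needed.
#'
#' @param prefix_list `utility_list` of the current prefix, or `NULL` at
#'   the root.
#' @param extension_lists List of `utility_list` extensions of the prefix,
#'   ordered ascending by TWU.
#' @param min_util Minimum utility threshold.
#' @param eucs An `eucs` object, or `NULL` to disable co-occurrence
#'   pruning (the result is identical either way; only the number of join
#'   attempts changes).
#' @param sink Function called as `sink(items, utility)` for every emitted
#'   high-utility itemset.
#' @return The number of list joins performed, invisibly.
#' @export
fhm_search <- function(prefix_list, extension_lists, min_util, eucs = NULL,
                       sink) {
  joins <- new.env(parent = emptyenv())
  joins$n <- 0L
  fhm_rec(prefix_list, extension_lists, min_util, eucs, sink, joins)
  invisible(joins$n)
}

fhm_rec <- function(p, exts, min_util, eucs, sink, joins) {
  n <- length(exts)
  for (i in seq_len(n)) {
    x <- exts[[i]]
    if (x$sum_iutils >= min_util) {
      sink(x$itemset, x$sum_iutils)
    }
    if (x$sum_iutils + x$sum_rutils >= min_util && i < n) {
      new_exts <- list()
      xi <- x$itemset[[length(x$itemset)]]
      for (j in seq.int(i + 1L, n)) {
        y <- exts[[j]]
        yj <- y$itemset[[length(y$itemset)]]
        if (!is.null(eucs) && !eucp_check(eucs, xi, yj, min_util)) next
        joins$n <- joins$n + 1L
        xy <- join_lists(x, y, p)
        if (nrow(xy$entries)) new_exts <- c(new_exts, list(xy))
      }
      if (length(new_exts)) fhm_rec(x, new_exts, min_util, eucs, sink, joins)
    }
  }
  invisible()
}

# full one-phase pipeline; returns result + counters
list_mine <- function(db, min_util, use_eucp = TRUE) {
  reorg <- as_reorg(db, min_util)
  init <- build_initial_lists(reorg)
  acc <- new_accumulator()
  sink <- function(items, utility) acc$add(sort(items, method = "radix"),
                                           utility)
  joins <- fhm_search(NULL, unname(init$lists), min_util,
                      eucs = if (use_eucp) init$eucs else NULL, sink)
  res <- acc$collect("utility", with_size = TRUE)
  list(result = dplyr::arrange(res, .data$itemset),
       counters = c(candidates = 0L, nodes = 0L, joins = joins,
                    switches = 0L),
       init = init, reorg = reorg)
}
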