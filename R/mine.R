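#' Mine high-utility itemsets
#'
#' Discovers every itemset whose exact utility reaches the minimum-utility
#' threshold, in one of three interchangeable modes:
#'
#' * `"tree"` — two-phase: build a UP-Tree over the reorganized database,
#'   generate candidates from overestimated node utilities by pattern
#'   growth, then verify candidates against exact utilities in one extra
#'   scan.
#' * `"list"` — one-phase: utility-list joins with remaining-utility and
#'   co-occurrence (EUCS) pruning; utilities are exact throughout.
#' * `"adaptive"` — hybrid: the search starts in the tree phase and, per
#'   promising 1-itemset prefix, switches to utility-list mining of that
#'   prefix's subtree when the prefix's overestimated utility clears
#'   `switch_factor * min_util`; prefixes that do not clear it stay in the
#'   tree phase (candidate growth plus verification).
#'
#' All three modes return identical itemset-utility maps; they differ only
#' in the work performed, visible through the counters in [glance()].
#'
#' @param db An [ftdb()] database (possibly a fuzzified one from
#'   [fuzzify_table()]).
#' @param min_util Absolute minimum utility threshold. Supply exactly one
#'   of `min_util` and `min_util_frac`.
#' @param min_util_frac Threshold as a fraction in `(0, 1]` of the total
#'   database utility.
#' @param mode `"adaptive"`, `"tree"` or `"list"`.
#' @param switch_factor Non-negative multiplier in the adaptive switch
#'   rule; `0` degenerates to pure list mining, `Inf` to pure tree mining
#'   (results are unchanged either way).
#' @param use_eucp Enable co-occurrence pruning in the list phase. Purely
#'   an efficiency lever; the mined set is identical with it off.
#' @return A tibble of class `hui_result` with columns `itemset`
#'   (space-joined sorted items), `items` (list), `size`, `utility`,
#'   sorted by `itemset`; counters and settings are attached and available
#'   via [glance()].
#' @examples
#' db <- worked_example_db()
#' res <- mine_hui(db, min_util = 100)
#' res
#' glance(res)
#' @export
mine_hui <- function(db, min_util = NULL, min_util_frac = NULL,
                     mode = c("adaptive", "tree", "list"),
                     switch_factor = 1, use_eucp = TRUE) {
  assert_ftdb(db)
  mode <- match.arg(mode)
  if (is.null(min_util) == is.null(min_util_frac)) {
    rlang::abort("supply exactly one of `min_util` and `min_util_frac`")
  }
  if (!is.null(min_util_frac)) {
    if (min_util_frac <= 0 || min_util_frac > 1) {
      rlang::abort("`min_util_frac` must lie in (0, 1]")
    }
    min_util <- min_util_frac * total_utility(db)
  }
  if (min_util < 0) rlang::abort("`min_util` must be non-negative")
  out <- switch(mode,
    tree = tree_mine(db, min_util),
    list = list_mine(db, min_util, use_eucp = use_eucp),
    adaptive = adaptive_mine(db, min_util, switch_factor = switch_factor,
                             use_eucp = use_eucp)
  )
  new_hui_result(out$result, counters = out$counters, min_util = min_util,
                 mode = mode)
}

new_hui_result <- function(tbl, counters, min_util, mode) {
  tibble::new_tibble(tbl, nrow = nrow(tbl), class = "hui_result",
                     counters = counters, min_util = min_util, mode = mode)
}

#' @export
print.hui_result <- function(x, ...) {
  cat(sprintf("# High-utility itemsets: %d (mode %s, min_util %s)\n",
              nrow(x), attr(x, "mode"), fmt_num(attr(x, "min_util"))))
  NextMethod()
}

#' The adaptive switch rule
#'
#' Decides, for a promising 1-itemset prefix, whether the hybrid miner
#' leaves the tree phase and mines the prefix's projected subtree with
#' utility lists: switch when the prefix's overestimated utility reaches
#' `switch_factor * min_util`. With `switch_factor = 1` this is precisely
#' "switch once the upper bound clears the minimum-utility threshold".
#'
#' @param overestimate The prefix's overestimated utility (sum of `nu`
#'   over the item's node-link chain).
#' @param min_util Minimum utility threshold.
#' @param switch_factor Non-negative multiplier; see [mine_hui()].
#' @return `TRUE` to switch to list mining for this prefix.
#' @export
switch_decision <- function(overestimate, min_util, switch_factor = 1) {
  thr <- switch_factor * min_util
  if (is.nan(thr)) thr <- if (switch_factor >= 1) Inf else 0  # Inf * 0
  overestimate >= thr
}

adaptive_mine <- function(db, min_util, switch_factor = 1, use_eucp = TRUE) {
  reorg <- as_reorg(db, min_util)
  tree <- build_up_tree(reorg)
  init <- build_initial_lists(reorg)
  order_asc <- attr(reorg, "item_order")
  eucs <- if (use_eucp) init$eucs else NULL

  acc <- new_accumulator()
  sink <- function(items, utility) acc$add(sort(items, method = "radix"),
                                           utility)
  cand <- new_accumulator()
  emit_cand <- function(items, oe) cand$add(sort(items, method = "radix"), oe)

  joins <- 0L
  switches <- 0L
  for (idx in seq_along(order_asc)) {
    it <- order_asc[[idx]]
    nodes <- item_nodes(tree, it)
    if (length(nodes) == 0L) next
    oe <- sum(vapply(nodes, function(n) n$nu, numeric(1)))
    if (oe < min_util) next
    if (switch_decision(oe, min_util, switch_factor)) {
      # list phase for this prefix's projected view
      switches <- switches + 1L
      ul <- init$lists[[it]]
      if (ul$sum_iutils >= min_util) sink(ul$itemset, ul$sum_iutils)
      if (ul$sum_iutils + ul$sum_rutils >= min_util &&
          idx < length(order_asc)) {
        exts <- list()
        for (jdx in seq.int(idx + 1L, length(order_asc))) {
          y <- init$lists[[order_asc[[jdx]]]]
          if (!is.null(eucs) && !eucp_check(eucs, it, y$itemset[[1]], min_util)) next
          joins <- joins + 1L
          xy <- join_lists(ul, y, NULL)
          if (nrow(xy$entries)) exts <- c(exts, list(xy))
        }
        if (length(exts)) {
          joins <- joins + fhm_search(ul, exts, min_util, eucs, sink)
        }
      }
    } else {
      # stay in the tree phase: grow candidates anchored at this prefix
      paths <- lapply(nodes, function(n) list(items = path_above(n), nu = n$nu))
      emit_cand(it, oe)
      mine_paths(it, paths, min_util, tree$header$item, emit_cand)
    }
  }
  cands <- cand$collect("overestimate")
  verified <- verify_candidates(cands, reorg, min_util)
  res <- dplyr::bind_rows(acc$collect("utility", with_size = TRUE), verified)
  list(result = dplyr::arrange(res, .data$itemset),
       counters = c(candidates = nrow(cands), nodes = tree$n_nodes$n,
                    joins = joins, switches = switches))
}

#' Brute-force high-utility itemset oracle
#'
#' Enumerates every non-empty itemset over the occurring items and keeps
#' those whose directly computed utility reaches `min_util`. Only itemsets
#' contained in at least one transaction are reported, so a threshold of 0
#' returns exactly the occurring itemsets rather than the full power set
#' (never-occurring itemsets have utility 0 and are of no interest).
#' Exponential in
#' the number of distinct items, so guarded; intended as an independent
#' reference for validating the miners on small databases, and useful in
#' its own right at desk scale.
#'
#' @inheritParams mine_hui
#' @param min_util Absolute minimum utility threshold.
#' @param max_items Refuse databases with more distinct occurring items
#'   than this (default 20).
#' @return A `hui_result` tibble, identical in shape to [mine_hui()]'s.
#' @export
brute_force_hui <- function(db, min_util, max_items = 20L) {
  assert_ftdb(db)
  um <- utility_matrix(db)
  k <- length(um$items)
  if (k > max_items) {
    rlang::abort(sprintf("%d distinct items exceed the brute-force guard of %d",
                         k, max_items),
                 class = "fhupm_guard_error")
  }
  acc <- new_accumulator()
  if (k > 0L) {
    for (size in seq_len(k)) {
      sets <- utils::combn(um$items, size, simplify = FALSE)
      for (its in sets) {
        cols <- match(its, um$items)
        inside <- if (size == 1L) um$P[, cols] else
          rowSums(um$P[, cols, drop = FALSE]) == size
        if (!any(inside)) next
        u <- sum(um$U[inside, cols, drop = FALSE])
        if (u >= min_util) acc$add(its, u)
      }
    }
  }
  res <- acc$collect("utility", with_size = TRUE)
  new_hui_result(dplyr::arrange(res, .data$itemset),
                 counters = c(candidates = 0L, nodes = 0L, joins = 0L,
                              switches = 0L),
                 min_util = min_util, mode = "brute_force")
}

#' Render mined itemsets as fuzzy rules
#'
#' Translates each mined itemset over fuzzy items (`NAME.L`, `NAME.M`,
#' `NAME.H`) into a human-readable conjunction, e.g.
#' `"if BMI is High and FBG is High (utility=46)"`. Items that do not carry
#' the fuzzy suffix are rendered by their raw identifiers. When a
#' reference-range table is supplied, conjuncts follow its attribute (tag)
#' order; otherwise they keep the itemset's lexicographic order.
#'
#' @param result A `hui_result` or tibble with columns `items` and
#'   `utility`.
#' @param ranges Optional reference-range table (`tag`, `name`).
#' @return A tibble with columns `itemset`, `rule`, `utility`.
#' @export
render_rules <- function(result, ranges = NULL) {
  stopifnot(all(c("items", "utility") %in% names(result)))
  letter_terms <- c(L = "Low", M = "Normal", H = "High")
  one <- function(items, utility) {
    m <- regmatches(items, regexec("^(.+)\\.([LMH])$", items))
    fuzzy <- vapply(m, length, integer(1)) == 3L
    name <- ifelse(fuzzy, vapply(m, function(x) x[[2]], character(1)), items)
    if (!is.null(ranges)) {
      ord <- order(match(name, ranges$name), name, method = "radix")
      items <- items[ord]; m <- m[ord]; fuzzy <- fuzzy[ord]; name <- name[ord]
    }
    conj <- ifelse(
      fuzzy,
      paste0(name, " is ",
             letter_terms[vapply(m, function(x) if (length(x) == 3L) x[[3]] else "",
                                 character(1))]),
      items)
    paste0("if ", paste(conj, collapse = " and "),
           " (utility=", fmt_num(utility), ")")
  }
  tibble::tibble(
    itemset = vapply(result$items, paste, character(1), collapse = " "),
    rule = unlist(purrr::map2(result$items, result$utility, one),
                  use.names = FALSE) %||% character(0),
    utility = result$utility
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
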