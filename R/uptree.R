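#' @name up_tree
#' @title UP-Tree construction
#'
#' @description
#' The two-phase miner compresses the reorganized database into a prefix
#' tree (UP-Tree). Transactions are inserted root-to-leaf in descending-TWU
#' item order — the reverse of the ascending order stored in the
#' reorganized transactions — so that shared high-TWU prefixes merge. Each
#' node carries a support count and an overestimated utility `nu`: on every
#' insertion a node at depth j accumulates the transaction's utility minus
#' the utilities of the items below it on the insertion path (the
#' discounted overestimate of the UP-Growth family; unpromising items'
#' utilities are already excluded because [reorganize()] removed those
#' items). A header table keyed by item, descending by TWU, threads
#' same-item nodes into a linked chain for pattern growth.
#'
#' @param reorg A reorganized database from [reorganize()], built at the
#'   same `min_util` the miner will use.
#' @return `build_up_tree()` returns an object of class `up_tree`: a list
#'   with the root node environment, a `header` (tibble with columns
#'   `item`, `twu`, descending), per-item node-link chain heads, and a
#'   node-creation counter.
NULL

new_up_node <- function(item, parent) {
  n <- new.env(parent = emptyenv())
  n$item <- item
  n$count <- 0L
  n$nu <- 0
  n$parent <- parent
  n$children <- list()
  n$link <- NULL
  n
}

#' @rdname up_tree
#' @export
build_up_tree <- function(reorg) {
  if (!inherits(reorg, "ftdb_reorg")) {
    rlang::abort("`reorg` must come from reorganize()")
  }
  order_asc <- attr(reorg, "item_order")
  tw <- attr(reorg, "item_twu")
  header <- dplyr::arrange(tw, dplyr::desc(.data$twu), dplyr::desc(.data$item))
  tree <- structure(list(
    root = new_up_node(NA_character_, NULL),
    header = header,
    heads = new.env(parent = emptyenv()),
    tails = new.env(parent = emptyenv()),
    n_nodes = new.env(parent = emptyenv())
  ), class = "up_tree")
  tree$n_nodes$n <- 0L
  e <- db_entries(reorg)
  for (g in split(e, e$tid)) {
    # stored ascending by TWU; insert descending so high-TWU items sit on top
    idx <- rev(seq_len(nrow(g)))
    up_insert(tree, g$item[idx], g$utility[idx])
  }
  tree
}

#' @rdname up_tree
#' @param tree An `up_tree`.
#' @param items Character vector of the transaction's items, ordered
#'   descending by TWU (header order, root-to-leaf).
#' @param utilities Per-item utilities of the transaction, aligned with
#'   `items`.
#' @export
up_insert <- function(tree, items, utilities) {
  stopifnot(inherits(tree, "up_tree"), length(items) == length(utilities))
  if (!all(items %in% tree$header$item)) {
    rlang::abort("transaction contains an item missing from the header",
                 class = "fhupm_contract_error")
  }
  rank <- match(items, tree$header$item)
  if (is.unsorted(rank, strictly = TRUE)) {
    rlang::abort("transaction items must follow header (descending TWU) order",
                 class = "fhupm_contract_error")
  }
  # nu at depth j accumulates TU minus the utilities of the items below j
  nu_path <- cumsum(utilities)
  node <- tree$root
  for (j in seq_along(items)) {
    it <- items[[j]]
    child <- node$children[[it]]
    if (is.null(child)) {
      child <- new_up_node(it, node)
      node$children[[it]] <- child
      tree$n_nodes$n <- tree$n_nodes$n + 1L
      # append to the item's node-link chain
      if (is.null(tree$heads[[it]])) {
        tree$heads[[it]] <- child
      } else {
        tree$tails[[it]]$link <- child
      }
      tree$tails[[it]] <- child
    }
    child$count <- child$count + 1L
    child$nu <- child$nu + nu_path[[j]]
    node <- child
  }
  invisible(tree)
}

# walk an item's node-link chain
item_nodes <- function(tree, item) {
  out <- list()
  n <- tree$heads[[item]]
  while (!is.null(n)) {
    out[[length(out) + 1L]] <- n
    n <- n$link
  }
  out
}

# items on the path from the root down to (excluding) `node`, top-down
path_above <- function(node) {
  items <- character()
  p <- node$parent
  while (!is.null(p) && !is.na(p$item)) {
    items <- c(p$item, items)
    p <- p$parent
  }
  items
}

#' Render a UP-Tree as indented text
#'
#' One line per node, `item:count:nu`, children indented under parents and
#' ordered by item — a golden-file-friendly dump for inspecting the
#' construction sequence.
#'
#' @param tree An `up_tree`.
#' @return A character vector of lines.
#' @export
format_up_tree <- function(tree) {
  stopifnot(inherits(tree, "up_tree"))
  lines <- character()
  walk <- function(node, depth) {
    if (!is.na(node$item)) {
      lines <<- c(lines, paste0(strrep("  ", depth), node$item, ":",
                                node$count, ":", fmt_num(node$nu)))
    }
    if (length(node$children)) {
      kids <- node$children[order(names(node$children), method = "radix")]
      for (k in kids) walk(k, depth + !is.na(node$item))
    }
  }
  walk(tree$root, 0L)
  lines
}

#' @export
print.up_tree <- function(x, ...) {
  cat(sprintf("<up_tree: %d nodes over %d items>\n", x$n_nodes$n, nrow(x$header)))
  cat(format_up_tree(x), sep = "\n")
  invisible(x)
}

#' Generate candidate high-utility itemsets from a UP-Tree
#'
#' Pattern growth over the header items in ascending-TWU order: for each
#' item, its conditional pattern base is gathered along the node-link chain
#' (one path per node, carrying the node's count and overestimated utility
#' `nu`), and the search recurses on the projected paths. An itemset is
#' emitted whenever its overestimate — the sum of path `nu` over the paths
#' containing it — reaches `min_util`. Because every path `nu` bounds the
#' exact utility of any sub-itemset of that path in the transactions it
#' covers, the emitted set is a superset of the true high-utility itemsets
#' and each overestimate bounds the exact utility from above.
#'
#' @param tree An `up_tree` from [build_up_tree()].
#' @param min_util Minimum utility threshold used to build the tree.
#' @return A tibble of candidates: `itemset` (space-joined key, items
#'   sorted), `items` (list column), `overestimate`.
#' @export
generate_candidates <- function(tree, min_util) {
  stopifnot(inherits(tree, "up_tree"))
  acc <- new_accumulator()
  emit <- function(items, oe) acc$add(sort(items, method = "radix"), oe)
  asc <- rev(tree$header$item)
  for (it in asc) {
    nodes <- item_nodes(tree, it)
    if (length(nodes) == 0L) next
    paths <- lapply(nodes, function(n) list(items = path_above(n), nu = n$nu))
    oe <- sum(vapply(paths, `[[`, numeric(1), "nu"))
    if (oe >= min_util) emit(it, oe)
    mine_paths(it, paths, min_util, tree$header$item, emit)
  }
  res <- acc$collect("overestimate")
  dplyr::arrange(res, .data$itemset)
}

# recursive growth over projected path lists (the conditional pattern base)
mine_paths <- function(prefix, paths, min_util, header_items, emit) {
  if (length(paths) == 0L) return(invisible())
  nus <- vapply(paths, `[[`, numeric(1), "nu")
  local_items <- unique(unlist(lapply(paths, `[[`, "items")))
  if (length(local_items) == 0L) return(invisible())
  # process extensions bottom-up: ascending TWU = reverse header order
  local_items <- local_items[order(match(local_items, header_items),
                                   decreasing = TRUE)]
  for (j in local_items) {
    has_j <- vapply(paths, function(p) j %in% p$items, logical(1))
    oe_j <- sum(nus[has_j])
    if (oe_j < min_util) next
    new_prefix <- c(prefix, j)
    emit(new_prefix, oe_j)
    sub <- lapply(paths[has_j], function(p) {
      pos <- match(j, p$items)
      list(items = p$items[seq_len(pos - 1L)], nu = p$nu)
    })
    mine_paths(new_prefix, sub, min_util, header_items, emit)
  }
  invisible()
}

#' Verify candidate itemsets against exact utilities
#'
#' The second phase of two-phase mining: one additional scan computes each
#' candidate's exact utility, and candidates whose exact utility falls
#' short of `min_util` are discarded.
#'
#' @param candidates Tibble from [generate_candidates()] (columns `itemset`,
#'   `items`; any others are ignored).
#' @param db The original (or reorganized) [ftdb()] database.
#' @param min_util Minimum utility threshold.
#' @return A tibble with columns `itemset`, `items`, `size`, `utility`.
#' @export
verify_candidates <- function(candidates, db, min_util) {
  assert_ftdb(db)
  if (nrow(candidates) == 0L) {
    return(tibble::tibble(itemset = character(), items = list(),
                          size = integer(), utility = double()))
  }
  u <- exact_utilities(db, candidates$items)
  out <- tibble::tibble(itemset = candidates$itemset, items = candidates$items,
                        size = lengths(candidates$items), utility = u)
  dplyr::arrange(dplyr::filter(out, .data$utility >= min_util), .data$itemset)
}

# full two-phase pipeline; returns result + counters
tree_mine <- function(db, min_util) {
  reorg <- as_reorg(db, min_util)
  tree <- build_up_tree(reorg)
  cands <- generate_candidates(tree, min_util)
  res <- verify_candidates(cands, reorg, min_util)
  list(result = res,
       counters = c(candidates = nrow(cands), nodes = tree$n_nodes$n,
                    joins = 0L, switches = 0L))
}
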