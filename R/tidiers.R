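#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mining result
#'
#' `tidy()` returns the mined itemsets as a plain tibble; `glance()`
#' returns a one-row summary with the threshold, mode, result size and the
#' work counters (tree nodes created, candidates generated, utility-list
#' joins performed, phase-switch events).
#'
#' @param x A `hui_result` from [mine_hui()] or [brute_force_hui()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hui_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidy.hui_result
#' @export
glance.hui_result <- function(x, ...) {
  cn <- attr(x, "counters")
  tibble::tibble(
    n_itemsets = nrow(x),
    total_utility = sum(x$utility),
    min_util = attr(x, "min_util"),
    mode = attr(x, "mode"),
    candidates = as.integer(cn[["candidates"]]),
    nodes = as.integer(cn[["nodes"]]),
    joins = as.integer(cn[["joins"]]),
    switches = as.integer(cn[["switches"]])
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), "hui_result")
  attr(x, "counters") <- NULL
  attr(x, "min_util") <- NULL
  attr(x, "mode") <- NULL
  x
}
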