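#' Generate a synthetic quantitative transaction database
#'
#' Seeded generator for miner validation: each of `n_items` items enters
#' each transaction independently with probability `density`; quantities
#' are uniform on `1..quantity_max` and external utilities uniform on
#' `1..external_max`. The same seed always reproduces the same database.
#'
#' @param n_transactions Number of transactions (0 gives an empty
#'   database; transactions that happen to draw no items are simply
#'   absent).
#' @param n_items Number of distinct items (`I01`, `I02`, ...).
#' @param density Inclusion probability in `(0, 1]`.
#' @param quantity_max,external_max Upper bounds of the uniform integer
#'   draws.
#' @param seed Integer seed; scoped so the caller's RNG state is untouched.
#' @return An [ftdb()] database.
#' @export
generate_transactions <- function(n_transactions, n_items, density = 0.3,
                                  quantity_max = 10L, external_max = 5L,
                                  seed = 1L) {
  stopifnot(n_transactions >= 0, n_items >= 1, density > 0, density <= 1,
            quantity_max >= 1, external_max >= 1)
  items <- sprintf("I%02d", seq_len(n_items))
  withr::with_seed(seed, {
    ext <- sample.int(external_max, n_items, replace = TRUE)
    tx <- purrr::map(seq_len(n_transactions), function(t) {
      inside <- stats::runif(n_items) < density
      if (!any(inside)) return(NULL)
      tibble::tibble(tid = t, item = items[inside],
                     quantity = sample.int(quantity_max, sum(inside),
                                           replace = TRUE))
    })
    ftdb(dplyr::bind_rows(tx),
         tibble::tibble(item = items, external_utility = ext))
  })
}

#' Generate a synthetic table of quantitative clinical records
#'
#' Seeded generator of subject-by-attribute measurement tables compatible
#' with [fuzzify_table()]: each attribute's values are drawn uniformly from
#' its reference range widened by `margin` times the range width on both
#' sides, so Low/Normal/High regions are all populated.
#'
#' @param n_records Number of records (rows).
#' @param ranges Reference-range table (`tag`, `name`, `lo`, `hi`).
#' @param margin Widening fraction (default 0.5): values are uniform on
#'   `[lo - margin * (hi - lo), hi + margin * (hi - lo)]`.
#' @param seed Integer seed.
#' @return A tibble with one column per attribute, named by `ranges$name`.
#' @export
generate_records <- function(n_records, ranges, margin = 0.5, seed = 1L) {
  stopifnot(n_records >= 0, is.data.frame(ranges), margin >= 0)
  withr::with_seed(seed, {
    cols <- purrr::pmap(ranges[, c("name", "lo", "hi")],
                        function(name, lo, hi) {
                          d <- margin * (hi - lo)
                          stats::runif(n_records, lo - d, hi + d)
                        })
    names(cols) <- ranges$name
    tibble::as_tibble(cols)
  })
}
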