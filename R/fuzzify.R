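#' Fuzzy partition of a clinical reference range
#'
#' Divides an attribute's value axis into three linguistic terms — Low,
#' Normal, High — around a reference range `[lo, hi]` (the interval a
#' clinician would read as "normal"). The partition is trapezoidal with
#' symmetric linear transitions of half-width `w = transition * (hi - lo) / 2`
#' centred at the two range boundaries: Low is fully 1 below `lo - w`,
#' Normal is fully 1 on `[lo + w, hi - w]`, High is fully 1 above `hi + w`.
#' Memberships of the three terms sum to 1 at every value (a Ruspini
#' partition), so a measurement's evidence is conserved when it is split
#' across neighbouring terms.
#'
#' `transition = 0` gives the crisp (indicator) partition: values below `lo`
#' are Low, values in `[lo, hi]` are Normal, values above `hi` are High.
#'
#' @param lo,hi Reference range bounds in the attribute's units, `lo < hi`.
#' @param transition Transition fraction in `[0, 1)`: the fraction of the
#'   half-range occupied by each linear crossover. Values `>= 1` make the
#'   Normal plateau vanish and are a configuration error.
#' @param tag,name Optional attribute tag (integer) and short name, carried
#'   through to fuzzy item labels.
#' @return An object of class `fuzzy_partition`.
#' @examples
#' p <- fuzzy_partition(3.2, 6.5, transition = 0.25, name = "FBG")
#' membership(p, c(4.85, 6.5, 10))
#' @export
fuzzy_partition <- function(lo, hi, transition = 0.25, tag = NA_integer_,
                            name = NA_character_) {
  if (!is.numeric(lo) || !is.numeric(hi) || !is.finite(lo) || !is.finite(hi) ||
      lo >= hi) {
    rlang::abort("need finite bounds with lo < hi", class = "fhupm_config_error")
  }
  if (!is.numeric(transition) || transition < 0 || transition >= 1) {
    rlang::abort("`transition` must lie in [0, 1): at 1 the transitions at lo and hi meet and the Normal plateau vanishes",
                 class = "fhupm_config_error")
  }
  w <- transition * (hi - lo) / 2
  structure(list(tag = as.integer(tag), name = as.character(name),
                 lo = lo, hi = hi, w = w, transition = transition),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition %s: Low < %s < Normal < %s < High, transition half-width %s>\n",
              ifelse(is.na(x$name), "", x$name), fmt_num(x$lo), fmt_num(x$hi),
              fmt_num(x$w)))
  invisible(x)
}

fuzzy_terms <- c("Low", "Normal", "High")
term_letters <- c(Low = "L", Normal = "M", High = "H")

#' Membership degrees of values in a fuzzy partition
#'
#' Evaluates the three term memberships at each value. Degrees are in
#' `[0, 1]` and sum to 1 across the terms at every value.
#'
#' @param partition A [fuzzy_partition()].
#' @param values Finite numeric vector of attribute values.
#' @return A tibble with columns `value`, `Low`, `Normal`, `High`.
#' @export
membership <- function(partition, values) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (!is.numeric(values) || any(!is.finite(values))) {
    rlang::abort("`values` must be finite numbers", class = "fhupm_validation_error")
  }
  lo <- partition$lo; hi <- partition$hi; w <- partition$w
  if (w == 0) {
    low <- as.numeric(values < lo)
    high <- as.numeric(values > hi)
  } else {
    ramp <- function(x, a, b) pmin(1, pmax(0, (x - a) / (b - a)))
    low <- 1 - ramp(values, lo - w, lo + w)
    high <- ramp(values, hi - w, hi + w)
  }
  tibble::tibble(value = values, Low = low, Normal = 1 - low - high, High = high)
}

#' Quantize a membership degree to an integer internal utility
#'
#' Maps a degree in `[0, 1]` to an integer on `0..scale` by half-up
#' rounding of `scale * degree`. The quantized degrees serve as internal
#' utilities of fuzzy items, mirroring the 0–10 integer utilities customary
#' in fuzzified clinical transaction tables.
#'
#' @param degree Numeric vector of degrees in `[0, 1]`.
#' @param scale Positive integer, the top of the utility scale (default 10).
#' @return Integer vector on `0..scale`; monotone non-decreasing in `degree`.
#' @export
quantize_degree <- function(degree, scale = 10L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale < 1 || scale != floor(scale)) {
    rlang::abort("`scale` must be a positive integer")
  }
  if (!is.numeric(degree) || anyNA(degree) || any(degree < 0 | degree > 1)) {
    rlang::abort("`degree` must lie in [0, 1]", class = "fhupm_validation_error")
  }
  as.integer(floor(scale * degree + 0.5))
}

#' Build partitions for a table of reference ranges
#'
#' @param ranges A data frame with columns `tag`, `name`, `lo`, `hi` — one
#'   row per clinical attribute.
#' @param transition Transition fraction passed to [fuzzy_partition()].
#' @return A named list of `fuzzy_partition` objects keyed by `name`.
#' @export
build_partitions <- function(ranges, transition = 0.25) {
  stopifnot(is.data.frame(ranges),
            all(c("tag", "name", "lo", "hi") %in% names(ranges)))
  ps <- purrr::pmap(ranges[, c("tag", "name", "lo", "hi")],
                    function(tag, name, lo, hi) {
                      fuzzy_partition(lo, hi, transition, tag = tag, name = name)
                    })
  names(ps) <- ranges$name
  ps
}

#' Read a reference-range table
#'
#' CSV with columns `tag,name,lo,hi` (attribute tag, short attribute name,
#' lower and upper bound of the reference range in attribute units).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_reference_ranges <- function(path) {
  rr <- readr::read_csv(path, col_types = readr::cols(
    tag = readr::col_integer(), name = readr::col_character(),
    lo = readr::col_double(), hi = readr::col_double()
  ))
  if (any(rr$lo >= rr$hi)) {
    rlang::abort("reference ranges must satisfy lo < hi",
                 class = "fhupm_validation_error")
  }
  rr
}

# label of the fuzzy item for attribute `name` and a linguistic term
fuzzy_item_label <- function(name, term) {
  paste0(name, ".", unname(term_letters[term]))
}

#' Fuzzify one record
#'
#' Converts a vector of attribute values into a fuzzy transaction: each
#' attribute contributes its strongest linguistic term (argmax membership)
#' as one fuzzy item, with the quantized membership degree as internal
#' utility. An exact tie at a crossover resolves to the lower-severity term
#' (Low < Normal < High).
#'
#' @param values Numeric vector of attribute values, one per partition, in
#'   partition order.
#' @param partitions Named list from [build_partitions()].
#' @param scale Utility scale for [quantize_degree()].
#' @param na_action `"error"` to fail on a missing value, `"skip"` to drop
#'   that attribute from the transaction.
#' @return A tibble with columns `tag`, `name`, `term`, `degree`,
#'   `quantity`, `item`.
#' @export
fuzzify_record <- function(values, partitions, scale = 10L,
                           na_action = c("error", "skip")) {
  na_action <- match.arg(na_action)
  if (length(values) != length(partitions)) {
    rlang::abort("`values` must supply one value per partition")
  }
  rows <- purrr::map2(partitions, as.numeric(values), function(p, v) {
    if (is.na(v)) {
      if (na_action == "error") {
        rlang::abort(sprintf("missing value for attribute '%s'", p$name),
                     class = "fhupm_validation_error")
      }
      return(NULL)
    }
    deg <- membership(p, v)
    d3 <- c(deg$Low, deg$Normal, deg$High)
    # severity-ordered argmax: ties resolve to the lower-severity term
    best <- which(d3 >= max(d3) - 1e-12)[[1]]
    tibble::tibble(tag = p$tag, name = p$name, term = fuzzy_terms[[best]],
                   degree = d3[[best]],
                   quantity = quantize_degree(d3[[best]], scale),
                   item = fuzzy_item_label(p$name, fuzzy_terms[[best]]))
  })
  dplyr::bind_rows(rows)
}

#' Fuzzify a table of quantitative records
#'
#' Turns a one-row-per-subject table of clinical measurements into a fuzzy
#' transaction database: row i becomes transaction i, each attribute
#' contributing one fuzzy item (see [fuzzify_record()]). Record columns are
#' matched to `ranges` rows by position; extra trailing columns (e.g. an
#' outcome label) are ignored.
#'
#' External utilities default to 1 for every fuzzy item. When `health_tag`
#' names a health-evaluation attribute, the external utility of that
#' attribute's Normal term is set to 0, so that unremarkable overall
#' evaluations contribute nothing and mining concentrates on the abnormal
#' profiles of interest.
#'
#' @param records Data frame of records; at least as many columns as
#'   `ranges` has rows.
#' @param ranges Reference-range table (`tag`, `name`, `lo`, `hi`).
#' @param scale,na_action Passed to [fuzzify_record()].
#' @param transition Passed to [fuzzy_partition()].
#' @param health_tag Optional tag of the health-evaluation attribute whose
#'   Normal term is weighted 0.
#' @return An [ftdb()] whose items are `<name>.<L|M|H>` fuzzy items.
#' @export
fuzzify_table <- function(records, ranges, scale = 10L, transition = 0.25,
                          health_tag = NULL, na_action = c("error", "skip")) {
  na_action <- match.arg(na_action)
  stopifnot(is.data.frame(records))
  if (ncol(records) < nrow(ranges)) {
    rlang::abort(sprintf("records have %d columns but %d reference ranges were given",
                         ncol(records), nrow(ranges)))
  }
  parts <- build_partitions(ranges, transition)
  vals <- do.call(cbind, lapply(records[seq_len(nrow(ranges))],
                                function(col) suppressWarnings(as.numeric(col))))
  tx <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- tryCatch(
      fuzzify_record(vals[i, ], parts, scale = scale, na_action = na_action),
      error = function(e) {
        rlang::abort(sprintf("record %d: %s", i, conditionMessage(e)),
                     class = "fhupm_validation_error")
      })
    if (is.null(rec) || nrow(rec) == 0L) return(NULL)
    tibble::tibble(tid = i, item = rec$item, quantity = rec$quantity)
  })
  items <- tibble::tibble(
    item = as.vector(vapply(ranges$name, fuzzy_item_label,
                            character(length(fuzzy_terms)), fuzzy_terms)),
    external_utility = 1
  )
  if (!is.null(health_tag)) {
    hname <- ranges$name[match(health_tag, ranges$tag)]
    if (is.na(hname)) {
      rlang::abort(sprintf("health_tag %s is not a tag in `ranges`", health_tag),
                   class = "fhupm_config_error")
    }
    items$external_utility[items$item == fuzzy_item_label(hname, "Normal")] <- 0
  }
  ftdb(dplyr::bind_rows(tx), items)
}
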