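# closed-form piecewise-linear evaluation used as the independent check
piecewise_membership <- function(lo, hi, w, x) {
  lin <- function(x, a, b) min(1, max(0, (x - a) / (b - a)))
  low <- if (w == 0) as.numeric(x < lo) else 1 - lin(x, lo - w, lo + w)
  high <- if (w == 0) as.numeric(x > hi) else lin(x, hi - w, hi + w)
  c(Low = low, Normal = 1 - low - high, High = high)
}

test_that("partition construction rejects degenerate configurations", {
  expect_error(fuzzy_partition(6.5, 3.2), class = "fhupm_config_error")
  expect_error(fuzzy_partition(3.2, 6.5, transition = 1),
               class = "fhupm_config_error")
  expect_error(fuzzy_partition(3.2, 6.5, transition = -0.1),
               class = "fhupm_config_error")
  p <- fuzzy_partition(3.2, 6.5, transition = 0.25)
  expect_equal(p$w, 0.25 * (6.5 - 3.2) / 2)
})

test_that("membership hits the plateaus, shoulders and crossovers", {
  p <- fuzzy_partition(3.2, 6.5, transition = 0.25, name = "FBG")
  mid <- membership(p, (3.2 + 6.5) / 2)
  expect_equal(mid$Normal, 1)
  expect_equal(mid$Low + mid$High, 0)
  expect_equal(membership(p, 100)$High, 1)
  expect_equal(membership(p, -100)$Low, 1)
  at_hi <- membership(p, 6.5)
  expect_equal(at_hi$Normal, 0.5)
  expect_equal(at_hi$High, 0.5)
  expect_error(membership(p, NaN), class = "fhupm_validation_error")
})

test_that("a near-crisp partition assigns hyperglycaemia a high degree", {
  p <- fuzzy_partition(3.2, 6.3, transition = 0.01)
  m <- membership(p, 6.4)
  expect_gt(m$High, 0.95)
  expect_lt(m$Normal, 0.05)
})

test_that("memberships stay in [0,1] and sum to 1", {
  p <- fuzzy_partition(9, 50, transition = 0.4, name = "ALT")
  withr::with_seed(11, xs <- stats::runif(1000, -30, 120))
  m <- membership(p, xs)
  degrees <- as.matrix(m[, c("Low", "Normal", "High")])
  expect_true(all(degrees >= 0 & degrees <= 1))
  expect_equal(rowSums(degrees), rep(1, 1000))
  # and they agree with the scalar piecewise evaluation
  for (x in xs[1:50]) {
    expect_equal(unlist(membership(p, x)[, 2:4]),
                 piecewise_membership(9, 50, p$w, x),
                 ignore_attr = TRUE)
  }
})

test_that("transition 0 reproduces the crisp indicator partition", {
  p <- fuzzy_partition(10, 20, transition = 0)
  m <- membership(p, c(9.99, 10, 15, 20, 20.01))
  expect_equal(m$Low, c(1, 0, 0, 0, 0))
  expect_equal(m$Normal, c(0, 1, 1, 1, 0))
  expect_equal(m$High, c(0, 0, 0, 0, 1))
})

test_that("quantization rounds half-up, stays in range and is monotone", {
  expect_identical(quantize_degree(1, 10L), 10L)
  expect_identical(quantize_degree(0, 10L), 0L)
  expect_identical(quantize_degree(0.55, 10L), 6L)
  expect_error(quantize_degree(1.2), class = "fhupm_validation_error")
  d <- seq(0, 1, by = 0.01)
  q <- quantize_degree(d, 10L)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= 0 & q <= 10))
})

test_that("fuzzify_record picks the argmax term with severity-ordered ties", {
  parts <- build_partitions(
    tibble::tibble(tag = 1:2, name = c("X", "Y"), lo = c(0, 10), hi = c(10, 20)),
    transition = 0.25)
  rec <- fuzzify_record(c(5, 15), parts)
  expect_identical(rec$term, c("Normal", "Normal"))
  expect_identical(rec$quantity, c(10L, 10L))
  expect_identical(rec$item, c("X.M", "Y.M"))
  # exactly at the upper breakpoint: Normal and High tie at 0.5 -> Normal
  tie <- fuzzify_record(c(10, 20), parts)
  expect_identical(tie$term, c("Normal", "Normal"))
  expect_identical(tie$quantity, c(5L, 5L))
  # at the lower breakpoint Low wins over Normal
  tie_lo <- fuzzify_record(c(0, 10), parts)
  expect_identical(tie_lo$term, c("Low", "Low"))
  # missing values honour the policy
  expect_error(fuzzify_record(c(NA, 15), parts),
               class = "fhupm_validation_error")
  skipped <- fuzzify_record(c(NA, 15), parts, na_action = "skip")
  expect_identical(nrow(skipped), 1L)
})

test_that("fuzzify_table yields one fuzzy item per attribute per record", {
  ranges <- reference_ranges_demo()
  recs <- generate_records(8, ranges, seed = 3)
  db <- fuzzify_table(recs, ranges)
  expect_s3_class(db, "ftdb")
  counts <- dplyr::count(db$transactions, tid)
  expect_identical(nrow(counts), 8L)
  expect_true(all(counts$n == 14L))
  expect_true(all(db$transactions$quantity >= 0 &
                    db$transactions$quantity <= 10))
  # empty input gives an empty database
  expect_identical(nrow(fuzzify_table(recs[0, ], ranges)$transactions), 0L)
  # extra trailing columns (outcome labels) are ignored
  db13 <- fuzzify_table(clinical_records_demo(), ranges[1:13, ])
  expect_true(all(dplyr::count(db13$transactions, tid)$n == 13L))
})

test_that("the health-evaluation Normal term is weighted to zero", {
  ranges <- tibble::tibble(tag = 1:2, name = c("FBG", "Health"),
                           lo = c(3.2, 0), hi = c(6.5, 10))
  recs <- tibble::tibble(FBG = c(10, 10), Health = c(5, 20))
  db <- fuzzify_table(recs, ranges, health_tag = 2L)
  eu <- db$items$external_utility[db$items$item == "Health.M"]
  expect_equal(eu, 0)
  # record 1: Health is Normal -> contributes nothing; FBG.H contributes 10
  expect_equal(transaction_utility(db, 1), 10)
  # record 2: Health is High (external 1) -> contributes fully
  expect_equal(transaction_utility(db, 2), 20)
  expect_error(fuzzify_table(recs, ranges, health_tag = 9L),
               class = "fhupm_config_error")
})

test_that("a vanishing transition recovers crisp interval classification", {
  ranges <- tibble::tibble(tag = 1L, name = "X", lo = 10, hi = 20)
  withr::with_seed(5, xs <- stats::runif(200, 0, 30))
  xs <- xs[pmin(abs(xs - 10), abs(xs - 20)) > 0.1]  # keep off the breakpoints
  crisp_term <- ifelse(xs < 10, "Low", ifelse(xs > 20, "High", "Normal"))
  parts <- build_partitions(ranges, transition = 1e-6)
  got <- vapply(xs, function(x) fuzzify_record(x, parts)$term, character(1))
  expect_identical(got, crisp_term)
})

test_that("fuzzified demo transactions satisfy the utility-sum identity", {
  db <- fuzzy_demo_db()
  tu <- transaction_utilities(db)
  sums <- dplyr::summarise(dplyr::group_by(db$transactions, tid),
                           s = sum(quantity), .groups = "drop")
  expect_equal(tu$tu, sums$s)  # unit externals: TU is the plain row sum
  expect_equal(tu$tu, c(75, 46, 93, 86, 86, 66, 73, 63))
})
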