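test_that("construction validates its invariants", {
  expect_s3_class(toy_db(), "ftdb")
  expect_error(
    ftdb(tibble::tibble(tid = c(1, 1), item = c("A", "A"), quantity = c(1, 2))),
    class = "fhupm_validation_error")
  expect_error(
    ftdb(tibble::tibble(tid = 1, item = "A", quantity = -1)),
    class = "fhupm_validation_error")
  expect_error(
    ftdb(tibble::tibble(tid = 1, item = "A", quantity = 1),
         tibble::tibble(item = "B", external_utility = 1)),
    class = "fhupm_validation_error")
  expect_error(
    ftdb(tibble::tibble(tid = 1, item = "A", quantity = 1),
         tibble::tibble(item = "A", external_utility = -2)),
    class = "fhupm_validation_error")
  empty <- ftdb(tibble::tibble())
  expect_identical(nrow(empty$transactions), 0L)
  expect_identical(nrow(empty$items), 0L)
})

test_that("the bundled worked example matches the in-code database", {
  db <- worked_example_db()
  expect_identical(dplyr::n_distinct(db$transactions$tid), 6L)
  expect_identical(nrow(db$items), 8L)
  expect_equal(db$transactions, toy_db()$transactions)
  expect_equal(db$items, toy_db()$items)
})

test_that("quantity_csv round-trips exactly, including reorganized order", {
  db <- toy_db()
  tf <- withr::local_tempfile(fileext = ".csv")
  ti <- withr::local_tempfile(fileext = ".csv")
  write_ftdb(db, tf, "quantity_csv", items_path = ti)
  back <- read_ftdb(tf, "quantity_csv", items_path = ti)
  expect_equal(back$transactions, db$transactions)
  expect_equal(back$items, db$items)

  reorg <- reorganize(db, 0)
  write_ftdb(reorg, tf, "quantity_csv", items_path = ti)
  back2 <- read_ftdb(tf, "quantity_csv", items_path = ti)
  expect_equal(back2$transactions, reorg$transactions)

  # empty database writes an empty (header-only) file
  write_ftdb(ftdb(tibble::tibble()), tf, "quantity_csv")
  expect_identical(nrow(read_ftdb(tf, "quantity_csv")$transactions), 0L)
})

test_that("spmf_utility dialect parses, validates, and round-trips utilities", {
  db <- toy_db()
  tf <- withr::local_tempfile(fileext = ".txt")
  write_ftdb(db, tf, "spmf_utility")
  back <- read_ftdb(tf, "spmf_utility")
  # external utilities are folded in, but all utility arithmetic agrees
  expect_equal(transaction_utilities(back), transaction_utilities(db))
  expect_equal(itemset_utility(back, c("A", "B")), 46)
  expect_equal(twu(back, "A"), 124)

  writeLines(c("A B:7:5 2", "A C:9:oops"), tf)
  expect_error(read_ftdb(tf, "spmf_utility"), "line 2",
               class = "fhupm_parse_error")
  writeLines("A B:99:5 2", tf)
  expect_error(read_ftdb(tf, "spmf_utility"), class = "fhupm_validation_error")
  writeLines("A B:3:5 -2", tf)
  expect_error(read_ftdb(tf, "spmf_utility"), class = "fhupm_validation_error")
  writeLines(character(), tf)
  expect_identical(nrow(read_ftdb(tf, "spmf_utility")$transactions), 0L)
})

test_that("single-occurrence utilities follow quantity times external utility", {
  db <- toy_db()
  expect_equal(item_utility(db, "A", 1), 5)
  expect_equal(item_utility(db, "A", 5), 10)
  expect_error(item_utility(db, "A", 2), class = "fhupm_item_absent")
  # zero external utility is a real zero, not absence
  dbz <- ftdb(tibble::tibble(tid = 1, item = "Z", quantity = 4),
              tibble::tibble(item = "Z", external_utility = 0))
  expect_equal(item_utility(dbz, "Z", 1), 0)
})

test_that("itemset utilities in transactions and across the database", {
  db <- toy_db()
  expect_equal(itemset_utility_in(db, c("A", "B"), 3), 14)
  expect_equal(itemset_utility_in(db, c("A", "B"), 6), 32)
  expect_equal(itemset_utility_in(db, "A", 1), item_utility(db, "A", 1))
  expect_error(itemset_utility_in(db, c("A", "B"), 1),
               class = "fhupm_not_contained")
  expect_equal(itemset_utility(db, "A"), 55)
  expect_equal(itemset_utility(db, c("A", "B")), 46)
  expect_equal(itemset_utility(db, c("A", "Z")), 0)
})

test_that("transaction utility, support and TWU reproduce hand calculations", {
  db <- toy_db()
  expect_equal(transaction_utility(db, 5), 27)
  expect_equal(transaction_utility(db, 6), 43)
  expect_equal(transaction_utility(db, 99), 0)
  expect_equal(transaction_utilities(db)$tu, c(17, 13, 37, 30, 27, 43))
  expect_identical(support_count(db, c("A", "C", "D")), 2L)
  expect_identical(support_count(db, "A"), 4L)
  expect_identical(support_count(db, "Z"), 0L)
  expect_equal(twu(db, "G"), 40)
  expect_equal(twu(db, "A"), 124)
  expect_equal(twu(db, "Z"), 0)
})

test_that("reorganize sorts ascending by TWU and prunes below the threshold", {
  db <- toy_db()
  r0 <- reorganize(db, 0)
  expect_identical(attr(r0, "item_order"),
                   c("F", "G", "H", "E", "B", "A", "D", "C"))
  t5 <- dplyr::filter(r0$transactions, tid == 5)
  expect_identical(t5$item, c("G", "E", "A", "C"))
  # no pruning at 0: all items and quantities survive
  expect_identical(sort(unique(r0$transactions$item)), LETTERS[1:8])
  # TWU(A) = 124 < 160, so A disappears everywhere
  r160 <- reorganize(db, 160)
  expect_false("A" %in% r160$transactions$item)
  expect_false("A" %in% attr(r160, "item_order"))
  # an item whose TWU equals the threshold exactly is kept
  r124 <- reorganize(db, 124)
  expect_true("A" %in% attr(r124, "item_order"))
  # pruning everything yields an empty reorganized database
  rbig <- reorganize(db, 1e6)
  expect_identical(nrow(rbig$transactions), 0L)
})

test_that("transaction utility decomposes into item utilities on random data", {
  for (s in 1:5) {
    db <- random_db(s)
    tu <- transaction_utilities(db)
    per_item <- vapply(tu$tid, function(t) {
      g <- dplyr::filter(db$transactions, tid == t)
      sum(vapply(g$item, function(i) item_utility(db, i, t), numeric(1)))
    }, numeric(1))
    expect_equal(tu$tu, per_item)
  }
})

test_that("TWU over-estimates utility and is anti-monotone", {
  db <- random_db(42, n_tx = 12, n_items = 6)
  subsets <- all_occurring_subsets(db)
  tw <- vapply(subsets, function(s) twu(db, s), numeric(1))
  ut <- vapply(subsets, function(s) itemset_utility(db, s), numeric(1))
  expect_true(all(tw >= ut - 1e-9))
  # X subset of Y implies twu(X) >= twu(Y); checked via all (k-1)-subsets
  key <- vapply(subsets, paste, character(1), collapse = " ")
  for (i in seq_along(subsets)) {
    y <- subsets[[i]]
    if (length(y) < 2) next
    for (drop in seq_along(y)) {
      x <- paste(y[-drop], collapse = " ")
      expect_gte(tw[[match(x, key)]], tw[[i]])
    }
  }
})

test_that("reorganizing at threshold 0 changes no itemset utility", {
  db <- random_db(7, n_tx = 10, n_items = 6)
  r <- reorganize(db, 0)
  for (s in all_occurring_subsets(db)) {
    expect_equal(itemset_utility(r, s), itemset_utility(db, s))
  }
})
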