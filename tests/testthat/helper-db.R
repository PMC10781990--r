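# six-transaction / eight-item hand-checkable database, built in code so it
# is independent of the bundled CSV fixtures
toy_db <- function() {
  ftdb(
    tibble::tribble(
      ~tid, ~item, ~quantity,
      1, "A", 1, 1, "C", 10, 1, "D", 1,
      2, "B", 2, 2, "C", 4, 2, "E", 1, 2, "G", 2,
      3, "A", 2, 3, "B", 2, 3, "D", 6, 3, "E", 2, 3, "F", 1,
      4, "B", 4, 4, "C", 13, 4, "D", 3, 4, "E", 1,
      5, "A", 2, 5, "C", 6, 5, "E", 2, 5, "G", 5,
      6, "A", 6, 6, "B", 1, 6, "C", 1, 6, "D", 4, 6, "H", 2
    ),
    tibble::tibble(item = LETTERS[1:8],
                   external_utility = c(5, 2, 1, 2, 3, 5, 1, 1))
  )
}

random_db <- function(seed, n_tx = 20, n_items = 8, density = 0.35) {
  generate_transactions(n_tx, n_items, density = density, seed = seed)
}

expect_same_result <- function(got, want) {
  expect_identical(got$itemset, want$itemset)
  expect_equal(got$utility, want$utility)
}

# all non-empty subsets of the items occurring in a database
all_occurring_subsets <- function(db) {
  items <- sort(unique(db$transactions$item), method = "radix")
  unlist(lapply(seq_along(items),
                function(k) utils::combn(items, k, simplify = FALSE)),
         recursive = FALSE)
}
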