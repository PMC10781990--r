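# fhupm — fuzzy high-utility pattern mining for quantitative clinical data

High-utility itemset mining (HUIM) looks for sets of items whose combined
*utility* — quantity times per-item weight, summed over the transactions
containing the set — clears a user threshold, rather than merely for sets
that occur often. Applied to clinical laboratory tables, it can surface
combinations of abnormal findings that dominate a cohort's burden of
abnormality. Raw lab values, however, are floating-point measurements with
sharp reference-range cut-offs; `fhupm` therefore first *fuzzifies* them:
each attribute's axis is split into Low / Normal / High linguistic terms
whose membership degrees sum to 1 everywhere (a Ruspini partition), and
each record becomes a fuzzy transaction whose item quantities are 0–10
quantized membership degrees. Mined itemsets then read directly as fuzzy
rules such as *"if BMI is High and FBG is High"*.

The package is aimed at researchers in medical data mining and anyone who
needs a tested, inspectable HUIM implementation with small-data oracles.

## The mining model

For item \(x\) with quantity \(IU(x, T_j)\) in transaction \(T_j\) and
external utility \(EU(x)\):

- \(U(x, T_j) = IU(x, T_j) \times EU(x)\), and
  \(U(X, T_j) = \sum_{x \in X} U(x, T_j)\) for an itemset \(X \subseteq T_j\);
- \(U(X) = \sum_{X \subseteq T_j} U(X, T_j)\) is the database utility; an
  itemset is *high-utility* when \(U(X) \ge minUtil\);
- \(TWU(X) = \sum_{X \subseteq T_j} TU(T_j)\) (transaction-weighted
  utility) over-estimates \(U\) and is anti-monotone, which drives all
  pruning.

Three interchangeable miners share one contract (identical output):

- **tree** (two-phase): a UP-Tree prefix tree over descending-TWU ordered
  transactions, nodes carrying support counts and discounted overestimated
  utilities; pattern growth emits candidates, one extra scan verifies them;
- **list** (one-phase): FHM-style utility lists `(tid, iutil, rutil)`
  joined k−1 → k, with remaining-utility pruning and an EUCS pairwise
  co-occurrence structure gating joins (EUCP);
- **adaptive** (hybrid): starts in the tree phase and, per promising
  1-itemset prefix, switches to utility-list mining when the prefix's
  upper-bound utility clears `switch_factor * minUtil`.

A guarded brute-force oracle (`brute_force_hui()`) provides the
independent reference on small databases.

## Worked example

The bundled six-transaction database is small enough to check by hand
(transaction 5 is (A:2)(C:6)(E:2)(G:5) with external utilities A=5, C=1,
E=3, G=1):

```r
library(fhupm)
db <- worked_example_db()
transaction_utility(db, 5)   # 27  = 2*5 + 6*1 + 2*3 + 5*1
twu(db, "A")                 # 124 = 17 + 37 + 27 + 43
itemset_utility(db, c("A", "B"))  # 46 = 14 (T3) + 32 (T6)

res <- mine_hui(db, min_util = 40, mode = "adaptive")
glance(res)
#>   n_itemsets total_utility min_util     mode candidates nodes joins switches
#> 1         13           639       40 adaptive          0    17    38        6
```

The 13 mined itemsets (e.g. `A C` with utility 62, `A B D` with 66,
maximum 67 for `A D`) coincide exactly with `brute_force_hui(db, 40)` in
every mode. On a fuzzified database the same result renders as rules:

```r
render_rules(res_fuzzy, ranges)
#> if BMI is High and FBG is High (utility=46)
```

End-to-end from a shell (see `?run_cli`):

```sh
Rscript inst/cli/fhupm gen --type records --n 100 --ranges ranges.csv --seed 7 --out recs.csv
Rscript inst/cli/fhupm fuzzify --records recs.csv --ranges ranges.csv --health-tag 14 --out fz.csv --items-out fzi.csv
Rscript inst/cli/fhupm mine --input fz.csv --items fzi.csv --min-util-frac 0.2 --output hui.txt
Rscript inst/cli/fhupm report --input hui.txt --ranges ranges.csv --out rules.txt
```

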