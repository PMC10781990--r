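---
title: "Fuzzy high-utility pattern mining: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy high-utility pattern mining: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhupm)
```

## The problem

A quantitative transaction database records, per transaction, how much of
each item is present (the *internal utility*), together with a per-item
weight (the *external utility*). The utility of an itemset $X$ in
transaction $T_j \supseteq X$ is
$U(X, T_j) = \sum_{x \in X} IU(x, T_j)\,EU(x)$, and its database utility
is $U(X) = \sum_{X \subseteq T_j} U(X, T_j)$. High-utility itemset mining
(HUIM) asks for every $X$ with $U(X) \ge minUtil$. Utility is not
anti-monotone — a superset can out-weigh its subsets — so the search is
pruned with the transaction-weighted utility
$TWU(X) = \sum_{X \subseteq T_j} TU(T_j)$, which both over-estimates $U$
and is anti-monotone.

In the clinical setting that motivates this package, transactions are
subjects, items are (attribute, linguistic term) pairs such as `FBG.H`
("fasting blood glucose is High"), internal utilities are quantized fuzzy
membership degrees, and external utilities encode which attributes the
analyst cares about. Mined itemsets are then conjunctions of linguistic
findings with a cohort-level utility — directly interpretable as fuzzy
rules.

## Fuzzification

### Partition shape

Each attribute has a clinical reference range $[lo, hi]$. We partition its
axis into Low / Normal / High with trapezoidal membership functions:
linear crossovers of half-width $w = \texttt{transition} \times (hi-lo)/2$
centred at $lo$ and $hi$, full-membership plateaus elsewhere. The shape is
the simplest one that (a) degenerates to the crisp indicator partition as
`transition` $\to 0$, and (b) forms a Ruspini partition — the three
degrees sum to exactly 1 at every value, so no measurement gains or loses
evidence by being near a boundary. At $x = hi$ exactly, Normal and High
are each 0.5.

`transition` (unitless, default **0.25**) is the only shape parameter. No
principled value can be derived from reference ranges alone; 0.25 keeps
half of each half-range as unambiguous plateau while still softening the
cut-offs, and the crisp limit is available for sensitivity checks.
`transition >= 1` makes the Normal plateau vanish and is rejected as a
configuration error rather than silently producing a two-term partition.

### From degrees to utilities

Each record contributes **one fuzzy item per attribute**: the argmax term,
with internal utility $\mathrm{round}(scale \times degree)$ (half-up,
`scale` default 10, giving the customary 0–10 integers). Emitting one item
per term instead would triple the item universe and make the
within-transaction "no duplicate item" invariant ambiguous; the
one-item-per-attribute layout is also what fuzzified clinical tables
conventionally print. An exact tie at a crossover resolves to the
lower-severity term (Low < Normal < High), a deliberate clinical
conservatism that keeps the mapping deterministic.

External utilities default to 1. When a health-evaluation attribute is
designated (`health_tag`), its Normal term gets external utility 0, so
subjects whose overall assessment is unremarkable contribute nothing
through that attribute and mining concentrates on abnormal profiles.

Raw attribute units are used throughout; no normalization is applied by
default (a record table can of course be rescaled upstream). Missing
values follow an explicit policy (`error` or `skip`); no imputation is
attempted.

## The miners

All three modes operate on the *reorganized* database: items with
$TWU < minUtil$ removed (strict inequality — an itemset meeting the
threshold exactly is a result, so a bound meeting it exactly must
survive), and each transaction's items sorted ascending by TWU with
lexicographic tie-breaks. Ties are not just a corner case — synthetic and
fuzzified data produce them routinely — and any fixed total order is
correct, so determinism is the only criterion.

### Two-phase tree mining

Transactions are inserted into a UP-Tree root-to-leaf in *descending* TWU
order (the reverse of the stored order), so high-TWU prefixes merge. On
insertion, the node at depth $j$ accumulates the transaction's utility
minus the utilities of the items below it on the path — the discounted
node utility of the UP-Growth family; utilities of globally unpromising
items were already removed by reorganization. Pattern growth proceeds
bottom-up over the header (ascending TWU, so each itemset is reached once
through its lowest-ordered item): an item's conditional pattern base is
read off its node-link chain, one projected path per node carrying the
node's `nu` as path utility, and the recursion prunes any local item whose
summed path utility falls below `minUtil`. Path utilities are *not*
re-discounted in conditional projections; this keeps the bound sound (a
path's `nu` dominates the utility of any sub-itemset of prefix ∪ path in
the transactions it covers) at the price of slightly looser conditional
bounds. Candidates are then verified against exact utilities in one
additional scan.

The per-node invariant worth stating precisely: a node's `nu` bounds its
root-path itemset's utility *over the transactions routed through that
node* — not database-wide, since an itemset may occur along several
branches. Database-wide soundness comes from summing over an item's whole
node-link chain, and is what the candidate set is tested against.

### One-phase list mining

Each itemset's utility list holds `(tid, iutil, rutil)` per containing
transaction, `rutil` being the summed utility of items ordered after the
itemset's last item. Lists join $k{-}1 \to k$: intersect on tid,
`iutil = iutil(Px) + iutil(Py) - iutil(P)`, `rutil` from the later-ordered
operand. The $-iutil(P)$ correction matters from $k = 3$ on — without it
the shared prefix is double-counted and the defining identity
$\sum \texttt{iutil} = U(X)$ fails. Search recurses only while
$\sum \texttt{iutil} + \sum \texttt{rutil} \ge minUtil$, and a join of
items $x, y$ is attempted only if their EUCS entry (pairwise TWU, stored
sparsely with absent $=$ 0) reaches `minUtil`. Both prunings are
transparent: they never change the mined set, only the work done, and the
test suite asserts exactly that.

### The adaptive hybrid

The driver walks promising 1-itemset prefixes in ascending TWU order. For
each, the tree provides an upper bound (the sum of `nu` over the item's
node chain, which equals the list bound $\sum \texttt{iutil} +
\sum \texttt{rutil}$ for that item). The switch rule is
`bound >= switch_factor * minUtil`: when it fires, the prefix's subtree is
mined exactly with utility lists; otherwise the prefix stays in the tree
phase (candidate growth, then verification). `switch_factor` defaults to
**1.0** — "switch as soon as the upper bound clears the threshold" —
with $0$ and $\infty$ degenerating to pure list and pure tree mining.
Switching is one-way per prefix; nothing in the search structure would be
gained by returning to the tree phase for a sub-prefix, and a one-way rule
keeps the phase accounting (the `switches` counter) meaningful.

`minUtil` may be given absolutely or as a fraction of total database
utility; the fraction is resolved once, before mining.

## Numerical and degenerate-input choices

- Utilities are plain doubles; with integer inputs (the common case, and
  all bundled data) every computation is integer-exact, so worked-example
  tests assert equality, and property tests allow only a `1e-9` slack for
  float-valued thresholds such as `0.1 * total_utility`.
- Zero quantities are accepted (fuzzified tables legitimately carry
  0-degree entries); negative quantities and external utilities are
  validation errors. A zero-utility occurrence is distinct from absence:
  `item_utility()` on an absent item signals a typed error.
- Empty databases, empty transactions, all-items-pruned reorganizations,
  and empty mining results all flow through every API without special
  cases.
- The brute-force oracle reports only itemsets with support ≥ 1, so that
  `minUtil = 0` means "every occurring itemset" for oracle and miners
  alike, and it refuses more than 20 distinct items.
- Result ordering is lexicographic on the space-joined itemset key, making
  outputs byte-stable and diffable; no randomness exists anywhere in the
  mining path.

## What the synthetic generators emulate — and what they don't

`generate_transactions()` draws Bernoulli(`density`) item inclusion with
uniform integer quantities (1..10) and external utilities (1..5);
`generate_records()` draws attribute values uniformly from reference
ranges widened by 50% on each side, so all three linguistic regions are
populated. Validation uses 30 seeded databases of ≤ 10 items × ≤ 40
transactions crossed with thresholds at {0, 10, 25, 50}% of total utility
— sizes chosen so the exhaustive oracle stays exact while still exercising
deep recursions, prefix sharing, TWU ties and heavy pruning.

Real clinical data differ in ways the generators deliberately ignore:
correlated attributes, skewed marginals, missingness, and item universes
orders of magnitude larger. Passing tests therefore certify *algorithmic
correctness* (miners ≡ oracle, bounds sound, prunings transparent), not
runtime behaviour or statistical meaningfulness on production-scale
medical databases.

## Known limitations

- In-memory only; no streaming or out-of-core handling.
- External utilities are non-negative and constant across transactions.
- Type-1 fuzzy sets only; interval/type-2 partitions are out of scope.
- The tree miner implements the discounted-utility overestimate but not
  the further node-minimum refinements of later UP-Growth variants; for
  the database sizes this package targets, verification cost is
  negligible.
- No benchmarking harness: runtime and memory comparisons between the
  modes are hardware- and data-dependent, and the package asserts nothing
  about them beyond the work counters it reports.
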