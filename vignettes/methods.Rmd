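---
title: "Pattern-based signed circuit inference: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-based signed circuit inference: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitry)
```

## The inference problem and the modelling stance

`circuitry` infers signed TF–gene regulations from paired measurements of
gene expression, TF expression (via the coding gene) and regulatory-region
accessibility over a handful of closely related cell populations. With so
few samples, correlation and model-fitting approaches are underpowered;
instead the package treats inference as a *consistency* problem: a
regulation is reported only when the discretized activity profiles of the
TF, the region and the gene jointly admit a coherent regulatory
explanation in **every** compared population. The sign falls out of which
of the two consistency systems (activation or inhibition) is satisfied.
The price of this stance is coarseness — levels, not effect sizes — and
the reward is robustness: each entity is discretized against its own
range, so absolute expression differences between entities are irrelevant.

## Discretization into patterns

For each entity, per-sample activities are averaged within populations,
shifted by a pseudocount, and log10-transformed. The interval between the
row minimum and maximum is split into four equal bins, and each population
receives the bin index of its value:

$$\mathrm{level}(g_i) = \max\!\Big(1,\ \Big\lceil 4\,\frac{g_i - \min_k g_k}{\max_k g_k - \min_k g_k} \Big\rceil\Big) \in \{1,2,3,4\}.$$

The minimum maps to 1 and the maximum to 4, so every variable pattern
contains both; a value exactly on an interior boundary $k/4$ of the range
gets level $k$ (the ceiling of an integer). Entities inactive everywhere
are classed *silent* (pattern all-0) and excluded from inference; entities
without meaningful variation are *constant* (all-5). When an external
classification exists — e.g. a differential-expression analysis — it
always overrides the built-in heuristic, which is deliberately trivial
(raw-mean floor for silence, log-range epsilon for constancy).

Tunable parameters, with defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `n_bins` | 4 | – | four bins separate most real activity profiles without exploding the pattern space; the constraint tables assume 4 |
| `pseudocount` | 1 | activity units | keeps zeros finite on the log scale; silence is detected on raw means *before* the pseudocount |
| `activity_floor` | 1 | raw mean | below this in every population, an entity is silent |
| `constancy_epsilon` | 1e-9 | log10 | effectively "exact equality"; real constancy calls should come from a DE analysis |
| `max_distance` | 500000 | bp | regulatory neighborhood cutoff for region–gene links |

Patterns are digit strings (one digit per population), which caps support
at 9 populations; larger designs are refused with a clear error rather
than silently re-encoded.

## Genomic linking

Distances are computed between the two closest extremities of two
intervals, regardless of orientation, on BED 0-based half-open
coordinates: overlapping or abutting intervals get 0, disjoint ones the
gap length, cross-chromosome pairs are never linked. The gene interval is
the gene body as supplied; whether a TSS would be the better anchor is an
open modelling question, so the choice is documented rather than hidden.
TF–region inclusion is binary: one overlapping binding site (≥ 1 bp)
suffices, and multiple sites collapse to one record. Both operations are
backed by `GenomicRanges`/`IRanges` and verified against a quadratic
brute-force oracle in the tests.

## The entity graph and the candidate query

Patterns and relations are materialized as an in-memory graph: entity maps
(gene/TF/region to pattern) plus two reified relation tables —
region–gene neighborhood records carrying the bp distance, and TF–region
inclusions. The candidate query is the join around regions, keeping
triples whose TF is expressed (not all-0). A deterministic Turtle export
is provided for interoperability with RDF tooling, and `import_graph`
round-trips it losslessly; note that the importer reads only this
package's own Turtle dialect, it is not a general RDF parser. A triple
store would return the identical result set at much higher operational
cost at desk scale, so the query contract — not the storage technology —
is what the tests pin down.

## Likelihood constraints and deviation policies

For a population with TF level $f$, region level $r$ and gene level $g$,
the *perfect* activation level is $l = \max(1, f - (4 - r))$: a fully open
region ($r=4$) transmits the TF level unchanged, and each step of lost
accessibility discounts it by one. Inhibition is the $5-g$ mirror. Each
population is then classed:

* **perfect** — $g = l$;
* **relaxed** — $|g - l| = 1$ and the accessibility bound
  $g \le \max(1, f - (4-r) + 2)$ holds;
* **region-violating** — $|g - l| = 1$ but the bound fails;
* **fail** — $|g - l| \ge 2$.

Policies count cell classes: `delta0` requires all populations perfect;
`delta1` tolerates one relaxed cell; `delta1_regOFF` one relaxed *or*
region-violating cell; `delta2` two relaxed cells, or one arbitrary
deviation. Two design choices deserve a note. First, the per-cell counting
semantics are normative here rather than a single summed deviation
$\sum_i |g_i - l_i| \le \delta$: the sum cannot express the region-bound
waiver of `delta1_regOFF` or `delta2`'s single-failure allowance. The sum
form is still available (`mode = "sum"`) as a documented alternative and
agrees with cell counting at `delta0`. Second, `delta2`'s "one cell
satisfying nothing" allowance is taken to include region-violating cells
(a strictly weaker failure), which preserves the nesting
`delta1 ⊆ delta1_regOFF ⊆/∩ delta2` verified exhaustively in the tests.
The default policy is `delta1` with the region bound on — the best
size/reliability compromise in the method's own benchmarking.

Triples in which all three patterns are constant are internally consistent
but carry no directional information; they are reported with sign `ND`.
Triples mixing constant and variable patterns can satisfy neither
equation system and are simply rejected. Per-sign admission is independent,
so a triple can in principle be admitted with both signs under relaxed
policies; after merging to unique TF–gene relations, pairs supported with
both signs through different regions are kept as two records flagged
`conflict` — a documented choice, since dropping either would silently
discard evidence.

## Key-regulator selection

For a TF and a gene pattern, *coverage* is the percentage of the pattern's
genes the TF targets and *specificity* the percentage of the TF's targets
inside the pattern. Both are needed: tiny patterns are trivially covered,
and large patterns soak up targets of unspecific TFs. A (TF, pattern) pair
is a key regulator when both metrics reach the threshold — by default the
last quartile of each metric's observed distribution (type-7 quantiles,
ties kept with ≥, so a degenerate single-row distribution keeps its row).
Metrics pool both signs by default with a per-sign mode available, since
the appropriate pooling is context-dependent. The annotation score is a
weighted sum (default weights 1/1/1) of GO-term hits and two citation
counts taken from *local* user-supplied tables — live database querying is
deliberately out of the tested surface to keep the package network-free;
the exact composite formula is a documented convention, not an empirical
claim. A zero composite flags selected TFs not yet studied in the context
of interest.

## Validation against curated tables

Curated TF–gene databases are filtered to *reachable* relations (both
endpoints measured), then enrichment of found relations is assessed with a
one-sided binomial tail: under the null, each reachable relation falls in
the network independently with probability network size / universe size.
The universe defaults to the candidate pairs emitted by the query stage;
the null is isolated in one function so it can be swapped. Symbols are
case-folded with an optional alias map before matching. Sign concordance
counts a shared pair as *true* when the database's single determined sign
matches, *different* when it contradicts, and *unknown* when the database
is unsigned or signed both ways (or the inference is `ND`).

## What the synthetic generator emulates — and what it does not

The generator emits raw per-sample tables and BED files realizing chosen
patterns, so the real discretization stage runs on them (inverse
discretization: level $k$ maps to the log10 mean $1 + (k-1)/3 \cdot 2$,
with multiplicative within-population jitter rescaled to exact means).
Defaults describe the stated test world: 4 populations, 50 genes, 10 TFs,
30 regions, 20 planted signed relations, 3 expression replicates per
population (a typical RNA-seq design at this scale) and 2 for regions
(regions are often measured with fewer replicates; one replicate, as in
some real designs, is below this generator's floor of two). Planted gene
patterns are the unique perfect completions of their (TF, region, sign),
so delta0 recall is 1 by construction — that is the point: the recovery
test checks the *pipeline*, not the biology. Noise mode moves exactly one
population of a planted gene pattern by one level, in the direction that
keeps the cell relaxed on the appropriate (possibly mirrored) scale, so
perturbed relations are delta1- but not delta0-recoverable. Decoy
regions/TFBS are placed with rejection against accidentally perfect
triples (logged if rejection fails after 20 tries).

What a green end-to-end test therefore establishes: the stages compose
correctly, the constraint algebra is implemented exactly, determinism
holds. What it does not establish: performance on real data with
overdispersed counts, discretization boundary instability, imperfect
peak calling, or binding-site noise — none of which the generator
simulates.

## Numerical and degenerate-input choices

* Bin boundaries follow ceiling semantics exactly; no epsilon fuzzing.
* `level_of` on a degenerate range (max ≤ min) is an error directing the
  caller to the constant class, never a silent fallback.
* The binomial tail is computed with `pbinom(..., lower.tail = FALSE)`;
  mathematically positive p-values can underflow to 0 in double precision
  for extreme tails (~1e-320) — accepted and documented.
* All outputs are written with fixed formatting and canonical row orders,
  so identical inputs and configuration produce byte-identical artifacts.
* Pattern tables, relation tables and exports are sorted lexicographically;
  tie-breaks are therefore deterministic by construction.

## Known limitations

* Four bins are hard-wired into the constraint tables; `n_bins` is exposed
  for exploration of the discretization alone, not for inference.
* The region-to-gene link is purely distance-based (no TAD/loop
  information), and distance is measured to the gene body, not the TSS.
* The constraint engine reasons population-wise and cannot represent
  cooperative or competitive TF binding at shared sites.
* Sparsely populated patterns distort coverage/specificity; merging or
  excluding them is left to the analyst.
* The "192 possible patterns" sometimes quoted for four populations does
  not match the 110 four-tuples containing both a 1 and a 4 that the level
  formula can emit; no pattern-count constant is hard-coded anywhere.
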