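# circuitry

Signed transcriptional regulatory circuit inference for few-sample
settings.

## The problem

Inferring which transcription factor (TF) regulates which gene — and
whether it activates or inhibits it — normally relies on correlation or
machine-learning approaches that need many samples. Typical human study
designs (10–20 samples over 4–8 closely related cell populations, e.g. B
cell differentiation stages profiled by RNA-seq and ATAC-seq) are far below
that. `circuitry` takes a different route: it discretizes each entity's
activity across populations into a coarse *pattern*, joins genes, TFs and
open-chromatin regulatory regions through their genomic coordinates, and
keeps only the TF–region–gene combinations whose three patterns are jointly
consistent with the biology of regulation. The consistency test itself
assigns the sign.

## The model

For each entity (gene, TF = its coding gene, or region) the per-population
mean activity is log10-transformed and min–max binned into four equal
intervals, giving a level per population:

    level(g_i) = max(1, ceil(4 * (g_i - min_k g_k) / (max_k g_k - min_k g_k)))

Silent entities get the all-0 pattern, constant ones all-5; every variable
pattern contains a 1 (its minimum) and a 4 (its maximum).

Candidate triples come from a graph join: TF has ≥1 binding site inside the
region, region lies within 500 kb of the gene, TF is expressed. A triple
supports an **activation** when, in every population,

    level(g_i) = max(1, level(f_i) - (4 - level(r_i)))

i.e. the gene tracks the TF level discounted by lost region accessibility;
an **inhibition** mirrors this through `5 - level(g_i)`. A deviation policy
relaxes the test: `delta0` (exact everywhere), `delta1` (one population may
miss the perfect level by one while respecting the accessibility bound
`level(g_i) <= max(1, level(f_i) - (4 - level(r_i)) + 2)`), `delta1_regOFF`
(that bound waived for the deviating population), `delta2` (two bounded
deviations, or one arbitrary one). Surviving records are merged into unique
signed TF–gene relations; a coverage/specificity filter then short-lists
key regulators per gene pattern, and curated relation tables can be used
for binomial-enrichment and sign-concordance checks.

## Worked example

Generate a synthetic bundle with 20 planted signed regulations among decoys
and run the full pipeline:

```r
library(circuitry)
b <- generate_fixture(fixture_spec(seed = 42L), "fx42")
cfg <- pipeline_config(
  expression         = b$paths[["expression"]],
  expression_samples = b$paths[["expression_samples"]],
  regions            = b$paths[["regions"]],
  region_samples     = b$paths[["region_samples"]],
  genes_bed          = b$paths[["genes_bed"]],
  regions_bed        = b$paths[["regions_bed"]],
  tfbs_bed           = b$paths[["tfbs_bed"]],
  out_dir = "fx42_out", policy = "delta1")
res <- run_pipeline(cfg)
```

The run log (`fx42_out/run_log.txt`) reports per-stage record counts:

```
genes: 60 (silent: 3, constant: 5)
regions: 30
tfs_resolved: 10
region_gene_neighbors: 30
tf_region_inclusions: 34
candidate_triples: 34
signed_triples: 20
merged_relations: 20
key_regulators: 8
```

34 candidate triples enter the constraint filter and 20 signed relations
survive — exactly the planted ones (recall 1.0 against
`b$truth`). The merged table carries the sign and the supporting regions:

```
  tf_id gene_id sign n_regions gene_pattern
1  TF01    G005    -         1         4441
2  TF01    G007    +         1         1114
3  TF01    G019    -         1         4221
```

`TF01 -| G005` reads: TF01's expression pattern, modulated by its region's
accessibility, is population-by-population consistent with *inhibition* of
G005 (whose expression collapses in the last population, pattern 4441).
`res$key_regulators` lists the (TF, pattern) pairs whose coverage and
specificity both reach the last quartile, e.g. `TF07/1421` with coverage
100 and specificity 100.

A command-line wrapper with the same stages as subcommands
(`patterns`, `links`, `integrate`, `infer`, `classify`, `validate`,
`simulate`, `run-all`) is installed at `inst/cli/circuitry`.

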