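Package: circuitry
Title: Signed Transcriptional Regulatory Circuit Inference from Discretized
    Activity Patterns
Version: 0.1.0
Authors@R:
    person("Regulatory", "Genomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers signed (activation/inhibition) transcription factor to
    gene regulatory relations in few-sample settings. Per-population mean
    activities of genes, transcription factors (TFs) and open-chromatin
    regulatory regions are discretized into fixed-length level patterns;
    genomic coordinates link regions to nearby genes (500 kb neighborhood)
    and TF binding sites to regions; the resulting entity graph is joined
    into candidate TF-region-gene triples which are filtered and signed by
    biological likelihood constraints under a tunable deviation policy.
    Post-hoc coverage/specificity filters rank key regulators, and inferred
    networks can be benchmarked against curated TF-gene relation tables.
    Includes a synthetic-fixture generator with planted signed regulations
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
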