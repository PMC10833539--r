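# shared pipeline helpers: run the full chain on a fixture bundle and
# measure recall of the planted signed relations

bundle_config <- function(bundle, out_dir, ...) {
  pipeline_config(
    expression = bundle$paths[["expression"]],
    expression_samples = bundle$paths[["expression_samples"]],
    regions = bundle$paths[["regions"]],
    region_samples = bundle$paths[["region_samples"]],
    genes_bed = bundle$paths[["genes_bed"]],
    regions_bed = bundle$paths[["regions_bed"]],
    tfbs_bed = bundle$paths[["tfbs_bed"]],
    out_dir = out_dir, ...)
}

planted_recall <- function(bundle, policy) {
  out <- file.path(tempdir(),
                   paste0("recall_", policy, "_", bundle$spec$seed))
  res <- run_pipeline(bundle_config(bundle, out, policy = policy))
  truth <- bundle$truth
  hit <- mapply(function(tf, gene, sign)
    any(res$merged$tf_id == tf & res$merged$gene_id == gene &
        res$merged$sign == sign),
    truth$tf, truth$gene, truth$sign)
  list(recall = mean(hit), merged = res$merged, result = res)
}

# vectorized table-driven oracle: per-population classes looked up in the
# enumeration-built table, policies applied by counting classes
oracle_admit_matrix <- function(fm, rm, gm, sign, policy) {
  key <- if (sign == "+") 1L else 2L
  n <- ncol(fm)
  cls <- matrix("", nrow(fm), n)
  for (j in seq_len(n))
    cls[, j] <- .class_table[cbind(fm[, j], rm[, j], gm[, j], key)]
  n_dark <- rowSums(cls == "dark"); n_light <- rowSums(cls == "light")
  n_grey <- rowSums(cls == "grey"); n_white <- rowSums(cls == "white")
  switch(policy,
    delta0 = n_dark == n,
    delta1 = n_white == 0L & n_grey == 0L & n_light <= 1L,
    delta1_regOFF = n_white == 0L & (n_light + n_grey) <= 1L,
    delta2 = (n_white == 0L & n_grey == 0L & n_light <= 2L) |
             (n_light + n_grey + n_white) <= 1L)
}

# every (tf pattern, region pattern, gene pattern) level-tuple triple for n
# populations, as three aligned matrices
all_triple_matrices <- function(n) {
  tuples <- all_level_tuples(n)
  k <- nrow(tuples)
  idx <- expand.grid(f = seq_len(k), r = seq_len(k), g = seq_len(k))
  list(f = tuples[idx$f, , drop = FALSE],
       r = tuples[idx$r, , drop = FALSE],
       g = tuples[idx$g, , drop = FALSE])
}
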