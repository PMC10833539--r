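# Independent oracles used across the suite. These re-derive expected
# results by brute force / direct enumeration and deliberately avoid the
# package's own code paths.

# gap between two half-open intervals by counting the integer positions
# lying strictly between them
oracle_interval_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_integer_)
  if (a$start < b$end && b$start < a$end) return(0L)  # overlap
  lo <- min(a$end, b$end); hi <- max(a$start, b$start)
  sum(seq(0L, max(a$end, b$end)) >= lo & seq(0L, max(a$end, b$end)) < hi)
}

oracle_all_pairs <- function(regions, genes, max_distance) {
  out <- data.frame(region_id = character(), gene_id = character(),
                    distance = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(genes))) {
      d <- oracle_interval_distance(as.list(regions[i, ]),
                                    as.list(genes[j, ]))
      if (!is.na(d) && d <= max_distance)
        out <- rbind(out, data.frame(region_id = regions$name[[i]],
                                     gene_id = genes$name[[j]],
                                     distance = d,
                                     stringsAsFactors = FALSE))
    }
  }
  out[order(out$region_id, out$gene_id), , drop = FALSE]
}

# brute-force triple join over all (tf, region, gene) combinations
oracle_triples <- function(graph) {
  out <- list()
  for (tf in names(graph$tfs)) {
    if (grepl("^0+$", graph$tfs[[tf]])) next
    for (k in seq_len(nrow(graph$tf_inclusion))) {
      if (graph$tf_inclusion$tf_id[[k]] != tf) next
      region <- graph$tf_inclusion$region_id[[k]]
      for (m in seq_len(nrow(graph$region_closest))) {
        if (graph$region_closest$region_id[[m]] != region) next
        out[[length(out) + 1L]] <- c(tf, region,
                                     graph$region_closest$gene_id[[m]])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(tf_id = character(), region_id = character(),
                      gene_id = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("tf_id", "region_id", "gene_id")
  df <- df[order(df$tf_id, df$region_id, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- table-driven constraint oracle -----------------------------------------
# The 4x4x4 per-sign cell-class table (dark / light / grey / white), built
# once by direct enumeration, then policies applied by counting cell
# classes and scoring dark = 2, light/grey = 1.

build_class_table <- function() {
  tab <- array("", dim = c(4, 4, 4, 2),
               dimnames = list(NULL, NULL, NULL, c("pos", "neg")))
  for (f in 1:4) for (r in 1:4) {
    l <- max(1, f - (4 - r))
    bound <- max(1, f - (4 - r) + 2)
    for (g in 1:4) {
      cls <- if (g == l) "dark"
             else if (abs(g - l) == 1 && g <= bound) "light"
             else if (abs(g - l) == 1) "grey"
             else "white"
      tab[f, r, g, "pos"] <- cls
      tab[f, r, 5 - g, "neg"] <- cls
    }
  }
  tab
}

.class_table <- build_class_table()

oracle_admit <- function(f, r, g, sign, policy) {
  key <- if (sign == "+") "pos" else "neg"
  cls <- vapply(seq_along(f), function(i)
    .class_table[f[[i]], r[[i]], g[[i]], key], character(1))
  n_dark <- sum(cls == "dark"); n_light <- sum(cls == "light")
  n_grey <- sum(cls == "grey"); n_white <- sum(cls == "white")
  n <- length(f)
  switch(policy,
    delta0 = n_dark == n,
    delta1 = n_white == 0 && n_grey == 0 && n_light <= 1,
    delta1_regOFF = n_white == 0 && (n_light + n_grey) <= 1,
    delta2 = (n_white == 0 && n_grey == 0 && n_light <= 2) ||
             (n_light + n_grey + n_white) <= 1)
}

random_variable_pattern <- circuitry:::random_variable_pattern

# all level tuples of length n as a matrix (4^n rows)
all_level_tuples <- function(n) {
  as.matrix(do.call(expand.grid, rep(list(1:4), n)))
}

# direct binomial upper-tail summation from the pmf formula
oracle_binom_upper <- function(found, size, prob) {
  if (found == 0) return(1)
  k <- found:size
  sum(choose(size, k) * prob^k * (1 - prob)^(size - k))
}

# small S1-style toy world used by integration and acceptance tests:
# 2 TFs, 2 regions, 2 genes; TF2 has no site in Region2; Region1 is more
# than 500 kb away from G2
make_toy_graph <- function() {
  genes <- data.frame(entity_id = c("G1", "G2"), class = "variable",
                      pattern = c("1124", "4411"), stringsAsFactors = FALSE)
  tfs <- data.frame(entity_id = c("TF1", "TF2"), class = "variable",
                    pattern = c("1124", "1144"), stringsAsFactors = FALSE)
  regions <- data.frame(entity_id = c("ATAC_1", "ATAC_2"), class = "variable",
                        pattern = c("1144", "4414"), stringsAsFactors = FALSE)
  neighbors <- data.frame(
    region_id = c("ATAC_1", "ATAC_2", "ATAC_2"),
    gene_id = c("G1", "G1", "G2"),
    distance = c(0L, 12000L, 3000L), stringsAsFactors = FALSE)
  inclusions <- data.frame(
    tf_id = c("TF1", "TF2", "TF1"),
    region_id = c("ATAC_1", "ATAC_1", "ATAC_2"), stringsAsFactors = FALSE)
  build_graph(genes, tfs, regions, neighbors, inclusions)
}
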