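#' Key-regulator selection by coverage and specificity
#'
#' Post-hoc filter on the merged TF-gene network. For a (TF, gene pattern)
#' pair, *coverage* is the percentage of that pattern's genes targeted by
#' the TF, and *specificity* the percentage of the TF's targets that fall
#' in the pattern. Key regulators must clear user-chosen thresholds on both
#' metrics simultaneously; small patterns are easily fully covered, which
#' is why neither metric suffices alone. An optional annotation-based score
#' computed from local GO / citation tables helps triage the short list.
#'
#' @name key_regulators
NULL

#' Coverage of a gene pattern by one TF
#'
#' @param tf TF id.
#' @param pattern gene pattern string.
#' @param relations merged relation data.frame with columns tf_id, gene_id,
#'   gene_pattern (see [merge_to_tf_gene()]).
#' @param gene_patterns pattern data.frame (entity_id, pattern) defining
#'   pattern membership for all genes.
#' @return percentage in [0, 100].
#' @export
coverage <- function(tf, pattern, relations, gene_patterns) {
  members <- gene_patterns$entity_id[gene_patterns$pattern == pattern]
  if (length(members) == 0L)
    stop("undefined coverage: no gene has pattern ", pattern)
  targets <- unique(relations$gene_id[relations$tf_id == tf])
  100 * length(intersect(targets, members)) / length(members)
}

#' Specificity of one TF for a gene pattern
#'
#' @inheritParams coverage
#' @return percentage in [0, 100].
#' @export
specificity <- function(tf, pattern, relations) {
  rel <- relations[relations$tf_id == tf, , drop = FALSE]
  targets <- unique(rel$gene_id)
  if (length(targets) == 0L)
    stop("undefined specificity: TF ", tf, " has no target")
  in_pat <- unique(rel$gene_id[rel$gene_pattern == pattern])
  100 * length(in_pat) / length(targets)
}

#' Coverage/specificity table over all (TF, pattern) pairs
#'
#' @param relations merged relation data.frame (tf_id, gene_id,
#'   gene_pattern, sign, tf_pattern).
#' @param gene_patterns pattern data.frame for all genes.
#' @param by_sign compute metrics separately per sign (default FALSE:
#'   both signs pooled).
#' @return data.frame with columns tf_id, pattern (the gene pattern),
#'   optionally sign, coverage, specificity.
#' @export
regulator_metrics <- function(relations, gene_patterns, by_sign = FALSE) {
  if (nrow(relations) == 0L)
    return(data.frame(tf_id = character(), pattern = character(),
                      coverage = numeric(), specificity = numeric()))
  dt <- data.table::as.data.table(
    relations[, intersect(c("tf_id", "gene_id", "gene_pattern", "sign"),
                          names(relations))])
  keys <- c("tf_id", if (by_sign) "sign")
  size <- table(gene_patterns$pattern)
  per_pat <- dt[, list(n_targets = length(unique(gene_id))),
                by = c(keys, "gene_pattern")]
  tot <- dt[, list(n_total = length(unique(gene_id))), by = keys]
  out <- merge(per_pat, tot, by = keys)
  out <- as.data.frame(out)
  names(out)[names(out) == "gene_pattern"] <- "pattern"
  out$coverage <- 100 * out$n_targets / as.integer(size[out$pattern])
  out$specificity <- 100 * out$n_targets / out$n_total
  out <- out[order(out$tf_id, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("tf_id", "pattern", if (by_sign) "sign", "coverage", "specificity")]
}

#' Select key regulators by a joint threshold policy
#'
#' A (TF, pattern) pair is kept iff its coverage and its specificity both
#' reach the respective thresholds (ties kept: `>=`). Thresholds are
#' derived from the observed metric distributions, or fixed.
#'
#' @param metrics data.frame from [regulator_metrics()].
#' @param policy a list: `list(type = "quantile", q = 0.75)` (default: last
#'   quartile, type-7 interpolation), `list(type = "mean_sd")` (mean + one
#'   standard deviation), or `list(type = "fixed", coverage = , specificity
#'   = )` (fixed percentages).
#' @return the selected rows of `metrics`, with the applied thresholds as
#'   attributes `coverage_threshold` / `specificity_threshold`.
#' @export
select_key_regulators <- function(metrics,
                                  policy = list(type = "quantile", q = 0.75)) {
  if (nrow(metrics) == 0L) return(metrics)
  thr <- switch(policy$type,
    quantile = c(stats::quantile(metrics$coverage, policy$q, type = 7,
                                 names = FALSE),
                 stats::quantile(metrics$specificity, policy$q, type = 7,
                                 names = FALSE)),
    mean_sd = c(mean(metrics$coverage) + stats::sd(metrics$coverage),
                mean(metrics$specificity) + stats::sd(metrics$specificity)),
    fixed = c(policy$coverage, policy$specificity),
    stop("unknown threshold policy: ", policy$type))
  thr[is.na(thr)] <- 0        # single-row distributions: sd undefined, keep
  out <- metrics[metrics$coverage >= thr[[1]] &
                 metrics$specificity >= thr[[2]], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coverage_threshold") <- thr[[1]]
  attr(out, "specificity_threshold") <- thr[[2]]
  out
}

#' Annotation-based score from local tables
#'
#' Counts, for each TF, hits against a user list of GO terms and two
#' citation counts (context-specific and broad), combined as a weighted
#' sum. A zero composite marks candidates not yet studied in the context of
#' interest. Live database queries are deliberately out of scope: the
#' tables are local files.
#'
#' @param tfs character vector of TF ids to score.
#' @param go_table data.frame (tf_id, term_id): GO annotations.
#' @param citation_table data.frame (tf_id, context_count, broad_count).
#' @param go_terms character vector of GO term ids of interest.
#' @param weights numeric length-3 weights for (go_hits, context, broad);
#'   default c(1, 1, 1).
#' @return data.frame with columns tf_id, go_hits, context_citations,
#'   broad_citations, composite, ordered by decreasing composite.
#' @export
annotation_score <- function(tfs, go_table, citation_table,
                             go_terms = unique(go_table$term_id),
                             weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L)
  tfs <- unique(as.character(tfs))
  go_hits <- vapply(tfs, function(tf)
    sum(go_table$tf_id == tf & go_table$term_id %in% go_terms), integer(1))
  idx <- match(tfs, citation_table$tf_id)
  ctx <- ifelse(is.na(idx), 0L, citation_table$context_count[idx])
  brd <- ifelse(is.na(idx), 0L, citation_table$broad_count[idx])
  missing <- !(tfs %in% go_table$tf_id) & is.na(idx)
  if (any(missing))
    warning(sum(missing), " TF(s) absent from all annotation tables: ",
            paste(utils::head(tfs[missing], 5L), collapse = ", "))
  out <- data.frame(tf_id = tfs, go_hits = unname(go_hits),
                    context_citations = as.integer(ctx),
                    broad_citations = as.integer(brd),
                    stringsAsFactors = FALSE)
  out$composite <- weights[[1]] * out$go_hits +
    weights[[2]] * out$context_citations + weights[[3]] * out$broad_citations
  out <- out[order(-out$composite, out$tf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
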