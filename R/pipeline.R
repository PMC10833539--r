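#' Pipeline orchestration
#'
#' Runs the full inference chain -- discretize, link, integrate, query,
#' constrain, merge, rank -- from a validated configuration, writing every
#' intermediate artifact (the unsigned candidate network is needed for
#' diagnostics) plus a run log with per-stage record counts. Reruns with
#' the same inputs and configuration are byte-identical: the pipeline has
#' no randomness of its own.
#'
#' @name pipeline
NULL

#' Build and validate a pipeline configuration
#'
#' @param expression path to the gene expression TSV (first column gene id,
#'   remaining columns samples).
#' @param expression_samples path to the sample -> population map TSV for
#'   the expression table.
#' @param regions path to the region activity TSV.
#' @param region_samples sample map TSV for the region table (defaults to
#'   `expression_samples`).
#' @param genes_bed,regions_bed,tfbs_bed BED paths; the TFBS name column
#'   holds the TF symbol.
#' @param out_dir output directory.
#' @param populations optional population order (default: order of first
#'   appearance in the expression sample map).
#' @param gene_classes optional TSV (entity_id, class) of external
#'   silent/constant/variable labels, e.g. from a DE analysis.
#' @param max_distance region-gene neighborhood cutoff in bp (default
#'   500000).
#' @param pseudocount added before log10 (default 1).
#' @param policy deviation policy (default "delta1").
#' @param threshold list for [select_key_regulators()] (default last
#'   quartile).
#' @param gene_pattern_filter optional pattern whitelist for the query.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression, expression_samples, regions,
                            genes_bed, regions_bed, tfbs_bed, out_dir,
                            region_samples = expression_samples,
                            populations = NULL, gene_classes = NULL,
                            max_distance = 500000L, pseudocount = 1,
                            policy = "delta1",
                            threshold = list(type = "quantile", q = 0.75),
                            gene_pattern_filter = NULL) {
  cfg <- list(expression = expression,
              expression_samples = expression_samples,
              regions = regions, region_samples = region_samples,
              genes_bed = genes_bed, regions_bed = regions_bed,
              tfbs_bed = tfbs_bed, out_dir = out_dir,
              populations = populations, gene_classes = gene_classes,
              max_distance = as.integer(max_distance),
              pseudocount = pseudocount,
              policy = match.arg(policy, deviation_policies()),
              threshold = threshold,
              gene_pattern_filter = gene_pattern_filter)
  for (f in c("expression", "expression_samples", "regions",
              "region_samples", "genes_bed", "regions_bed", "tfbs_bed")) {
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  }
  if (!is.null(cfg$gene_classes) && !file.exists(cfg$gene_classes))
    stop("input file for 'gene_classes' not found: ", cfg$gene_classes)
  structure(cfg, class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage outputs
#'   (gene_patterns, region_patterns, graph, candidates, signed, merged,
#'   metrics, key_regulators) and `paths` to the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    "# pipeline run log",
    paste0("policy: ", config$policy),
    paste0("max_distance: ", config$max_distance),
    paste0("pseudocount: ", config$pseudocount))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  de_info <- NULL
  if (!is.null(config$gene_classes)) {
    gc_tab <- read_tsv(config$gene_classes)
    de_info <- stats::setNames(as.character(gc_tab[[2]]),
                               as.character(gc_tab[[1]]))
  }

  gene_pat <- stage("patterns", activity_patterns(
    read_activity_tsv(config$expression),
    read_sample_map(config$expression_samples),
    populations = config$populations, pseudocount = config$pseudocount,
    de_info = de_info))
  region_pat <- stage("patterns", activity_patterns(
    read_activity_tsv(config$regions),
    read_sample_map(config$region_samples),
    populations = config$populations, pseudocount = config$pseudocount))

  genes_bed <- stage("links", read_bed(config$genes_bed, prefix = "gene"))
  regions_bed <- stage("links", read_bed(config$regions_bed, prefix = "ATAC"))
  tfbs_bed <- stage("links", read_bed(config$tfbs_bed, prefix = "TFBS"))
  neighbors <- stage("links", region_gene_neighbors(
    regions_bed, genes_bed, config$max_distance))
  inclusions <- stage("links", tf_region_inclusion(tfbs_bed, regions_bed))

  # silent entities bear no usable signal: drop them before integration
  tf_pat <- stage("integrate",
                  tf_patterns_from_genes(unique(tfbs_bed$name), gene_pat))
  gene_pat_active <- gene_pat[gene_pat$class != "silent", , drop = FALSE]
  region_pat_active <- region_pat[region_pat$class != "silent", , drop = FALSE]
  graph <- stage("integrate", build_graph(
    gene_pat_active, tf_pat, region_pat_active, neighbors, inclusions))

  candidates <- stage("query",
                      candidate_triples(graph, config$gene_pattern_filter))
  signed <- stage("constraints", filter_and_sign(candidates, config$policy))
  merged <- stage("merge", merge_to_tf_gene(signed))

  signed_only <- merged[merged$sign %in% c("+", "-"), , drop = FALSE]
  metrics <- stage("classify",
                   regulator_metrics(signed_only, gene_pat_active))
  keyreg <- stage("classify",
                  select_key_regulators(metrics, config$threshold))

  paths <- c(gene_patterns = "gene_patterns.tsv",
             region_patterns = "region_patterns.tsv",
             candidate_triples = "candidate_triples.tsv",
             signed_triples = "signed_triples.tsv",
             merged_relations = "merged_relations.tsv",
             regulator_metrics = "regulator_metrics.tsv",
             key_regulators = "key_regulators.tsv",
             graph = "graph.ttl",
             run_log = "run_log.txt")
  paths <- stats::setNames(file.path(config$out_dir, paths), names(paths))
  write_tsv(gene_pat, paths[["gene_patterns"]])
  write_tsv(region_pat, paths[["region_patterns"]])
  write_tsv(candidates, paths[["candidate_triples"]])
  write_tsv(signed, paths[["signed_triples"]])
  write_tsv(merged, paths[["merged_relations"]])
  write_tsv(metrics, paths[["regulator_metrics"]])
  write_tsv(keyreg, paths[["key_regulators"]])
  export_graph(graph, paths[["graph"]])

  log_lines <- c(log_lines,
    paste0("genes: ", nrow(gene_pat),
           " (silent: ", sum(gene_pat$class == "silent"),
           ", constant: ", sum(gene_pat$class == "constant"), ")"),
    paste0("regions: ", nrow(region_pat)),
    paste0("tfs_resolved: ", nrow(tf_pat)),
    paste0("region_gene_neighbors: ", nrow(neighbors)),
    paste0("tf_region_inclusions: ", nrow(inclusions)),
    paste0("candidate_triples: ", nrow(candidates)),
    paste0("signed_triples: ", nrow(signed)),
    paste0("merged_relations: ", nrow(merged)),
    paste0("key_regulators: ", nrow(keyreg)))
  writeLines(log_lines, paths[["run_log"]])

  invisible(list(gene_patterns = gene_pat, region_patterns = region_pat,
                 graph = graph, candidates = candidates, signed = signed,
                 merged = merged, metrics = metrics, key_regulators = keyreg,
                 paths = paths))
}

#' Read a pipeline configuration file (DCF key: value format)
#'
#' Keys match the arguments of [pipeline_config()]; `threshold` is given as
#' `threshold_type` plus `threshold_q` / `threshold_coverage` /
#' `threshold_specificity`; `populations` and `gene_pattern_filter` are
#' comma-separated. Relative paths resolve against the config file's
#' directory.
#'
#' @param path config file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  split_csv <- function(x)
    if (is.null(x)) NULL else trimws(strsplit(x, ",")[[1]])
  threshold <- switch(kv$threshold_type %||% "quantile",
    quantile = list(type = "quantile",
                    q = as.numeric(kv$threshold_q %||% 0.75)),
    mean_sd = list(type = "mean_sd"),
    fixed = list(type = "fixed",
                 coverage = as.numeric(kv$threshold_coverage),
                 specificity = as.numeric(kv$threshold_specificity)))
  pipeline_config(
    expression = resolve(kv$expression),
    expression_samples = resolve(kv$expression_samples),
    regions = resolve(kv$regions),
    region_samples = resolve(kv$region_samples %||% kv$expression_samples),
    genes_bed = resolve(kv$genes_bed),
    regions_bed = resolve(kv$regions_bed),
    tfbs_bed = resolve(kv$tfbs_bed),
    out_dir = resolve(kv$out_dir),
    populations = split_csv(kv$populations),
    gene_classes = resolve(kv$gene_classes),
    max_distance = as.integer(kv$max_distance %||% 500000L),
    pseudocount = as.numeric(kv$pseudocount %||% 1),
    policy = kv$policy %||% "delta1",
    threshold = threshold,
    gene_pattern_filter = split_csv(kv$gene_pattern_filter))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
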