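#' Entity graph integration and the candidate-triple query
#'
#' Patterns and genomic relations are materialized as an in-memory entity
#' graph (genes, TFs, regions with their patterns; reified region-gene
#' neighborhood records carrying bp distances; binary TF-region inclusion).
#' The candidate query joins the two relations around regions and keeps
#' triples whose TF is expressed. The graph can be serialized to Turtle for
#' interoperability with RDF tooling; the join itself is plain indexed
#' merging -- the query contract, not the storage technology, is normative.
#'
#' @name integration
NULL

#' Build a regulatory graph
#'
#' @param gene_patterns,tf_patterns,region_patterns data.frames with columns
#'   entity_id, class, pattern (as from [activity_patterns()]). TF patterns
#'   are those of their coding genes; see [tf_patterns_from_genes()].
#' @param neighbors data.frame (region_id, gene_id, distance) from
#'   [region_gene_neighbors()].
#' @param inclusions data.frame (tf_id, region_id) from
#'   [tf_region_inclusion()].
#' @param xref optional pass-through metadata data.frame (never used in the
#'   join).
#' @return a `regulatory_graph` object. Relations whose endpoints lack a
#'   pattern are dropped with a message reporting the count.
#' @export
build_graph <- function(gene_patterns, tf_patterns, region_patterns,
                        neighbors, inclusions, xref = NULL) {
  pat_map <- function(df) {
    stopifnot(all(c("entity_id", "pattern") %in% names(df)))
    check_unique_ids(df$entity_id, "pattern table")
    out <- as.character(df$pattern)
    names(out) <- as.character(df$entity_id)
    out[order(names(out))]        # canonical order: exports are reproducible
  }
  genes <- pat_map(gene_patterns)
  tfs <- pat_map(tf_patterns)
  regions <- pat_map(region_patterns)

  nb <- neighbors[neighbors$region_id %in% names(regions) &
                  neighbors$gene_id %in% names(genes), , drop = FALSE]
  inc <- inclusions[inclusions$tf_id %in% names(tfs) &
                    inclusions$region_id %in% names(regions), , drop = FALSE]
  dropped <- (nrow(neighbors) - nrow(nb)) + (nrow(inclusions) - nrow(inc))
  if (dropped > 0L)
    message(dropped, " relation(s) dropped: endpoint without a pattern")

  nb <- nb[order(nb$region_id, nb$gene_id), , drop = FALSE]
  inc <- inc[order(inc$tf_id, inc$region_id), , drop = FALSE]
  rownames(nb) <- rownames(inc) <- NULL
  structure(list(genes = genes, tfs = tfs, regions = regions,
                 region_closest = nb, tf_inclusion = inc, xref = xref),
            class = "regulatory_graph")
}

#' TF pattern table derived from the gene table
#'
#' TFs are encoded by genes; a TF inherits the class and pattern of the gene
#' with the same symbol. TFs absent from the gene table are excluded with a
#' message (they cannot be assessed for expression). Silent coding genes
#' yield silent (all-0) TFs, which the query later discards as unexpressed.
#'
#' @param tf_symbols character vector of TF symbols.
#' @param gene_patterns pattern data.frame covering the coding genes.
#' @return pattern data.frame restricted to resolvable TFs.
#' @export
tf_patterns_from_genes <- function(tf_symbols, gene_patterns) {
  tf_symbols <- unique(as.character(tf_symbols))
  hit <- tf_symbols %in% gene_patterns$entity_id
  if (any(!hit))
    message(sum(!hit), " TF(s) absent from the gene table, excluded: ",
            paste(utils::head(tf_symbols[!hit], 5L), collapse = ", "),
            if (sum(!hit) > 5L) ", ..." else "")
  idx <- match(tf_symbols[hit], gene_patterns$entity_id)
  out <- gene_patterns[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat("<regulatory_graph>\n",
      "  genes:   ", length(x$genes), "\n",
      "  tfs:     ", length(x$tfs), "\n",
      "  regions: ", length(x$regions), "\n",
      "  region_closest: ", nrow(x$region_closest), "\n",
      "  tf_inclusion:   ", nrow(x$tf_inclusion), "\n", sep = "")
  invisible(x)
}

is_silent_pattern <- function(p) grepl("^0+$", p)

#' Candidate TF-region-gene triples
#'
#' The query: every (tf, region, gene) such that the TF has a binding site
#' in the region, the region is within the neighborhood of the gene, and
#' the TF is expressed (pattern not all-0). Each triple carries the three
#' patterns and the region-gene distance.
#'
#' @param graph a `regulatory_graph`.
#' @param gene_pattern_filter optional character vector of gene patterns;
#'   when given, only triples whose gene has one of these patterns are
#'   returned.
#' @return data.frame with columns tf_id, region_id, gene_id, tf_pattern,
#'   region_pattern, gene_pattern, distance, in (tf, region, gene)
#'   lexicographic order.
#' @export
candidate_triples <- function(graph, gene_pattern_filter = NULL) {
  stopifnot(inherits(graph, "regulatory_graph"))
  inc <- graph$tf_inclusion
  inc <- inc[!is_silent_pattern(graph$tfs[inc$tf_id]), , drop = FALSE]
  out <- merge(inc, graph$region_closest, by = "region_id")
  out$tf_pattern <- unname(graph$tfs[out$tf_id])
  out$region_pattern <- unname(graph$regions[out$region_id])
  out$gene_pattern <- unname(graph$genes[out$gene_id])
  if (!is.null(gene_pattern_filter))
    out <- out[out$gene_pattern %in% gene_pattern_filter, , drop = FALSE]
  out <- out[order(out$tf_id, out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("tf_id", "region_id", "gene_id", "tf_pattern", "region_pattern",
          "gene_pattern", "distance")]
}

# ---- Turtle serialization ---------------------------------------------------

ttl_escape <- function(x) gsub('"', '\\\\"', x)
ttl_unescape <- function(x) gsub('\\\\"', '"', x)

# ids go into literals (lossless); node names are positional and synthetic.
#' Export a regulatory graph to Turtle
#'
#' Entities become typed nodes with id and pattern literals; neighborhood
#' and inclusion records become reified relation nodes (the former carrying
#' the bp distance). Node identifiers are deterministic so exports are
#' byte-for-byte reproducible; [import_graph()] round-trips losslessly.
#'
#' @param graph a `regulatory_graph`.
#' @param path output file path (`.ttl`).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "regulatory_graph"))
  ent <- function(kind, ids, patterns) {
    if (length(ids) == 0L) return(character(0))
    o <- order(ids)
    sprintf(':%s_%d a :%s ; :id "%s" ; :pattern "%s" .',
            tolower(kind), seq_along(ids), kind,
            ttl_escape(ids[o]), patterns[o])
  }
  lines <- c(
    "@prefix : <http://example.org/circuitry#> .",
    "",
    ent("Gene", names(graph$genes), unname(graph$genes)),
    ent("TF", names(graph$tfs), unname(graph$tfs)),
    ent("Region", names(graph$regions), unname(graph$regions)))
  nb <- graph$region_closest
  if (nrow(nb) > 0L)
    lines <- c(lines, sprintf(
      ':closest_%d a :RegionClosest ; :region "%s" ; :gene "%s" ; :distance %d .',
      seq_len(nrow(nb)), ttl_escape(nb$region_id), ttl_escape(nb$gene_id),
      nb$distance))
  inc <- graph$tf_inclusion
  if (nrow(inc) > 0L)
    lines <- c(lines, sprintf(
      ':inclusion_%d a :TFInclusion ; :tf "%s" ; :region "%s" .',
      seq_len(nrow(inc)), ttl_escape(inc$tf_id), ttl_escape(inc$region_id)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE, sep = "\n")
  invisible(path)
}

#' Import a regulatory graph from Turtle written by [export_graph()]
#'
#' @param path `.ttl` file path.
#' @return a `regulatory_graph`.
#' @export
import_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  grab <- function(pattern) {
    m <- regmatches(lines, regexec(pattern, lines))
    m[vapply(m, length, integer(1)) > 0L]
  }
  lit <- '"((?:[^"\\\\]|\\\\.)*)"'
  ents <- grab(paste0('a :(Gene|TF|Region) ; :id ', lit,
                      ' ; :pattern "([0-9]+)"'))
  pat_tab <- function(kind) {
    keep <- vapply(ents, function(x) x[[2]] == kind, logical(1))
    ids <- ttl_unescape(vapply(ents[keep], `[[`, character(1), 3L))
    out <- vapply(ents[keep], `[[`, character(1), 4L)
    names(out) <- ids
    out[order(ids)]
  }
  nbm <- grab(paste0('a :RegionClosest ; :region ', lit, ' ; :gene ', lit,
                     ' ; :distance ([0-9]+)'))
  nb <- data.frame(
    region_id = ttl_unescape(vapply(nbm, `[[`, character(1), 2L)),
    gene_id = ttl_unescape(vapply(nbm, `[[`, character(1), 3L)),
    distance = as.integer(vapply(nbm, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  incm <- grab(paste0('a :TFInclusion ; :tf ', lit, ' ; :region ', lit))
  inc <- data.frame(
    tf_id = ttl_unescape(vapply(incm, `[[`, character(1), 2L)),
    region_id = ttl_unescape(vapply(incm, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  nb <- nb[order(nb$region_id, nb$gene_id), , drop = FALSE]
  inc <- inc[order(inc$tf_id, inc$region_id), , drop = FALSE]
  rownames(nb) <- rownames(inc) <- NULL
  structure(list(genes = pat_tab("Gene"), tfs = pat_tab("TF"),
                 regions = pat_tab("Region"), region_closest = nb,
                 tf_inclusion = inc, xref = NULL),
            class = "regulatory_graph")
}
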