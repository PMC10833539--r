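#' Genomic linking of regions, genes and TF binding sites
#'
#' Two relations are derived from BED coordinates: region-gene neighborhood
#' (gap distance between closest extremities, capped at 500 kb, 0 for
#' overlapping or abutting intervals) and binary TF-region inclusion (a TF
#' binds a region when at least one of its binding sites overlaps it by at
#' least 1 bp). Coordinates are BED-style 0-based half-open throughout;
#' strand is ignored.
#'
#' @name genomic_links
NULL

#' Distance between two genomic intervals
#'
#' Gap length between the two closest extremities, regardless of relative
#' position: 0 when the intervals overlap or abut, `NA` when they sit on
#' different chromosomes.
#'
#' @param a,b lists or one-row data.frames with fields chrom, start, end
#'   (0-based half-open).
#' @return integer bp distance, or `NA_integer_` across chromosomes.
#' @export
interval_distance <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  if (a$chrom != b$chrom) return(NA_integer_)
  gap <- max(a$start, b$start) - min(a$end, b$end)
  as.integer(max(0L, gap))
}

as_interval <- function(x) {
  x <- as.list(x)
  stopifnot(!is.null(x$chrom), !is.null(x$start), !is.null(x$end))
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (is.na(x$start) || is.na(x$end) || x$start < 0L || x$start >= x$end)
    stop("malformed interval: need 0 <= start < end")
  x
}

#' Read a BED file into an interval table
#'
#' BED3+ is accepted; column 4, when present, supplies the interval name
#' (for TFBS files this is the TF symbol). Missing names are synthesized as
#' `<prefix>_<rownumber>`.
#'
#' @param path BED file path.
#' @param prefix name prefix for intervals lacking a name column
#'   (default "region").
#' @return data.frame with columns chrom, start, end, name.
#' @export
read_bed <- function(path, prefix = "region") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
  if (nrow(bed) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(bed) >= 4L) as.character(bed[[4]])
              else paste0(prefix, "_", seq_len(nrow(bed)))
  if (any(out$start < 0L | out$start >= out$end))
    stop("malformed BED intervals in ", path)
  out
}

# BED half-open -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    name = df$name)
}

#' Region-gene neighborhood relations
#'
#' Emits one record per (region, gene) pair on the same chromosome whose
#' gap distance is at most `max_distance` (default 500 kb); overlapping or
#' abutting pairs get distance 0.
#'
#' @param regions,genes interval data.frames (chrom, start, end, name) as
#'   returned by [read_bed()].
#' @param max_distance maximum retained distance in bp (default 500000).
#' @return data.frame with columns region_id, gene_id, distance, sorted by
#'   (region_id, gene_id).
#' @export
region_gene_neighbors <- function(regions, genes, max_distance = 500000L) {
  check_unique_ids(regions$name, "regions")
  check_unique_ids(genes$name, "genes")
  if (nrow(regions) == 0L || nrow(genes) == 0L)
    return(data.frame(region_id = character(), gene_id = character(),
                      distance = integer()))
  gr_r <- as_granges(regions)
  gr_g <- as_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g,
                                      maxgap = as.integer(max_distance),
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(gr_r[qh], gr_g[sh], ignore.strand = TRUE)
  out <- data.frame(region_id = regions$name[qh],
                    gene_id = genes$name[sh],
                    distance = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[out$distance <= max_distance, , drop = FALSE]
  out <- out[order(out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary TF-region inclusion from binding-site overlaps
#'
#' A (tf, region) pair is emitted iff at least one binding site of the TF
#' overlaps the region by at least 1 bp; multiple sites collapse to one
#' binary record.
#'
#' @param tfbs interval data.frame whose `name` column holds the TF symbol.
#' @param regions interval data.frame of regulatory regions.
#' @return data.frame with columns tf_id, region_id (deduplicated, sorted).
#' @export
tf_region_inclusion <- function(tfbs, regions) {
  check_unique_ids(regions$name, "regions")
  empty <- data.frame(tf_id = character(), region_id = character())
  if (nrow(tfbs) == 0L) {
    warning("empty TFBS input: no TF-region inclusions produced")
    return(empty)
  }
  if (nrow(regions) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(tfbs), as_granges(regions),
                                      minoverlap = 1L, ignore.strand = TRUE)
  out <- unique(data.frame(
    tf_id = tfbs$name[S4Vectors::queryHits(hits)],
    region_id = regions$name[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  out <- out[order(out$tf_id, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate ids in ", what, ": ", paste(dup, collapse = ", "))
  invisible(TRUE)
}
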