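#' Benchmarking inferred networks against curated relation tables
#'
#' Curated TF-gene databases (e.g. exports of TRRUST, Signor, CytReg,
#' HTRIdb, TFacts) cover only relations whose endpoints are measured in the
#' experiment at hand; validation therefore restricts to *reachable*
#' relations, tests enrichment of found relations with a one-sided binomial
#' test, and scores sign concordance on the signed subset.
#'
#' @name validation
NULL

norm_symbols <- function(x, normalize = TRUE, alias = NULL) {
  x <- as.character(x)
  if (normalize) x <- toupper(x)
  if (!is.null(alias)) {
    hit <- x %in% names(alias)
    x[hit] <- unname(alias[x[hit]])
  }
  x
}

#' Restrict a curated table to relations reachable in a universe
#'
#' @param db data.frame (tf_id, gene_id, sign) of curated relations; sign
#'   in {"+", "-", "unknown"}.
#' @param universe_tfs,universe_genes character vectors of ids present in
#'   the experiment.
#' @param normalize case-fold symbols before matching (default TRUE).
#' @param alias optional named character vector mapping alternate symbols
#'   to the network's symbol space.
#' @return the reachable subset of `db`, with normalized ids.
#' @export
reachable_relations <- function(db, universe_tfs, universe_genes,
                                normalize = TRUE, alias = NULL) {
  db$tf_id <- norm_symbols(db$tf_id, normalize, alias)
  db$gene_id <- norm_symbols(db$gene_id, normalize, alias)
  keep <- db$tf_id %in% norm_symbols(universe_tfs, normalize, alias) &
          db$gene_id %in% norm_symbols(universe_genes, normalize, alias)
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial enrichment of curated relations in an inferred network
#'
#' One-sided upper-tail binomial test: under the null each of the
#' `reachable` curated relations lands in the network independently with
#' probability `network_size / universe_size` (the network's density over
#' the candidate universe), and `found` of them did.
#'
#' @param found number of reachable relations present in the network.
#' @param reachable number of curated relations with both endpoints in the
#'   universe.
#' @param network_size number of relations in the inferred network.
#' @param universe_size number of possible relations in the candidate
#'   universe (default choice: all TF-gene pairs emitted by the query
#'   stage).
#' @return p-value `P(X >= found)`, `X ~ Binomial(reachable, rate)`.
#' @export
enrichment_pvalue <- function(found, reachable, network_size, universe_size) {
  if (universe_size <= 0) stop("universe_size must be positive")
  if (found > reachable) stop("found cannot exceed reachable")
  if (network_size > universe_size)
    stop("network_size cannot exceed universe_size")
  rate <- network_size / universe_size
  if (found == 0) return(1)
  stats::pbinom(found - 1, size = reachable, prob = rate, lower.tail = FALSE)
}

#' Sign concordance between an inferred network and a curated table
#'
#' Over pairs present in both: a curated pair with a single determined sign
#' matching the inferred one counts as true, mismatching as different; a
#' pair unsigned in the database, or signed both + and - (possibly across
#' entries), counts as unknown. Inferred "ND" relations also count as
#' unknown.
#'
#' @param inferred merged relation data.frame (tf_id, gene_id, sign).
#' @param db curated data.frame (tf_id, gene_id, sign).
#' @param normalize,alias see [reachable_relations()].
#' @return list with `true_pct` (percent of sign-determined shared pairs
#'   with matching sign; `NA` when none), `true_count`, `different_count`,
#'   `unknown_count`, `shared_pairs`.
#' @export
sign_concordance <- function(inferred, db, normalize = TRUE, alias = NULL) {
  inferred$tf_id <- norm_symbols(inferred$tf_id, normalize, alias)
  inferred$gene_id <- norm_symbols(inferred$gene_id, normalize, alias)
  db$tf_id <- norm_symbols(db$tf_id, normalize, alias)
  db$gene_id <- norm_symbols(db$gene_id, normalize, alias)
  key <- function(d) paste(d$tf_id, d$gene_id, sep = "\r")
  db_signs <- split(as.character(db$sign), key(db))
  inf_signs <- split(as.character(inferred$sign), key(inferred))
  shared <- intersect(names(db_signs), names(inf_signs))
  true_n <- diff_n <- unk_n <- 0L
  for (k in shared) {
    ds <- unique(db_signs[[k]]); is <- unique(inf_signs[[k]])
    ds_det <- setdiff(ds, "unknown")
    if (length(ds_det) != 1L || identical(is, "ND")) {
      unk_n <- unk_n + 1L          # unsigned, or + and - in the databases
    } else if (ds_det %in% is) {
      true_n <- true_n + 1L
    } else {
      diff_n <- diff_n + 1L
    }
  }
  determined <- true_n + diff_n
  list(true_pct = if (determined > 0L) 100 * true_n / determined else NA_real_,
       true_count = true_n, different_count = diff_n,
       unknown_count = unk_n, shared_pairs = length(shared))
}
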