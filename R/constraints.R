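#' Regulatory likelihood constraints
#'
#' The constraint engine decides, for a candidate (TF, region, gene) pattern
#' triple, whether the three level tuples are jointly consistent with an
#' activation (+) and/or an inhibition (-), under a deviation policy that
#' tolerates a bounded number of per-population departures from the perfect
#' configuration.
#'
#' The perfect gene level for a positive regulation in population i is
#' `l_i = max(1, f_i - (4 - r_i))`: a fully accessible region (r = 4)
#' transmits the TF level unchanged, and each step of lost accessibility
#' discounts it by one. Inhibition is the mirror image: the observed gene
#' level g is replaced by `5 - g`. A deviating population is *relaxed*
#' (light blue) when the gene level misses the perfect one by exactly one
#' and still satisfies the region-accessibility bound
#' `g <= max(1, f - (4 - r) + 2)`, *region-violating* (grey) when it misses
#' by one but breaks that bound, and a *fail* (white) otherwise.
#'
#' @name constraints
NULL

#' Deviation policies
#'
#' @return character vector of the four policy names: `delta0` (all
#'   populations perfect), `delta1` (at most one relaxed), `delta1_regOFF`
#'   (at most one relaxed or region-violating), `delta2` (at most two
#'   relaxed, or at most one arbitrary deviation).
#' @export
deviation_policies <- function() c("delta0", "delta1", "delta1_regOFF", "delta2")

#' Perfect gene level for a (TF level, region level) pair
#'
#' @param f_level,r_level integer levels in 1..4.
#' @param sign "+" for activation, "-" for inhibition.
#' @return integer level in 1..4: `max(1, f - (4 - r))` for "+", and
#'   `5 -` that value for "-".
#' @export
perfect_gene_level <- function(f_level, r_level, sign = c("+", "-")) {
  sign <- match.arg(sign)
  f <- as.integer(f_level); r <- as.integer(r_level)
  if (any(f < 1L | f > 4L | r < 1L | r > 4L))
    stop("levels must lie in 1..4 (constant/silent handled upstream)")
  l <- pmax(1L, f - (4L - r))
  if (sign == "-") 5L - l else l
}

#' Status of one population's levels against the constraints
#'
#' @param f,r,g integer levels in 1..4 (vectorized).
#' @param sign "+" or "-".
#' @return character vector in {"perfect", "relaxed", "region_violating",
#'   "fail"}.
#' @export
cell_status <- function(f, r, g, sign = c("+", "-")) {
  sign <- match.arg(sign)
  f <- as.integer(f); r <- as.integer(r); g <- as.integer(g)
  if (any(c(f, r, g) < 1L) || any(c(f, r, g) > 4L))
    stop("levels must lie in 1..4")
  gm <- if (sign == "-") 5L - g else g          # mirror to the positive scale
  l <- pmax(1L, f - (4L - r))
  bound <- pmax(1L, f - (4L - r) + 2L)
  dev <- abs(gm - l)
  status <- rep("fail", length(f))
  status[dev == 0L] <- "perfect"
  status[dev == 1L & gm <= bound] <- "relaxed"
  status[dev == 1L & gm > bound] <- "region_violating"
  status
}

# Vectorized core: admissibility of one sign for rows of level matrices.
# fm/rm/gm: integer matrices (rows = triples, cols = populations), levels 1..4.
admit_sign_matrix <- function(fm, rm, gm, sign, policy,
                              mode = c("cells", "sum")) {
  mode <- match.arg(mode)
  if (sign == "-") gm <- 5L - gm
  l <- pmax(1L, fm - (4L - rm))
  dev <- abs(gm - l)
  if (mode == "sum") {
    # documented alternative: summed deviation with the region bound applied
    # to every deviating population; delta1_regOFF drops the bound
    delta <- switch(policy, delta0 = 0L, delta1 = 1L,
                    delta1_regOFF = 1L, delta2 = 2L)
    ok_bound <- gm <= pmax(1L, fm - (4L - rm) + 2L)
    total <- rowSums(dev)
    if (policy == "delta1_regOFF")
      return(total <= delta)
    return(total <= delta & rowSums(dev > 0L & !ok_bound) == 0L)
  }
  bound_ok <- gm <= pmax(1L, fm - (4L - rm) + 2L)
  n_perfect <- rowSums(dev == 0L)
  n_relaxed <- rowSums(dev == 1L & bound_ok)
  n_grey    <- rowSums(dev == 1L & !bound_ok)
  n_fail    <- rowSums(dev >= 2L)
  n <- ncol(fm)
  switch(policy,
    delta0 = n_perfect == n,
    delta1 = n_fail == 0L & n_grey == 0L & n_relaxed <= 1L,
    delta1_regOFF = n_fail == 0L & (n_relaxed + n_grey) <= 1L,
    delta2 = (n_fail == 0L & n_grey == 0L & n_relaxed <= 2L) |
             (n_relaxed + n_grey + n_fail) <= 1L,
    stop("unknown policy: ", policy))
}

#' Admitted regulation signs for a pattern triple
#'
#' Evaluates both signs independently and returns the admitted set. Triples
#' in which all three patterns are constant (all-5) are consistent but
#' unsignable and return `"ND"`; a triple mixing constant and variable
#' patterns can satisfy neither sign and returns the empty set.
#'
#' @param tf_pattern,region_pattern,gene_pattern patterns as level vectors
#'   or digit strings, all the same length, none all-0.
#' @param policy one of [deviation_policies()].
#' @param mode "cells" (normative per-population cell-count semantics) or
#'   "sum" (summed-deviation alternative).
#' @return character vector: subset of `c("+", "-")`, or `"ND"`.
#' @export
evaluate_triple <- function(tf_pattern, region_pattern, gene_pattern,
                            policy = "delta1", mode = c("cells", "sum")) {
  mode <- match.arg(mode)
  policy <- match.arg(policy, deviation_policies())
  f <- as_levels(tf_pattern); r <- as_levels(region_pattern)
  g <- as_levels(gene_pattern)
  if (length(f) != length(r) || length(f) != length(g))
    stop("pattern length mismatch")
  if (any(f == 0L) || any(r == 0L) || any(g == 0L))
    stop("silent (all-0) patterns cannot enter constraint evaluation")
  const <- c(all(f == 5L), all(r == 5L), all(g == 5L))
  if (all(const)) return("ND")
  if (any(const)) return(character(0))
  fm <- matrix(f, nrow = 1L); rm <- matrix(r, nrow = 1L)
  gm <- matrix(g, nrow = 1L)
  signs <- character(0)
  if (admit_sign_matrix(fm, rm, gm, "+", policy, mode)) signs <- c(signs, "+")
  if (admit_sign_matrix(fm, rm, gm, "-", policy, mode)) signs <- c(signs, "-")
  signs
}

as_levels <- function(p) {
  if (is.character(p)) as.integer(strsplit(p, "")[[1]]) else as.integer(p)
}

#' Filter candidate triples and attribute signs
#'
#' Applies [evaluate_triple()] to every row of a candidate-triple table,
#' keeping one output row per admitted sign (including "ND" rows for
#' all-constant triples). Evaluation is vectorized over triples.
#'
#' @param triples data.frame with columns tf_id, region_id, gene_id,
#'   tf_pattern, region_pattern, gene_pattern (and optionally distance), as
#'   produced by [candidate_triples()].
#' @param policy one of [deviation_policies()] (default "delta1").
#' @param mode see [evaluate_triple()].
#' @param keep_nd keep unsignable all-constant triples as sign "ND"
#'   (default TRUE).
#' @return the surviving rows with an added `sign` column, ordered by
#'   (tf_id, region_id, gene_id, sign).
#' @export
filter_and_sign <- function(triples, policy = "delta1",
                            mode = c("cells", "sum"), keep_nd = TRUE) {
  mode <- match.arg(mode)
  policy <- match.arg(policy, deviation_policies())
  empty <- cbind(triples[0, , drop = FALSE], sign = character(0))
  if (nrow(triples) == 0L) return(empty)
  n <- nchar(triples$tf_pattern[[1]])
  fm <- pattern_levels(triples$tf_pattern)
  rm <- pattern_levels(triples$region_pattern)
  gm <- pattern_levels(triples$gene_pattern)
  is_silent <- rowSums(fm == 0L) > 0L | rowSums(rm == 0L) > 0L |
               rowSums(gm == 0L) > 0L
  if (any(is_silent))
    message(sum(is_silent), " triple(s) with a silent pattern dropped")
  is_const <- rowSums(fm == 5L) == n & rowSums(rm == 5L) == n &
              rowSums(gm == 5L) == n
  has_const <- rowSums(fm == 5L) > 0L | rowSums(rm == 5L) > 0L |
               rowSums(gm == 5L) > 0L
  variable <- !has_const & !is_silent
  is_const <- is_const & !is_silent
  pos <- neg <- rep(FALSE, nrow(triples))
  if (any(variable)) {
    pos[variable] <- admit_sign_matrix(fm[variable, , drop = FALSE],
                                       rm[variable, , drop = FALSE],
                                       gm[variable, , drop = FALSE],
                                       "+", policy, mode)
    neg[variable] <- admit_sign_matrix(fm[variable, , drop = FALSE],
                                       rm[variable, , drop = FALSE],
                                       gm[variable, , drop = FALSE],
                                       "-", policy, mode)
  }
  parts <- list(
    cbind(triples[pos, , drop = FALSE],
          sign = rep("+", sum(pos)), stringsAsFactors = FALSE),
    cbind(triples[neg, , drop = FALSE],
          sign = rep("-", sum(neg)), stringsAsFactors = FALSE))
  if (keep_nd && any(is_const))
    parts <- c(parts, list(cbind(triples[is_const, , drop = FALSE],
                                 sign = rep("ND", sum(is_const)),
                                 stringsAsFactors = FALSE)))
  out <- do.call(rbind, parts)
  out <- out[order(out$tf_id, out$region_id, out$gene_id, out$sign), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge signed TF-region-gene records to unique TF-gene relations
#'
#' Records sharing (tf, gene, sign) through different regions collapse to
#' one relation carrying all supporting region ids. A pair admitted with
#' both signs through different regions yields two records flagged
#' `conflict`.
#'
#' @param signed data.frame as returned by [filter_and_sign()].
#' @return data.frame with columns tf_id, gene_id, sign, n_regions,
#'   region_ids (comma-separated), conflict (logical), plus tf_pattern and
#'   gene_pattern.
#' @export
merge_to_tf_gene <- function(signed) {
  if (nrow(signed) == 0L)
    return(data.frame(tf_id = character(), gene_id = character(),
                      sign = character(), n_regions = integer(),
                      region_ids = character(), conflict = logical(),
                      tf_pattern = character(), gene_pattern = character()))
  dt <- data.table::as.data.table(signed)
  merged <- dt[, list(
      n_regions = length(unique(region_id)),
      region_ids = paste(sort(unique(region_id)), collapse = ","),
      tf_pattern = tf_pattern[[1]],
      gene_pattern = gene_pattern[[1]]),
    by = c("tf_id", "gene_id", "sign")]
  nsigns <- merged[, list(.nsign = sum(sign %in% c("+", "-"))),
                   by = c("tf_id", "gene_id")]
  merged <- merge(merged, nsigns, by = c("tf_id", "gene_id"))
  merged[, "conflict" := merged$sign %in% c("+", "-") & merged$.nsign > 1L]
  merged[, ".nsign" := NULL]
  out <- as.data.frame(merged)
  out <- out[order(out$tf_id, out$gene_id, out$sign), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("tf_id", "gene_id", "sign", "n_regions", "region_ids",
          "conflict", "tf_pattern", "gene_pattern")]
}
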