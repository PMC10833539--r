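#' Discretization of activity measurements into level patterns
#'
#' Per-sample activity measurements (normalized read counts for genes/TFs,
#' read densities for regulatory regions) are reduced to one discrete
#' *pattern* per entity: an n-tuple of levels, one per compared cell
#' population. Variable entities carry levels in 1..4 obtained by min-max
#' binning of the log10 per-population means; silent entities are all-0 and
#' constant entities all-5 by convention.
#'
#' @name discretize
NULL

#' Per-population log-mean activity matrix
#'
#' Averages per-sample activity within each population, adds a pseudocount,
#' and log10-transforms. This is the quantity on which level patterns are
#' computed.
#'
#' @param sample_table numeric matrix or data.frame, rows = entities
#'   (rownames = entity ids; or first column holding ids), columns = samples.
#' @param sample_map named character vector or two-column data.frame
#'   (sample, population) assigning every sample column to one population.
#' @param populations character vector giving the population order of the
#'   output. Defaults to the order of first appearance in `sample_map`.
#' @param pseudocount non-negative value added to each per-population mean
#'   before taking log10 (default 1), so that zero activity stays finite.
#' @param check_finite fail on non-finite log-means (default TRUE). Callers
#'   that discard silent rows afterwards (all-zero activity with
#'   `pseudocount = 0` gives `-Inf`) may disable the check.
#' @return numeric matrix, rows = entities, columns = populations (in the
#'   declared order), values = log10(mean + pseudocount).
#' @export
population_log_means <- function(sample_table, sample_map,
                                 populations = NULL, pseudocount = 1,
                                 check_finite = TRUE) {
  m <- as_activity_matrix(sample_table)
  map <- as_sample_map(sample_map)
  unmapped <- setdiff(colnames(m), names(map))
  if (length(unmapped) > 0L)
    stop("samples not present in sample_map: ",
         paste(unmapped, collapse = ", "))
  map <- map[colnames(m)]
  if (is.null(populations))
    populations <- unique(unname(map))
  empty <- setdiff(populations, map)
  if (length(empty) > 0L)
    stop("populations with no mapped sample: ",
         paste(empty, collapse = ", "))
  extra <- setdiff(map, populations)
  if (length(extra) > 0L)
    stop("sample_map uses populations absent from 'populations': ",
         paste(extra, collapse = ", "))
  stopifnot(pseudocount >= 0)
  out <- vapply(populations, function(p) {
    cols <- which(map == p)
    log10(rowMeans(m[, cols, drop = FALSE]) + pseudocount)
  }, numeric(nrow(m)))
  if (nrow(m) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(m), populations))
  if (check_finite && any(!is.finite(out)))
    stop("non-finite log-means; raise 'pseudocount' or check input values")
  out
}

#' Discrete activity level of one value within an entity's range
#'
#' Min-max bins a log-mean value into four equal intervals:
#' `max(1, ceiling(4 * (value - vmin) / (vmax - vmin)))`. The minimum maps
#' to level 1 and the maximum to level 4; a value exactly on an interior
#' boundary k/4 of the range gets level k (ceiling of an integer).
#'
#' @param value numeric vector of values, each within `[vmin, vmax]`.
#' @param vmin,vmax range of the entity's log-means; must satisfy
#'   `vmin < vmax` (constant entities are classified upstream, not binned).
#' @param n_bins number of equal bins (default 4; constraint tables assume 4).
#' @return integer vector of levels in 1..n_bins.
#' @export
level_of <- function(value, vmin, vmax, n_bins = 4L) {
  if (!is.finite(vmin) || !is.finite(vmax) || vmax <= vmin)
    stop("degenerate range (vmax <= vmin): classify the entity as constant")
  if (any(value < vmin | value > vmax))
    stop("value outside [vmin, vmax]")
  as.integer(pmax(1L, ceiling(n_bins * (value - vmin) / (vmax - vmin))))
}

#' Classify an entity as silent, constant or variable
#'
#' An external classification (e.g. from a differential-expression analysis)
#' always wins when supplied. Otherwise a threshold heuristic is used:
#' silent when every per-population raw mean is below `activity_floor`,
#' constant when the log-mean range is below `constancy_epsilon`, variable
#' otherwise.
#'
#' @param raw_row numeric vector of per-sample raw activities for one entity.
#' @param sample_map as in [population_log_means()]; needed when `de_info`
#'   is absent.
#' @param de_info optional external label: one of "silent", "constant",
#'   "variable".
#' @param activity_floor raw-mean threshold below which a population counts
#'   as inactive (default 1).
#' @param constancy_epsilon log10-space range below which the entity is
#'   constant (default 1e-9).
#' @param pseudocount passed to the log-mean computation.
#' @return one of "silent", "constant", "variable".
#' @export
classify_entity <- function(raw_row, sample_map = NULL, de_info = NULL,
                            activity_floor = 1, constancy_epsilon = 1e-9,
                            pseudocount = 1) {
  classes <- c("silent", "constant", "variable")
  if (!is.null(de_info)) {
    de_info <- unique(as.character(de_info))
    if (length(de_info) != 1L)
      stop("contradictory external classification labels: ",
           paste(de_info, collapse = ", "))
    if (!de_info %in% classes)
      stop("unknown classification label: ", de_info)
    return(de_info)
  }
  map <- as_sample_map(sample_map)
  if (is.null(names(raw_row)))
    names(raw_row) <- names(map)[seq_along(raw_row)]
  pops <- unique(unname(map[names(raw_row)]))
  means <- vapply(pops, function(p)
    mean(raw_row[names(map)[map == p]]), numeric(1))
  if (all(means < activity_floor))
    return("silent")
  lm <- log10(means + pseudocount)
  if (max(lm) - min(lm) < constancy_epsilon)
    return("constant")
  "variable"
}

#' Level pattern of one entity
#'
#' Silent entities get the all-0 pattern, constant entities the all-5
#' pattern, and variable entities the element-wise [level_of()] of their
#' log-means with the row min/max as range. Every variable pattern
#' therefore contains at least one 1 and one 4.
#'
#' @param values numeric vector of per-population log-means (one row of the
#'   matrix returned by [population_log_means()]).
#' @param cls entity class, one of "silent", "constant", "variable".
#' @return a `circuit_pattern`: integer vector of levels with a string form
#'   (see [pattern_string()]).
#' @export
pattern_of <- function(values, cls = c("variable", "silent", "constant")) {
  cls <- match.arg(cls)
  n <- length(values)
  if (n > 9L)
    stop("patterns support at most 9 populations (one digit per level)")
  levels <- switch(cls,
    silent   = rep(0L, n),
    constant = rep(5L, n),
    variable = {
      vmin <- min(values); vmax <- max(values)
      if (vmax <= vmin)
        stop("zero range for a variable entity: classify it as constant")
      level_of(values, vmin, vmax)
    })
  new_pattern(levels)
}

#' @rdname pattern_of
#' @param levels integer vector of levels.
#' @export
new_pattern <- function(levels) {
  levels <- as.integer(levels)
  if (!(all(levels == 0L) || all(levels == 5L) ||
        all(levels >= 1L & levels <= 4L)))
    stop("invalid pattern: must be all-0, all-5, or all levels in 1..4")
  if (all(levels >= 1L & levels <= 4L) &&
      !(any(levels == 1L) && any(levels == 4L)))
    stop("invalid variable pattern: must contain a 1 and a 4")
  structure(levels, class = "circuit_pattern")
}

#' Pattern string form
#'
#' @param p a `circuit_pattern` or integer vector of levels.
#' @return single string of concatenated digits, e.g. `"1124"`.
#' @export
pattern_string <- function(p) paste(as.integer(p), collapse = "")

#' Parse a pattern string back to levels
#'
#' @param s character vector of digit strings.
#' @return integer matrix, one row per string.
#' @export
pattern_levels <- function(s) {
  t(vapply(strsplit(as.character(s), ""),
           function(x) as.integer(x), integer(nchar(s[[1]]))))
}

#' @export
print.circuit_pattern <- function(x, ...) {
  cat("<pattern> ", pattern_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.circuit_pattern <- function(x, ...) pattern_string(x)

#' Discretize a full activity table into classes and patterns
#'
#' End-to-end wrapper: computes per-population log-means, classifies each
#' entity (honouring external labels when given) and emits its pattern.
#'
#' @inheritParams population_log_means
#' @param de_info optional named character vector (entity id -> label) of
#'   external classifications; entities absent from it fall back to the
#'   heuristic.
#' @param activity_floor,constancy_epsilon see [classify_entity()].
#' @return data.frame with columns entity_id, class, pattern.
#' @export
activity_patterns <- function(sample_table, sample_map, populations = NULL,
                              pseudocount = 1, de_info = NULL,
                              activity_floor = 1, constancy_epsilon = 1e-9) {
  m <- as_activity_matrix(sample_table)
  map <- as_sample_map(sample_map)
  lm <- population_log_means(m, map, populations, pseudocount,
                             check_finite = FALSE)
  ids <- rownames(m)
  cls <- vapply(ids, function(id) {
    ext <- if (!is.null(de_info) && id %in% names(de_info)) de_info[[id]]
    classify_entity(m[id, ], map, de_info = ext,
                    activity_floor = activity_floor,
                    constancy_epsilon = constancy_epsilon,
                    pseudocount = pseudocount)
  }, character(1))
  bad <- cls != "silent" & !apply(is.finite(lm), 1, all)
  if (any(bad))
    stop("non-finite log-means for non-silent entities: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "),
         "; raise 'pseudocount'")
  pat <- vapply(ids, function(id)
    pattern_string(pattern_of(lm[id, ], cls[[id]])), character(1))
  data.frame(entity_id = ids, class = unname(cls), pattern = unname(pat),
             stringsAsFactors = FALSE)
}

# ---- input coercion helpers -------------------------------------------------

as_activity_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("activity matrix needs entity rownames")
    return(x)
  }
  x <- as.data.frame(x)
  if (is.character(x[[1]]) || is.factor(x[[1]])) {
    ids <- as.character(x[[1]])
    if (anyDuplicated(ids))
      stop("duplicate entity ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    return(m)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m))) stop("activity table needs entity ids")
  m
}

as_sample_map <- function(x) {
  if (is.null(x)) stop("a sample -> population map is required")
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2L)
    out <- as.character(x[[2]])
    names(out) <- as.character(x[[1]])
    return(out)
  }
  if (is.null(names(x))) stop("sample_map must be named by sample")
  vapply(x, as.character, character(1))
}
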