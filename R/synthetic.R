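#' Synthetic input bundles with planted signed regulations
#'
#' The generator emits a complete, self-consistent input bundle (per-sample
#' expression and region-activity tables, sample maps, BED coordinates for
#' genes, regions and TF binding sites) together with the planted ground
#' truth, so the whole pipeline -- including the discretization stage -- can
#' be exercised without external data. Planted gene patterns are the unique
#' perfect completions of their (TF, region, sign), so noise-free recall at
#' delta0 is 1 by construction; raw values are produced by inverse
#' discretization with within-population jitter rescaled to exact means.
#'
#' @name synthetic_fixtures
NULL

#' Fixture specification
#'
#' @param n_populations number of cell populations (2..9, default 4).
#' @param n_genes number of target genes, planted plus decoys (default 50).
#' @param n_tfs number of TFs (default 10).
#' @param n_regions number of regulatory regions, planted plus decoys
#'   (default 30).
#' @param n_planted number of planted signed TF-region-gene relations;
#'   each uses its own gene and region (default 20).
#' @param noise "none" or "one_cell": with `noise_prob` per planted
#'   relation, move exactly one population of the gene pattern by one
#'   level (a deviation recoverable at delta1 but not delta0).
#' @param noise_prob per-relation perturbation probability (default 0.5).
#' @param samples_per_population replicates per population in the
#'   expression table (default 3; regions use 2).
#' @param seed integer seed; fully determines the bundle.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_populations = 4L, n_genes = 50L, n_tfs = 10L,
                         n_regions = 30L, n_planted = 20L,
                         noise = c("none", "one_cell"), noise_prob = 0.5,
                         samples_per_population = 3L, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_populations >= 2L, n_populations <= 9L,
            n_planted <= n_genes, n_planted <= n_regions,
            n_planted <= n_tfs * n_genes, n_tfs >= 1L,
            samples_per_population >= 2L)
  structure(list(n_populations = as.integer(n_populations),
                 n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_regions = as.integer(n_regions),
                 n_planted = as.integer(n_planted), noise = noise,
                 noise_prob = noise_prob,
                 samples_per_population = as.integer(samples_per_population),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

random_variable_pattern <- function(n) {
  repeat {
    p <- sample(1:4, n, replace = TRUE)
    if (any(p == 1L) && any(p == 4L)) return(p)
  }
}

#' Perfect gene pattern completing a (TF, region, sign) plant
#'
#' Inverts the constraint equations: for each population the planted gene
#' level is the perfect level of the (TF level, region level) pair under
#' the requested sign. Returns `NULL` when the perfect pattern is not a
#' valid variable pattern (it must contain both a 1 and a 4), in which
#' case the caller resamples.
#'
#' @param tf_pattern,region_pattern valid variable patterns (levels or
#'   digit strings).
#' @param sign "+" or "-".
#' @return integer level vector, or `NULL` when infeasible.
#' @export
plant_regulation <- function(tf_pattern, region_pattern, sign = c("+", "-")) {
  sign <- match.arg(sign)
  f <- as_levels(tf_pattern); r <- as_levels(region_pattern)
  stopifnot(length(f) == length(r))
  g <- perfect_gene_level(f, r, sign)
  if (any(g == 1L) && any(g == 4L)) g else NULL
}

# one-cell perturbation that keeps the pattern valid and delta1-recoverable.
# On the positive (mirrored for "-") scale the perturbed cell must end up
# one *below* the perfect level -- always a relaxed (light-blue) cell -- or,
# as a fallback, one above it while still inside the region bound.
perturb_one_cell <- function(g, f, r, sign) {
  step <- if (sign == "+") -1L else 1L   # away from the perfect level,
                                         # downward on the mirrored scale
  movable <- function(delta) {
    gn <- g + delta
    ok <- gn >= 1L & gn <= 4L
    # keep validity: never remove the only 1 or the only 4
    ok & !(g == 1L & sum(g == 1L) == 1L) & !(g == 4L & sum(g == 4L) == 1L)
  }
  safe <- which(movable(step))
  if (length(safe) > 0L) {
    i <- if (length(safe) == 1L) safe else sample(safe, 1L)
    g[i] <- g[i] + step
    return(g)
  }
  # fallback: move toward the bound; only when the relaxed region condition
  # still holds on the mirrored scale (the cell stays light blue, not grey)
  fb <- which(movable(-step))
  for (i in fb) {
    gm <- if (sign == "+") g[i] - step else 5L - (g[i] - step)
    if (gm <= max(1L, f[i] - (4L - r[i]) + 2L)) {
      g[i] <- g[i] - step
      return(g)
    }
  }
  NULL
}

# raw per-sample values realizing a target pattern: level k maps to the
# log10 mean lo + (k-1)/3 * (hi-lo), so re-discretization returns k exactly;
# jitter is rescaled so per-population means are exact
raw_values_for <- function(levels, cls, n_samples, pseudocount = 1,
                           lo = 1, hi = 3, jitter = 0.05) {
  n <- length(levels)
  if (cls == "silent") return(rep(0, n * n_samples))
  target_means <- if (cls == "constant") rep(10^2 - pseudocount, n)
                  else 10^(lo + (levels - 1L) / 3 * (hi - lo)) - pseudocount
  unlist(lapply(target_means, function(m) {
    u <- 1 + stats::runif(n_samples, -jitter, jitter)
    m * u / mean(u)
  }), use.names = FALSE)
}

#' Generate a synthetic fixture bundle
#'
#' Writes `expression.tsv`, `expression_samples.tsv`, `regions.tsv`,
#' `region_samples.tsv`, `genes.bed`, `regions.bed`, `tfbs.bed` and
#' `ground_truth.tsv` under `dir`. Planted (region, gene) pairs sit within
#' 500 kb on one chromosome; planted TFBS sit inside their regions; decoy
#' regions/TFBS are placed near decoy genes with rejection against
#' accidentally perfect triples (logged when rejection fails). TF coding
#' genes are included in the expression table (on a separate chromosome,
#' away from all regions). Byte-identical across runs with the same spec.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths), `truth` (data.frame tf,
#'   region, gene, sign, perturbed) and `spec`, invisibly classed
#'   `fixture_bundle`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_populations
  pops <- paste0("P", seq_len(n))

  tf_ids <- sprintf("TF%02d", seq_len(spec$n_tfs))
  gene_ids <- sprintf("G%03d", seq_len(spec$n_genes))
  region_ids <- sprintf("ATAC_%d", seq_len(spec$n_regions))

  tf_pat <- lapply(seq_len(spec$n_tfs), function(i) random_variable_pattern(n))
  names(tf_pat) <- tf_ids

  # planted relations: gene i and region i are dedicated to relation i
  truth <- data.frame(tf = character(0), region = character(0),
                      gene = character(0), sign = character(0),
                      perturbed = logical(0), stringsAsFactors = FALSE)
  gene_pat <- vector("list", spec$n_genes); names(gene_pat) <- gene_ids
  gene_cls <- rep("variable", spec$n_genes); names(gene_cls) <- gene_ids
  region_pat <- vector("list", spec$n_regions); names(region_pat) <- region_ids

  for (i in seq_len(spec$n_planted)) {
    repeat {
      tf <- sample(tf_ids, 1L)
      sign <- sample(c("+", "-"), 1L)
      rp <- random_variable_pattern(n)
      g <- plant_regulation(tf_pat[[tf]], rp, sign)
      if (!is.null(g)) break
    }
    perturbed <- FALSE
    if (spec$noise == "one_cell" && stats::runif(1) < spec$noise_prob) {
      g2 <- perturb_one_cell(g, tf_pat[[tf]], rp, sign)
      if (!is.null(g2)) { g <- g2; perturbed <- TRUE }
    }
    region_pat[[region_ids[[i]]]] <- rp
    gene_pat[[gene_ids[[i]]]] <- g
    truth <- rbind(truth, data.frame(
      tf = tf, region = region_ids[[i]], gene = gene_ids[[i]], sign = sign,
      perturbed = perturbed, stringsAsFactors = FALSE))
  }

  # decoy genes: mostly variable, some silent/constant to exercise classes
  decoy_genes <- gene_ids[-seq_len(spec$n_planted)]
  for (id in decoy_genes) {
    u <- stats::runif(1)
    if (u < 0.1) {
      gene_cls[[id]] <- "silent"; gene_pat[[id]] <- rep(0L, n)
    } else if (u < 0.2) {
      gene_cls[[id]] <- "constant"; gene_pat[[id]] <- rep(5L, n)
    } else {
      gene_pat[[id]] <- random_variable_pattern(n)
    }
  }
  for (id in region_ids[-seq_len(spec$n_planted)])
    region_pat[[id]] <- random_variable_pattern(n)

  # coordinates: target genes spaced 2 Mb on chr1 (planted region 50 kb
  # upstream of its gene); TF coding genes on chr2, no region nearby
  gene_start <- 2e6 * seq_len(spec$n_genes)
  genes_bed <- data.frame(chrom = "chr1", start = as.integer(gene_start),
                          end = as.integer(gene_start + 10000),
                          name = gene_ids, stringsAsFactors = FALSE)
  tf_start <- 2e6 * seq_len(spec$n_tfs)
  genes_bed <- rbind(genes_bed, data.frame(
    chrom = "chr2", start = as.integer(tf_start),
    end = as.integer(tf_start + 10000), name = tf_ids,
    stringsAsFactors = FALSE))

  region_anchor <- integer(spec$n_regions)  # index of the gene each region sits near
  region_anchor[seq_len(spec$n_planted)] <- seq_len(spec$n_planted)
  n_decoy_r <- spec$n_regions - spec$n_planted
  if (n_decoy_r > 0L) {
    pool <- seq(spec$n_planted + 1L, spec$n_genes)
    region_anchor[(spec$n_planted + 1L):spec$n_regions] <-
      sample(pool, n_decoy_r, replace = TRUE)
  }
  r_start <- as.integer(gene_start[region_anchor] - 50000)
  regions_bed <- data.frame(chrom = "chr1", start = r_start,
                            end = r_start + 500L, name = region_ids,
                            stringsAsFactors = FALSE)

  # TFBS: planted TF inside its region; decoy TFBS (random TF) in decoy regions
  tfbs <- data.frame(chrom = "chr1", start = r_start[seq_len(spec$n_planted)] + 100L,
                     end = r_start[seq_len(spec$n_planted)] + 110L,
                     name = truth$tf, stringsAsFactors = FALSE)
  if (n_decoy_r > 0L) {
    decoy_idx <- (spec$n_planted + 1L):spec$n_regions
    tfbs <- rbind(tfbs, data.frame(
      chrom = "chr1", start = r_start[decoy_idx] + 100L,
      end = r_start[decoy_idx] + 110L,
      name = sample(tf_ids, n_decoy_r, replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # rejection: a decoy (tf, region, gene-near-region) combination must not
  # form an accidentally perfect triple at delta0
  if (n_decoy_r > 0L) {
    for (j in (spec$n_planted + 1L):spec$n_regions) {
      tf <- tfbs$name[[j]]
      gid <- gene_ids[[region_anchor[[j]]]]
      if (gene_cls[[gid]] != "variable") next
      ok <- FALSE
      for (try in 1:20) {
        signs <- evaluate_triple(tf_pat[[tf]], region_pat[[region_ids[[j]]]],
                                 gene_pat[[gid]], policy = "delta0")
        if (length(signs) == 0L) { ok <- TRUE; break }
        region_pat[[region_ids[[j]]]] <- random_variable_pattern(n)
      }
      if (!ok) message("decoy rejection failed for region ", region_ids[[j]],
                       ": accidental perfect triple kept")
    }
  }

  # inverse discretization -> per-sample tables
  expr_samples <- as.vector(outer(seq_len(spec$samples_per_population), pops,
                                  function(s, p) paste0(p, "_s", s)))
  expr_samples <- sort(expr_samples)
  all_gene_ids <- c(gene_ids, tf_ids)
  all_pat <- c(gene_pat, tf_pat)
  all_cls <- c(gene_cls, stats::setNames(rep("variable", spec$n_tfs), tf_ids))
  expr <- t(vapply(all_gene_ids, function(id) {
    v <- raw_values_for(all_pat[[id]], all_cls[[id]],
                        spec$samples_per_population)
    names(v) <- as.vector(vapply(pops, function(p)
      paste0(p, "_s", seq_len(spec$samples_per_population)), character(spec$samples_per_population)))
    v[expr_samples]
  }, numeric(length(expr_samples))))

  reg_samples <- as.vector(vapply(pops, function(p)
    paste0(p, "_r", 1:2), character(2)))
  reg <- t(vapply(region_ids, function(id) {
    v <- raw_values_for(region_pat[[id]], "variable", 2L)
    names(v) <- reg_samples
    v
  }, numeric(length(reg_samples))))

  # write bundle
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             expression_samples = file.path(dir, "expression_samples.tsv"),
             regions = file.path(dir, "regions.tsv"),
             region_samples = file.path(dir, "region_samples.tsv"),
             genes_bed = file.path(dir, "genes.bed"),
             regions_bed = file.path(dir, "regions.bed"),
             tfbs_bed = file.path(dir, "tfbs.bed"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_activity_tsv(expr, "gene_id", paths[["expression"]])
  write_tsv(data.frame(sample = expr_samples,
                       population = sub("_s[0-9]+$", "", expr_samples)),
            paths[["expression_samples"]])
  write_activity_tsv(reg, "region_id", paths[["regions"]])
  write_tsv(data.frame(sample = reg_samples,
                       population = sub("_r[0-9]+$", "", reg_samples)),
            paths[["region_samples"]])
  write_bed(genes_bed, paths[["genes_bed"]])
  write_bed(regions_bed, paths[["regions_bed"]])
  write_bed(tfbs, paths[["tfbs_bed"]])
  write_tsv(truth, paths[["ground_truth"]])

  invisible(structure(list(paths = paths, truth = truth, spec = spec,
                           populations = pops),
                      class = "fixture_bundle"))
}
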