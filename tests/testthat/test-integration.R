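test_that("toy world: graph counts and the 4-triple join", {
  g <- make_toy_graph()
  expect_equal(length(g$genes) + length(g$tfs) + length(g$regions), 6L)
  expect_equal(nrow(g$region_closest) + nrow(g$tf_inclusion), 6L)

  tr <- candidate_triples(g)
  expect_equal(nrow(tr), 4L)
  expect_equal(paste(tr$tf_id, tr$region_id, tr$gene_id),
               c("TF1 ATAC_1 G1", "TF1 ATAC_2 G1", "TF1 ATAC_2 G2",
                 "TF2 ATAC_1 G1"))
  expect_equal(tr$tf_pattern[tr$tf_id == "TF2"], "1144")

  filt <- candidate_triples(g, gene_pattern_filter = "1124")
  expect_true(all(filt$gene_pattern == "1124"))
  expect_equal(nrow(filt), 3L)
})

test_that("silent TFs are excluded from the join", {
  g <- make_toy_graph()
  g$tfs[] <- c("0000", "0000")
  expect_equal(nrow(candidate_triples(g)), 0L)
})

test_that("relations with missing endpoints are dropped with a message", {
  genes <- data.frame(entity_id = "G1", class = "variable",
                      pattern = "1124", stringsAsFactors = FALSE)
  tfs <- genes; tfs$entity_id <- "TF1"
  regions <- genes; regions$entity_id <- "R1"
  nb <- data.frame(region_id = c("R1", "R_missing"), gene_id = "G1",
                   distance = 0L, stringsAsFactors = FALSE)
  inc <- data.frame(tf_id = "TF1", region_id = "R1",
                    stringsAsFactors = FALSE)
  expect_message(g <- build_graph(genes, tfs, regions, nb, inc),
                 "1 relation")
  expect_equal(nrow(g$region_closest), 1L)
})

test_that("tf_patterns_from_genes resolves symbols against the gene table", {
  genes <- data.frame(entity_id = c("BACH2", "IRF4", "SIL1"),
                      class = c("variable", "variable", "silent"),
                      pattern = c("4441", "1114", "0000"),
                      stringsAsFactors = FALSE)
  expect_message(tfp <- tf_patterns_from_genes(c("BACH2", "SIL1", "NOPE"),
                                               genes),
                 "absent from the gene table")
  expect_equal(tfp$entity_id, c("BACH2", "SIL1"))
  # a TF whose coding gene is silent is carried with the all-0 pattern
  expect_equal(tfp$pattern[tfp$entity_id == "SIL1"], "0000")
})

test_that("candidate_triples equals the brute-force triple loop", {
  set.seed(77)
  for (trial in 1:5) {
    n_g <- 8L; n_t <- 5L; n_r <- 6L
    genes <- data.frame(entity_id = paste0("G", 1:n_g), class = "variable",
                        pattern = vapply(1:n_g, function(i)
                          pattern_string(random_variable_pattern(3)),
                          character(1)), stringsAsFactors = FALSE)
    tfs <- data.frame(entity_id = paste0("TF", 1:n_t), class = "variable",
                      pattern = c("000", vapply(2:n_t, function(i)
                        pattern_string(random_variable_pattern(3)),
                        character(1))), stringsAsFactors = FALSE)
    regions <- data.frame(entity_id = paste0("R", 1:n_r), class = "variable",
                          pattern = vapply(1:n_r, function(i)
                            pattern_string(random_variable_pattern(3)),
                            character(1)), stringsAsFactors = FALSE)
    nb <- unique(data.frame(
      region_id = sample(regions$entity_id, 10, TRUE),
      gene_id = sample(genes$entity_id, 10, TRUE),
      stringsAsFactors = FALSE))
    nb$distance <- sample(0:500000, nrow(nb))
    inc <- unique(data.frame(
      tf_id = sample(tfs$entity_id, 10, TRUE),
      region_id = sample(regions$entity_id, 10, TRUE),
      stringsAsFactors = FALSE))
    g <- build_graph(genes, tfs, regions, nb, inc)
    got <- candidate_triples(g)[, c("tf_id", "region_id", "gene_id")]
    expect_equal(got, oracle_triples(g))

    # monotone: adding relations never removes triples
    g2 <- g
    g2$region_closest <- rbind(g2$region_closest,
                               data.frame(region_id = "R1", gene_id = "G1",
                                          distance = 1L))
    g2$region_closest <- unique(g2$region_closest)
    expect_gte(nrow(candidate_triples(g2)), nrow(got))
  }
})

test_that("Turtle export round-trips losslessly", {
  g <- make_toy_graph()
  path <- tempfile(fileext = ".ttl")
  export_graph(g, path)
  g2 <- import_graph(path)
  expect_equal(g2$genes, g$genes)
  expect_equal(g2$tfs, g$tfs)
  expect_equal(g2$regions, g$regions)
  expect_equal(g2$region_closest, g$region_closest)
  expect_equal(g2$tf_inclusion, g$tf_inclusion)

  # unicode and quoted ids survive
  gu <- g
  names(gu$genes)[1] <- "Géne\"1"
  gu$region_closest$gene_id[gu$region_closest$gene_id == "G1"] <- "Géne\"1"
  gu$region_closest <- gu$region_closest[
    order(gu$region_closest$region_id, gu$region_closest$gene_id), ]
  rownames(gu$region_closest) <- NULL
  gu$genes <- gu$genes[order(names(gu$genes))]
  export_graph(gu, path)
  gu2 <- import_graph(path)
  expect_equal(gu2$genes, gu$genes)
  expect_equal(gu2$region_closest, gu$region_closest)

  # empty graph round-trips
  empty <- build_graph(
    data.frame(entity_id = character(), class = character(),
               pattern = character()),
    data.frame(entity_id = character(), class = character(),
               pattern = character()),
    data.frame(entity_id = character(), class = character(),
               pattern = character()),
    data.frame(region_id = character(), gene_id = character(),
               distance = integer()),
    data.frame(tf_id = character(), region_id = character()))
  export_graph(empty, path)
  e2 <- import_graph(path)
  expect_equal(length(e2$genes), 0L)
  expect_equal(nrow(candidate_triples(e2)), 0L)

  # byte-identical re-export
  path2 <- tempfile(fileext = ".ttl")
  export_graph(g, path); export_graph(g, path2)
  expect_identical(readLines(path), readLines(path2))
})
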