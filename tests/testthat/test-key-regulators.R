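make_relations <- function(targets) {
  # targets: named list tf -> data.frame(gene_id, gene_pattern)
  do.call(rbind, lapply(names(targets), function(tf)
    data.frame(tf_id = tf, gene_id = targets[[tf]]$gene_id,
               gene_pattern = targets[[tf]]$gene_pattern, sign = "+",
               tf_pattern = "1144", stringsAsFactors = FALSE)))
}

test_that("coverage and specificity are the stated proportions", {
  genes <- data.frame(entity_id = paste0("G", 1:30),
                      pattern = rep(c("1124", "4441"), c(20, 10)),
                      stringsAsFactors = FALSE)
  rel <- make_relations(list(
    TFA = data.frame(gene_id = paste0("G", 1:5), gene_pattern = "1124"),
    TFB = data.frame(gene_id = c("G1", paste0("G", 21:23)),
                     gene_pattern = c("1124", rep("4441", 3)))))
  expect_equal(coverage("TFA", "1124", rel, genes), 25)   # 5 of 20
  expect_equal(coverage("TFB", "4441", rel, genes), 30)   # 3 of 10
  expect_equal(coverage("TFA", "4441", rel, genes), 0)
  expect_error(coverage("TFA", "9999", rel, genes), "no gene")

  expect_equal(specificity("TFA", "1124", rel), 100)
  expect_equal(specificity("TFB", "1124", rel), 25)       # 1 of 4 targets
  expect_equal(specificity("TFB", "4441", rel), 75)
  expect_error(specificity("TFC", "1124", rel), "no target")

  # a 1-gene pattern is trivially fully covered (small-pattern caveat)
  tiny <- rbind(genes, data.frame(entity_id = "G99", pattern = "1114"))
  rel2 <- rbind(rel, data.frame(tf_id = "TFA", gene_id = "G99",
                                gene_pattern = "1114", sign = "+",
                                tf_pattern = "1144"))
  expect_equal(coverage("TFA", "1114", rel2, tiny), 100)
})

test_that("specificity of each TF sums to 100 across patterns", {
  set.seed(13)
  genes <- data.frame(entity_id = paste0("G", 1:40),
                      pattern = sample(c("1124", "4441", "1114"), 40, TRUE),
                      stringsAsFactors = FALSE)
  rel <- do.call(rbind, lapply(paste0("TF", 1:6), function(tf) {
    targets <- sample(genes$entity_id, sample(3:15, 1))
    data.frame(tf_id = tf, gene_id = targets,
               gene_pattern = genes$pattern[match(targets, genes$entity_id)],
               sign = "+", tf_pattern = "1144", stringsAsFactors = FALSE)
  }))
  met <- regulator_metrics(rel, genes)
  sums <- tapply(met$specificity, met$tf_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # metrics invariant under gene renaming
  ren <- function(x) paste0("X_", x)
  rel2 <- rel; rel2$gene_id <- ren(rel2$gene_id)
  genes2 <- genes; genes2$entity_id <- ren(genes2$entity_id)
  met2 <- regulator_metrics(rel2, genes2)
  expect_equal(met2$coverage, met$coverage)
  expect_equal(met2$specificity, met$specificity)
})

test_that("select_key_regulators applies joint thresholds per policy", {
  set.seed(19)
  metrics <- data.frame(tf_id = paste0("TF", 1:40),
                        pattern = "1124",
                        coverage = runif(40, 0, 100),
                        specificity = runif(40, 0, 100),
                        stringsAsFactors = FALSE)
  sel <- select_key_regulators(metrics, list(type = "quantile", q = 0.75))
  qc <- quantile(metrics$coverage, 0.75, type = 7, names = FALSE)
  qs <- quantile(metrics$specificity, 0.75, type = 7, names = FALSE)
  expect_equal(sort(sel$tf_id),
               sort(metrics$tf_id[metrics$coverage >= qc &
                                  metrics$specificity >= qs]))

  perfect <- select_key_regulators(metrics, list(type = "fixed",
                                                 coverage = 100,
                                                 specificity = 100))
  expect_equal(nrow(perfect), 0L)
  metrics2 <- rbind(metrics, data.frame(tf_id = "TFSTAR", pattern = "1124",
                                        coverage = 100, specificity = 100))
  sel2 <- select_key_regulators(metrics2, list(type = "fixed",
                                               coverage = 100,
                                               specificity = 100))
  expect_equal(sel2$tf_id, "TFSTAR")

  # degenerate single-row distribution: the row is its own quantile, kept
  one <- metrics[1, , drop = FALSE]
  expect_equal(nrow(select_key_regulators(one,
                                          list(type = "quantile", q = 0.75))),
               1L)

  # monotone: raising a fixed threshold never adds pairs
  lo <- select_key_regulators(metrics, list(type = "fixed", coverage = 30,
                                            specificity = 30))
  hi <- select_key_regulators(metrics, list(type = "fixed", coverage = 60,
                                            specificity = 30))
  expect_true(all(hi$tf_id %in% lo$tf_id))
})

test_that("annotation scores are weighted count sums", {
  go <- data.frame(tf_id = c("TFA", "TFA", "TFA", "TFB"),
                   term_id = c("GO:1", "GO:2", "GO:9", "GO:1"),
                   stringsAsFactors = FALSE)
  cites <- data.frame(tf_id = c("TFA", "TFB"),
                      context_count = c(10L, 0L),
                      broad_count = c(100L, 5L), stringsAsFactors = FALSE)
  terms <- c("GO:1", "GO:2")
  sc <- annotation_score(c("TFA", "TFB"), go, cites, go_terms = terms)
  expect_equal(sc$composite[sc$tf_id == "TFA"], 112)   # 2 + 10 + 100
  sc2 <- annotation_score("TFA", go, cites, go_terms = terms,
                          weights = c(2, 1, 0))
  expect_equal(sc2$composite, 14)
  expect_warning(sc3 <- annotation_score("TFZ", go, cites, go_terms = terms),
                 "absent")
  expect_equal(sc3$composite, 0)   # null score: not studied yet
})
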