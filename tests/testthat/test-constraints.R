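test_that("perfect_gene_level follows the accessibility-discounted formula", {
  expect_equal(perfect_gene_level(4, 4, "+"), 4L)
  expect_equal(perfect_gene_level(4, 1, "+"), 1L)
  expect_equal(perfect_gene_level(4, 4, "-"), 1L)
  expect_equal(perfect_gene_level(3, 2, "-"), 4L)   # 5 - max(1, 3 - 2) = 4
  expect_error(perfect_gene_level(0, 4, "+"), "1..4")
  expect_error(perfect_gene_level(4, 5, "+"), "1..4")
})

test_that("cell_status distinguishes perfect, relaxed, grey and fail", {
  expect_equal(cell_status(4, 3, 3, "+"), "perfect")
  expect_equal(cell_status(4, 3, 4, "+"), "relaxed")          # l=3, bound=5
  expect_equal(cell_status(1, 1, 2, "+"), "region_violating") # l=1, bound=1
  expect_equal(cell_status(4, 4, 1, "+"), "fail")             # |g-l| = 3
  # negative sign mirrors through 5-g
  expect_equal(cell_status(4, 3, 2, "-"), "perfect")
  expect_equal(cell_status(1, 1, 3, "-"), "region_violating")
})

test_that("cell_status matches the enumeration-built class table", {
  combos <- all_level_tuples(3)   # (f, r, g) over 4^3 cells
  for (sign in c("+", "-")) {
    key <- if (sign == "+") "pos" else "neg"
    got <- cell_status(combos[, 1], combos[, 2], combos[, 3], sign)
    want <- vapply(seq_len(nrow(combos)), function(i)
      .class_table[combos[i, 1], combos[i, 2], combos[i, 3], key],
      character(1))
    map <- c(dark = "perfect", light = "relaxed", grey = "region_violating",
             white = "fail")
    expect_equal(got, unname(map[want]))
  }
})

test_that("evaluate_triple: worked sign attributions", {
  expect_equal(evaluate_triple("4441", "4441", "4441", "delta0"), "+")
  expect_equal(evaluate_triple("4441", "4441", "1114", "delta0"), "-")
  # cell 3 deviates by one (l = 3, g = 4): rejected at delta0, relaxed at delta1
  expect_equal(evaluate_triple("4441", "4431", "4441", "delta0"), character(0))
  expect_equal(evaluate_triple("4441", "4431", "4441", "delta1"), "+")
  # all-constant triples are consistent but unsignable
  for (p in deviation_policies())
    expect_equal(evaluate_triple("5555", "5555", "5555", p), "ND")
  # mixed constant/variable triples can satisfy neither sign
  expect_equal(evaluate_triple("5555", "1144", "1144", "delta2"),
               character(0))
  expect_error(evaluate_triple("14", "1144", "1144", "delta0"), "mismatch")
  expect_error(evaluate_triple("0000", "1144", "1144", "delta0"), "silent")
})

test_that("equation evaluator equals the table-driven oracle exhaustively", {
  for (n in 2:3) {
    tuples <- all_level_tuples(n)
    idx <- expand.grid(f = seq_len(nrow(tuples)), r = seq_len(nrow(tuples)),
                       g = seq_len(nrow(tuples)))
    fm <- tuples[idx$f, , drop = FALSE]
    rm_ <- tuples[idx$r, , drop = FALSE]
    gm <- tuples[idx$g, , drop = FALSE]
    # spot-check the full cross with the per-row oracle on a fixed sample,
    # and the whole set via the vectorized path in test-acceptance.R
    set.seed(5)
    rows <- sample(nrow(idx), 400)
    for (policy in deviation_policies()) {
      for (sign in c("+", "-")) {
        got <- circuitry:::admit_sign_matrix(fm[rows, , drop = FALSE],
                                             rm_[rows, , drop = FALSE],
                                             gm[rows, , drop = FALSE],
                                             sign, policy)
        want <- vapply(seq_along(rows), function(k)
          oracle_admit(fm[rows[k], ], rm_[rows[k], ], gm[rows[k], ],
                       sign, policy), logical(1))
        expect_equal(unname(got), want)
      }
    }
  }
})

test_that("exactly one perfect gene pattern exists per (f, r) pair and sign", {
  tuples <- all_level_tuples(2)
  for (i in seq_len(nrow(tuples))) for (j in seq_len(nrow(tuples))) {
    for (sign in c("+", "-")) {
      perfect <- vapply(seq_len(nrow(tuples)), function(g)
        circuitry:::admit_sign_matrix(tuples[i, , drop = FALSE],
                                      tuples[j, , drop = FALSE],
                                      tuples[g, , drop = FALSE],
                                      sign, "delta0"), logical(1))
      expect_equal(sum(perfect), 1L)
    }
  }
})

test_that("sum-deviation mode agrees with cell counting where comparable", {
  # at delta0 both modes demand the all-perfect configuration
  set.seed(9)
  tuples <- all_level_tuples(4)
  rows <- sample(nrow(tuples), 100)
  for (k in 1:60) {
    f <- tuples[sample(rows, 1), ]; r <- tuples[sample(rows, 1), ]
    g <- tuples[sample(rows, 1), ]
    expect_equal(evaluate_triple(f, r, g, "delta0", mode = "sum"),
                 evaluate_triple(f, r, g, "delta0", mode = "cells"))
  }
})

test_that("filter_and_sign keeps planted perfect triples with their sign", {
  set.seed(31)
  rows <- list()
  for (i in 1:30) {
    repeat {
      f <- random_variable_pattern(4)
      r <- random_variable_pattern(4)
      sign <- sample(c("+", "-"), 1)
      g <- plant_regulation(f, r, sign)
      if (!is.null(g)) break
    }
    rows[[i]] <- data.frame(
      tf_id = paste0("TF", i), region_id = paste0("R", i),
      gene_id = paste0("G", i), tf_pattern = pattern_string(f),
      region_pattern = pattern_string(r), gene_pattern = pattern_string(g),
      distance = 0L, planted_sign = sign, stringsAsFactors = FALSE)
  }
  triples <- do.call(rbind, rows)
  out <- filter_and_sign(triples[, 1:7], "delta0")
  expect_equal(nrow(out), 30L)
  expect_equal(out$sign[match(triples$tf_id, out$tf_id)],
               triples$planted_sign)

  # random decoys survive rarely
  set.seed(32)
  decoys <- do.call(rbind, lapply(1:300, function(i) data.frame(
    tf_id = paste0("D", i), region_id = paste0("R", i),
    gene_id = paste0("G", i),
    tf_pattern = pattern_string(random_variable_pattern(4)),
    region_pattern = pattern_string(random_variable_pattern(4)),
    gene_pattern = pattern_string(random_variable_pattern(4)),
    distance = 0L, stringsAsFactors = FALSE)))
  surv <- nrow(filter_and_sign(decoys, "delta0")) / nrow(decoys)
  expect_lt(surv, 0.2)

  expect_equal(nrow(filter_and_sign(triples[0, 1:7], "delta1")), 0L)
})

test_that("merge_to_tf_gene aggregates regions and flags conflicts", {
  mk <- function(tf, region, gene, sign)
    data.frame(tf_id = tf, region_id = region, gene_id = gene,
               tf_pattern = "1144", region_pattern = "1144",
               gene_pattern = "1144", distance = 0L, sign = sign,
               stringsAsFactors = FALSE)
  signed <- rbind(mk("TF1", "R1", "G1", "+"), mk("TF1", "R2", "G1", "+"),
                  mk("TF1", "R3", "G1", "+"))
  m <- merge_to_tf_gene(signed)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_regions, 3L)
  expect_equal(m$region_ids, "R1,R2,R3")
  expect_false(m$conflict)

  both <- rbind(mk("TF1", "R1", "G1", "+"), mk("TF1", "R2", "G1", "-"))
  m2 <- merge_to_tf_gene(both)
  expect_equal(nrow(m2), 2L)
  expect_true(all(m2$conflict))

  disjoint <- rbind(mk("TF1", "R1", "G1", "+"), mk("TF2", "R2", "G2", "-"))
  expect_equal(nrow(merge_to_tf_gene(disjoint)), 2L)
})
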