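test_that("the type weight table is the printed 0/1/0.66/0.33", {
  expect_identical(type_weight(1), 0)
  expect_identical(type_weight(2), 1)
  expect_identical(type_weight(3), 0.66)
  expect_identical(type_weight(4), 0.33)
  expect_error(type_weight(0), "1, 2, 3 or 4")
  expect_error(type_weight(5), "1, 2, 3 or 4")
})

test_that("position score reproduces the worked-example arithmetic", {
  s <- position_score(c(0, 7, 0, 1), 8)
  expect_equal(s$mid, 4)
  expect_equal(s$diff, 3)
  expect_equal(s$weight, 1)
  expect_equal(s$score, 1.25)
  s <- position_score(c(0, 4, 0, 4), 8)
  expect_equal(s$diff, 0)
  expect_equal(s$score, 2)
  s <- position_score(c(8, 0, 0, 0), 8)       # invariant site
  expect_equal(s$diff, 4)
  expect_equal(s$score, 0)
  s <- position_score(c(2, 2, 2, 2), 8)       # tetra-allelic balanced
  expect_equal(s$diff, 2)
  expect_equal(s$weight, 0.33)
  expect_equal(s$score, 0.83)
  expect_error(position_score(c(1, 1, 1, 1), 8), "sum")
})

test_that("score stays in [0, 2] and matches the float re-derivation", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(2:40, 1)
    counts <- tabulate(sample(1:4, n, replace = TRUE), nbins = 4)
    s <- position_score(counts, n)
    expect_gte(s$score, 0)
    expect_lte(s$score, 2)
    expect_equal(s$score, oracle_score(counts, n))
    # a perfectly balanced biallelic site attains the maximum
    if (s$score == 2) expect_true(s$diff == 0 && s$n_types == 2)
  }
  expect_equal(position_score(c(3, 3, 0, 0), 6)$score, 2)
})

test_that("odd node sizes give half-integral mid and diff", {
  s <- position_score(c(3, 2, 0, 0), 5)
  expect_equal(s$mid, 2.5)
  expect_equal(s$diff, 0.5)
  expect_equal(s$score, (2.5 - 0.5) / 2.5 + 1)
})

test_that("best_split maximises the score with deterministic tie-breaks", {
  a <- figure3_fixture()
  sp <- best_split(a, 1:8)
  expect_equal(sp$position, 6L)
  expect_equal(sp$pivot, "C")        # C/T both at |mid - f| = 0; A < C wins
  expect_equal(sp$score$score, 2)
  # only one candidate position for a 2-row subset
  b <- aligned_set(c("x", "y"), c("AAGA", "AACA"))
  sp <- best_split(b, 1:2)
  expect_equal(sp$position, 3L)
  expect_equal(sp$pivot, "C")        # alphabetically smaller of C, G
  # two positions with identical maximal scores: smaller index returned
  c2 <- aligned_set(c("x", "y", "z", "w"),
                    c("AAC", "AAC", "TTG", "TTG"))
  sp <- best_split(c2, 1:4)
  expect_equal(sp$position, 1L)
  expect_error(best_split(aligned_set(c("x", "y"), c("AC", "AC")), 1:2),
               "indistinguishable.*x.*y")
})

test_that("greedy split choice equals the brute-force scan on random nodes", {
  for (i in 1:25) {
    a <- draw_panel(i)
    rows <- seq_len(nrow(a$matrix))
    got <- best_split(a, rows)
    want <- oracle_best_split(a, rows)
    expect_equal(got$position, want$position)
    expect_equal(got$pivot, want$pivot)
    expect_equal(got$score$score, want$score)
  }
})

test_that("build_tree separates every species into its own leaf", {
  # two species, one informative site
  a <- aligned_set(c("x", "y"), c("AAGA", "AACA"))
  tr <- build_tree(a)
  expect_equal(tr$kind, "decision")
  expect_setequal(dtsb:::tree_leaves(tr), c("x", "y"))
  expect_equal(dtsb:::tree_decision_count(tr), 1L)
  # worked-example panel: 7 decision nodes, 8 leaves, root at position 6
  tr <- build_tree(figure3_fixture())
  expect_equal(tr$position, 6L)
  expect_equal(tr$level, 1L)
  expect_equal(dtsb:::tree_decision_count(tr), 7L)
  expect_setequal(dtsb:::tree_leaves(tr), paste0("S", 1:8))
  # identical sequences are rejected
  dup <- aligned_set(c("x", "y", "z"), c("ACG", "ACG", "ACT"))
  expect_error(build_tree(dup), "indistinguishable")
})

test_that("every row of a built tree classifies back to its own species", {
  for (i in 1:15) {
    a <- draw_panel(100 + i)
    tr <- build_tree(a)
    n <- nrow(a$matrix)
    expect_equal(dtsb:::tree_decision_count(tr), n - 1L)
    expect_setequal(dtsb:::tree_leaves(tr), a$labels)
    for (r in seq_len(n))
      expect_equal(classify(tr, a$matrix[r, ]), a$labels[r])
  }
})

test_that("classification ignores non-decision positions and flags gaps", {
  a <- figure3_fixture()
  tr <- build_tree(a)
  row <- a$matrix["S3", ]
  row[3] <- "T"                      # position 3 is never a decision site
  expect_equal(classify(tr, row), "S3")
  row <- a$matrix["S1", ]
  row[tr$position] <- "N"
  expect_error(classify(tr, row), "unclassifiable.*position 6")
  expect_error(classify(tr, "ACGT"), "length")
})

test_that("decision levels on any path stay below the panel size", {
  for (i in 1:10) {
    a <- draw_panel(200 + i)
    tr <- build_tree(a)
    max_depth <- function(node) {
      if (node$kind == "leaf") return(node$level - 1L)  # decisions above leaf
      max(max_depth(node$left), max_depth(node$right))
    }
    expect_lte(max_depth(tr), nrow(a$matrix) - 1L)
  }
})

test_that("tree JSON round-trips structure and classification", {
  a <- figure3_fixture()
  tr <- build_tree(a)
  f <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, f)
  tr2 <- read_tree_json(f)
  expect_equal(unclass(tr2), unclass(tr), ignore_attr = TRUE)
  expect_equal(attr(tr2, "alignment_width"), 8L)
  for (r in 1:8)
    expect_equal(classify(tr2, a$matrix[r, ]), a$labels[r])
})

test_that("DOT export names every species and decision site", {
  tr <- build_tree(figure3_fixture())
  dot <- tree_to_dot(tr)
  expect_match(dot, "^digraph")
  for (sp in paste0("S", 1:8)) expect_match(dot, sp)
  expect_match(dot, "p6")
})
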