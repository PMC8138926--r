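markers <- cohort_marker_frame(build_cohort_fixture())
PREDICTORS <- c("h3k27me3", "atrx", "idh1_r132h")

test_that("split score has its closed-form values and guards its inputs", {
  expect_equal(split_score(c(50, 50), c(50, 0), c(0, 50)), 2 * 100 * log(2))
  # children reproducing parent proportions score zero
  expect_equal(split_score(c(40, 60), c(20, 30), c(20, 30)), 0)
  expect_error(split_score(c(10, 10), c(10, 10), c(0, 0)), "nonempty")
  expect_error(split_score(c(10, 10), c(5, 5), c(4, 5)), "equal parent")
})

test_that("leaf probabilities follow the raw and prior-smoothed formulas", {
  expect_equal(leaf_probability(c(10, 0), c(0.5, 0.5), "raw"), c(1, 0))
  expect_equal(leaf_probability(c(10, 0), c(0.5, 0.5), "laplace_prior"),
               c(10.5 / 11, 0.5 / 11))
  expect_equal(sum(leaf_probability(c(3, 7), c(0.31, 0.69))), 1)
  expect_error(leaf_probability(c(0, 0), c(0.5, 0.5)), "empty leaf")
})

test_that("the default tree recovers the published split order", {
  tree <- fit_tree(markers, PREDICTORS, "oligo")
  seq <- tree_split_sequence(tree)
  expect_equal(seq[1:3], c("h3k27me3", "atrx", "idh1_r132h"))
  # the nuclear-loss / ATRX-retained / R132H-positive phenotype predicts
  # oligodendroglioma with high probability
  pred <- predict(tree, c(h3k27me3 = "NL", atrx = "RETAINED",
                          idh1_r132h = "POS"))
  expect_equal(pred$class, "OLIGO")
  expect_gt(pred$probability, 0.9)
})

test_that("the forced R132H-first spine isolates the published 50-case stratum", {
  tree <- fit_tree(markers, PREDICTORS, "oligo",
                   forced_root = c("idh1_r132h", "atrx", "h3k27me3"))
  expect_equal(tree_split_sequence(tree)[1], "idh1_r132h")
  stratum <- tree_node(tree, c("POS", "RETAINED"))
  expect_equal(stratum$n, 50)
  expect_equal(unname(stratum$counts["OLIGO"]), 39)
})

test_that("greedy splits equal the exhaustive best split on random cohorts", {
  withr::local_seed(29)
  for (i in 1:25) {
    d <- random_binary_cohort(n = sample(40:80, 1))
    tree <- fit_tree(d, c("x1", "x2", "x3"), "y", min_leaf = 5)
    oracle <- oracle_best_split(d, c("x1", "x2", "x3"), "y", min_leaf = 5)
    if (is.null(oracle$var)) {
      expect_null(tree$root$split_var)
    } else {
      expect_equal(tree$root$split_var, oracle$var)
      expect_equal(tree$root$g2, oracle$g2, tolerance = 1e-9)
    }
  }
})

test_that("child counts are conserved at every node", {
  check_node <- function(node) {
    if (is.null(node$split_var)) return(invisible())
    kids <- node$children
    expect_equal(kids[[1]]$counts + kids[[2]]$counts, node$counts)
    expect_equal(kids[[1]]$n + kids[[2]]$n, node$n)
    lapply(kids, check_node)
    invisible()
  }
  check_node(fit_tree(markers, PREDICTORS, "oligo")$root)
})

test_that("degenerate cohorts and profiles are handled explicitly", {
  const <- data.frame(x1 = factor(rep(c("A", "B"), 10)),
                      y = factor(rep("CASE", 20), levels = c("CASE", "CTRL")))
  tree <- fit_tree(const, "x1", "y")
  expect_null(tree$root$split_var)  # constant response: single leaf
  pred <- predict(tree, c(x1 = "A"))
  expect_equal(pred$class, "CASE")

  expect_error(fit_tree(markers[0, ], PREDICTORS, "oligo"), "empty")
  tri <- data.frame(x = factor(c("A", "B", "C")), y = factor(c("u", "v", "u")))
  expect_error(fit_tree(tri, "x", "y"), "not binary")

  full_tree <- fit_tree(markers, PREDICTORS, "oligo")
  expect_error(predict(full_tree, c(atrx = "RETAINED", idh1_r132h = "POS")),
               "missing tested variable")
  expect_error(predict(full_tree, c(h3k27me3 = "MAYBE")), "unknown level")
})

test_that("prediction is total and deterministic over all 8 marker profiles", {
  tree <- fit_tree(markers, PREDICTORS, "oligo")
  grid <- expand.grid(h3k27me3 = c("NL", "NR"), atrx = c("RETAINED", "LOST"),
                      idh1_r132h = c("POS", "NEG"), stringsAsFactors = FALSE)
  preds <- apply(grid, 1, function(row) predict(tree, as.list(row)))
  for (p in preds) {
    expect_true(p$class %in% c("OLIGO", "OTHER"))
    expect_true(p$probability > 0.5 && p$probability <= 1)
  }
  # the two published phenotype -> prediction examples
  expect_equal(predict(tree, c(h3k27me3 = "NL", atrx = "RETAINED",
                               idh1_r132h = "POS"))$class, "OLIGO")
  expect_equal(predict(tree, c(h3k27me3 = "NR", atrx = "LOST",
                               idh1_r132h = "POS"))$class, "OTHER")
})

test_that("trees serialize to JSON with counts and probabilities", {
  tree <- fit_tree(markers, PREDICTORS, "oligo")
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$root$split_var, "h3k27me3")
  expect_equal(parsed$root$n, 145)
  expect_equal(parsed$root$counts$OLIGO, 45)
})
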