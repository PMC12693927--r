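test_that("Gini impurity matches the closed form", {
  expect_equal(gini(c(10, 0)), 0)
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(2, 1, 1)), 0.625)
  expect_error(gini(c(0, 0)), "zero")
})

test_that("degenerate inputs yield degenerate trees", {
  x <- data.frame(a = 1:30)
  y <- factor(rep("z", 30))
  fit <- grow_tree(x, y)
  expect_true(fit$root$leaf)
  expect_equal(as.character(predict(fit, x))[1], "z")

  sep <- data.frame(x = c(seq(-1, -0.1, length.out = 10),
                          seq(0.1, 1, length.out = 10)))
  lab <- factor(rep(c("A", "B"), each = 10))
  fit2 <- grow_tree(sep, lab, min_split = 2, min_leaf = 1)
  expect_false(fit2$root$leaf)
  expect_true(fit2$root$left$leaf && fit2$root$right$leaf)
  expect_equal(mean(predict(fit2, sep) == lab), 1)
})

test_that("the grown root split equals the exhaustive-search optimum", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(10:40, 1)
    p <- sample(1:3, 1)
    x <- as.data.frame(matrix(round(runif(n * p, 0, 10), 1), ncol = p))
    y <- factor(sample(letters[1:sample(2:3, 1)], n, replace = TRUE))
    if (length(unique(y)) < 2) next
    fit <- grow_tree(x, y, min_split = 2, min_leaf = 1, max_depth = 1)
    oracle <- brute_force_root_split(x, y, min_leaf = 1)
    if (is.null(oracle)) next
    if (fit$root$leaf) {
      # no impurity-reducing split existed; the oracle score must not beat
      # the parent node either
      expect_gte(oracle$score, fit$root$impurity - 1e-12)
    } else {
      expect_equal(fit$root$feature, oracle$feature)
      expect_equal(fit$root$threshold, oracle$threshold)
    }
  }
})

test_that("predictions agree with an established CART implementation", {
  skip_if_not_installed("rpart")
  set.seed(99)
  for (rep in 1:5) {
    n <- 250
    x <- data.frame(a = runif(n), b = runif(n), c = rnorm(n))
    y <- factor(ifelse(x$a > runif(1, 0.3, 0.7) & x$b < 0.6, "p",
                       ifelse(x$c > 0.3, "q", "r")))
    fit <- grow_tree(x, y, min_split = 20, min_leaf = 7)
    rp <- rpart::rpart(y ~ ., data = cbind(x, y = y),
                       control = rpart::rpart.control(minsplit = 20, minbucket = 7,
                                                      cp = 0, xval = 0, maxdepth = 30))
    agree <- mean(as.character(predict(fit, x)) ==
                    as.character(predict(rp, x, type = "class")))
    expect_gte(agree, 0.9)
  }
})

test_that("the pruning path is nested with increasing alpha", {
  set.seed(31)
  collect_splits <- function(node, acc = character()) {
    if (node$leaf) return(acc)
    acc <- c(acc, paste(node$feature, signif(node$threshold, 12)))
    acc <- collect_splits(node$left, acc)
    collect_splits(node$right, acc)
  }
  for (rep in 1:5) {
    n <- 150
    x <- data.frame(a = runif(n), b = runif(n))
    y <- factor(sample(c("u", "v", "w"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)))
    fit <- grow_tree(x, y, min_split = 10, min_leaf = 3)
    path <- prune_path(fit)
    expect_true(all(diff(path$table$alpha) > 0))
    expect_true(all(diff(path$table$n_leaves) < 0))
    expect_equal(path$table$n_leaves[length(path$trees)], 1)
    splits <- lapply(path$trees, function(tr) collect_splits(tr$root))
    for (i in seq_along(splits)[-1]) {
      expect_true(all(splits[[i]] %in% splits[[i - 1]]))
    }
  }
})

test_that("single-leaf trees and separable stumps prune as expected", {
  leafy <- grow_tree(data.frame(a = 1:30), factor(rep("z", 30)))
  path <- prune_path(leafy)
  expect_equal(nrow(path$table), 1)

  sep <- data.frame(x = c(seq(-1, -0.1, length.out = 15),
                          seq(0.1, 1, length.out = 15)))
  lab <- factor(rep(c("A", "B"), each = 15))
  stump <- grow_tree(sep, lab, min_split = 2, min_leaf = 1)
  p2 <- prune_path(stump)
  # the stump removes the whole root error: its weakest-link alpha equals
  # the per-leaf error reduction R(root) - 0 = 0.5
  expect_equal(p2$table$alpha, c(0, 0.5))
  expect_equal(p2$table$cp, c(0, 1))
  expect_true(p2$trees[[2]]$root$leaf)
})

test_that("the rolling-origin plan expands from an initial window", {
  plan <- rolling_origin_plan(100, k = 5)
  expect_equal(plan$train_end, c(50, 60, 70, 80, 90))
  expect_equal(plan$val_start, c(51, 61, 71, 81, 91))
  expect_equal(plan$val_end, c(60, 70, 80, 90, 100))
  expect_error(rolling_origin_plan(6, k = 5), "too few")
})

test_that("a root-only cp reduces CV error to the majority-class error", {
  set.seed(5)
  n <- 120
  x <- data.frame(a = runif(n))
  y <- factor(c(rep("maj", 90), rep("min", 30))[sample(n)])
  cv <- rolling_origin_cv(x, y, k = 4, cp_grid = c(0, 10),
                          min_split = 10, min_leaf = 3)
  plan <- attr(cv, "plan")
  expected <- sapply(seq_len(nrow(plan)), function(f) {
    tr <- y[seq_len(plan$train_end[f])]
    maj <- names(which.max(table(tr)))
    va <- y[plan$val_start[f]:plan$val_end[f]]
    mean(va != maj)
  })
  expect_equal(cv$mean_error[cv$cp == 10], mean(expected))
})

test_that("unsorted timestamps trigger the ordering warning", {
  set.seed(6)
  x <- data.frame(a = runif(40))
  y <- factor(sample(c("A", "B"), 40, replace = TRUE))
  expect_warning(
    rolling_origin_cv(x, y, k = 2, timestamps = sample(1:40),
                      min_split = 5, min_leaf = 2),
    "time order")
})

test_that("1-SE selection picks the simplest model within one SE of the best", {
  cv <- data.frame(cp = c(0.01, 0.05, 0.2),
                   mean_error = c(0.10, 0.11, 0.20),
                   se_error = c(0.02, 0.02, 0.02))
  expect_equal(one_se_select(cv), 0.05)
  flat <- data.frame(cp = c(0.01, 0.1, 0.5), mean_error = 0.2, se_error = 0.01)
  expect_equal(one_se_select(flat), 0.5)
  single <- data.frame(cp = 0.3, mean_error = 0.1, se_error = 0.05)
  expect_equal(one_se_select(single), 0.3)
})

test_that("the temporal holdout keeps the last rows untouched", {
  rows <- data.frame(t = 1:10, y = rnorm(10))
  split <- temporal_holdout(rows)
  expect_equal(nrow(split$train), 7)
  expect_equal(nrow(split$test), 3)
  expect_true(min(split$test$t) > max(split$train$t))
  split100 <- temporal_holdout(data.frame(t = 1:100))
  expect_equal(nrow(split100$test), 30)
  expect_error(temporal_holdout(data.frame(t = 1:3)), "at least 4")
})

test_that("evaluation metrics match hand arithmetic", {
  classes <- c("neg", "pos")
  truth <- c(rep("neg", 60), rep("pos", 40))
  pred <- c(rep("neg", 45), rep("pos", 15), rep("neg", 25), rep("pos", 15))
  ev <- evaluate_classification(truth, pred, classes)
  expect_equal(as.numeric(ev$confusion), c(45, 25, 15, 15))
  expect_equal(ev$accuracy, 0.60)
  expect_equal(ev$kappa, (0.60 - 0.54) / (1 - 0.54), tolerance = 1e-12)
  expect_equal(ev$balanced_accuracy, mean(c(45 / 60, 15 / 40)))
  f1_neg <- 2 * 45 / (2 * 45 + 25 + 15)
  f1_pos <- 2 * 15 / (2 * 15 + 15 + 25)
  expect_equal(ev$macro_f1, mean(c(f1_neg, f1_pos)))

  perfect <- evaluate_classification(truth, truth, classes)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  expect_warning(deg <- evaluate_classification(rep("pos", 5), rep("pos", 5), classes),
                 "undefined")
  expect_true(is.na(deg$kappa))
  expect_error(evaluate_classification(c("pos"), c("pos", "neg"), classes),
               "length")
})

test_that("the full pipeline recovers a planted 2-rule daily-status structure", {
  d <- planted_daily(n = 400, seed = 11)
  fit <- fit_microclimate_tree(d)
  expect_gte(fit$report$balanced_accuracy, 0.9)
  expect_s3_class(fit$tree, "microclim_tree")
  # the selected tree must rely on the planted drivers
  feats_used <- local({
    used <- character()
    walk <- function(nd) {
      if (nd$leaf) return(invisible())
      used <<- c(used, fit$tree$features[nd$feature])
      walk(nd$left); walk(nd$right)
    }
    walk(fit$tree$root)
    unique(used)
  })
  expect_true(all(feats_used %in% c("pct_critical_RH", "pct_critical_VPD")))
})
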