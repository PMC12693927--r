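#' Gini impurity of a count vector
#'
#' `1 - sum(p^2)` over class proportions.
#'
#' @param class_counts nonnegative numeric vector with at least one
#'   positive entry.
#' @return impurity in `[0, 1)`.
#' @examples
#' gini(c(5, 5))     # 0.5
#' gini(c(2, 1, 1))  # 0.625
#' @export
gini <- function(class_counts) {
  stopifnot(is.numeric(class_counts), all(class_counts >= 0))
  n <- sum(class_counts)
  if (n == 0) stop("gini(): all counts are zero", call. = FALSE)
  1 - sum((class_counts / n)^2)
}

# Best binary split for one node, vectorised per feature via cumulative
# statistics over the sorted feature. Candidate thresholds are midpoints
# between consecutive distinct values. Ties break to the lowest feature
# index, then the lowest threshold. Returns NULL when no admissible split
# improves impurity.
best_split <- function(x, y, min_leaf, type, feature_idx) {
  n <- length(y)
  best <- NULL
  for (j in feature_idx) {
    xj <- x[, j]
    ord <- order(xj, method = "radix")
    xs <- xj[ord]
    lo <- min_leaf; hi <- n - min_leaf
    if (hi < lo) next
    valid <- seq_len(n - 1L) >= lo & seq_len(n - 1L) <= hi &
      xs[-n] < xs[-1L]
    if (!any(valid)) next
    if (type == "classification") {
      ys <- y[ord]
      K <- max(y)
      cum <- matrix(0, nrow = n, ncol = K)
      for (k in seq_len(K)) cum[, k] <- cumsum(ys == k)
      i <- seq_len(n - 1L)
      nl <- i; nr <- n - i
      left <- cum[i, , drop = FALSE]
      right <- matrix(cum[n, ], nrow = n - 1L, ncol = K, byrow = TRUE) - left
      gl <- 1 - rowSums((left / nl)^2)
      gr <- 1 - rowSums((right / nr)^2)
      score <- (nl * gl + nr * gr) / n   # weighted child Gini; lower is better
    } else {
      ys <- y[ord]
      cs <- cumsum(ys); cs2 <- cumsum(ys^2)
      i <- seq_len(n - 1L)
      nl <- i; nr <- n - i
      sse_l <- cs2[i] - cs[i]^2 / nl
      sse_r <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / nr
      score <- sse_l + sse_r               # total child SSE; lower is better
    }
    score[!valid] <- Inf
    b <- which.min(score)
    if (is.finite(score[b]) &&
        (is.null(best) || score[b] < best$score - 1e-12)) {
      best <- list(feature = j, threshold = (xs[b] + xs[b + 1L]) / 2,
                   score = score[b])
    }
  }
  best
}

node_impurity <- function(y, type, K) {
  if (type == "classification") {
    counts <- tabulate(y, nbins = K)
    list(impurity = gini(counts), counts = counts,
         pred = which.max(counts))           # first max: first level wins ties
  } else {
    list(impurity = sum((y - mean(y))^2), counts = NULL, pred = mean(y))
  }
}

#' Grow a binary decision tree
#'
#' CART-style greedy growth: at each node the split minimising the
#' size-weighted child Gini impurity (classification) or total child sum of
#' squared errors (regression) is chosen among midpoints of consecutive
#' distinct feature values. Tie-breaks are deterministic (lowest feature
#' index, then lowest threshold); leaves predict the majority class (first
#' declared level on ties) or the node mean. Rows go left when
#' `feature <= threshold`.
#'
#' @param x numeric matrix or data frame of features (no missing values).
#' @param y response: factor/character (classification) or numeric
#'   (regression).
#' @param type `"classification"` or `"regression"`; inferred from `y` by
#'   default.
#' @param min_split minimum node size eligible for splitting.
#' @param min_leaf minimum rows in a child.
#' @param max_depth maximum depth (root = 0).
#' @param mtry if non-`NULL`, number of features sampled (without
#'   replacement) as split candidates at every node — used by the bagged
#'   ensembles of [impute_series()].
#' @param class_levels class order for classification (defaults to factor
#'   levels / sorted unique values); fixes prediction tie-breaks and the
#'   confusion-matrix layout downstream.
#' @return object of class `microclim_tree`.
#' @seealso [prune_path()], [predict.microclim_tree()]
#' @export
grow_tree <- function(x, y, type = NULL, min_split = 20L, min_leaf = 7L,
                      max_depth = 30L, mtry = NULL, class_levels = NULL) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("grow_tree(): missing feature values; impute upstream", call. = FALSE)
  if (is.null(type))
    type <- if (is.numeric(y)) "regression" else "classification"
  type <- match.arg(type, c("classification", "regression"))
  if (type == "classification") {
    if (is.null(class_levels))
      class_levels <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
    yi <- match(as.character(y), class_levels)
    if (anyNA(yi)) stop("grow_tree(): labels outside class_levels", call. = FALSE)
  } else {
    yi <- as.numeric(y)
    class_levels <- NULL
  }
  K <- length(class_levels)
  p <- ncol(x)
  n_try <- if (is.null(mtry)) p else max(1L, min(p, as.integer(mtry)))

  build <- function(idx, depth) {
    info <- node_impurity(yi[idx], type, K)
    node <- list(n = length(idx), pred = info$pred, counts = info$counts,
                 impurity = info$impurity, leaf = TRUE)
    if (length(idx) >= min_split && depth < max_depth && info$impurity > 1e-12) {
      feats <- if (n_try < p) sort(sample.int(p, n_try)) else seq_len(p)
      sp <- best_split(x[idx, , drop = FALSE], yi[idx], min_leaf, type, feats)
      if (!is.null(sp)) {
        go_left <- x[idx, sp$feature] <= sp$threshold
        node$leaf <- FALSE
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$left <- build(idx[go_left], depth + 1L)
        node$right <- build(idx[!go_left], depth + 1L)
      }
    }
    node
  }
  root <- build(seq_along(yi), 0L)
  structure(list(root = root, type = type, class_levels = class_levels,
                 features = colnames(x), n = length(yi)),
            class = "microclim_tree")
}

#' Predict from a grown tree
#'
#' @param object a `microclim_tree`.
#' @param newdata matrix/data frame with the training feature columns.
#' @param type `"class"` (factor; classification), `"prob"` (class share
#'   matrix) or `"response"` (numeric; regression). Default matches the
#'   tree type.
#' @param ... unused.
#' @return predictions, one per row of `newdata`.
#' @export
predict.microclim_tree <- function(object, newdata, type = NULL, ...) {
  newdata <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(newdata) <- "double"
  if (is.null(type))
    type <- if (object$type == "classification") "class" else "response"
  n <- nrow(newdata)
  K <- length(object$class_levels)
  out_num <- numeric(n)
  out_prob <- if (type == "prob") matrix(NA_real_, n, K,
                                         dimnames = list(NULL, object$class_levels))
  walk <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) {
      out_num[idx] <<- node$pred
      if (type == "prob") out_prob[idx, ] <<- rep(node$counts / node$n, each = length(idx))
      return(invisible())
    }
    go_left <- newdata[idx, node$feature] <= node$threshold
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(object$root, seq_len(n))
  switch(type,
         class = factor(object$class_levels[out_num], levels = object$class_levels),
         prob = out_prob,
         response = out_num)
}

#' @export
print.microclim_tree <- function(x, ...) {
  count_leaves <- function(nd) if (nd$leaf) 1L else
    count_leaves(nd$left) + count_leaves(nd$right)
  cat(sprintf("%s tree: n = %d, %d leaves\n",
              x$type, x$n, count_leaves(x$root)))
  invisible(x)
}

# resubstitution risk of a node taken as a leaf, in misclassification counts
leaf_risk <- function(node) node$n - max(node$counts)

#' Cost-complexity pruning path
#'
#' Weakest-link pruning of a classification tree: repeatedly collapses the
#' internal node(s) with the smallest per-leaf error increase
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)` until only the root
#' remains. Risks are resubstitution misclassification rates; the reported
#' `cp` column normalises alpha by the root-as-leaf risk (relative-error
#' convention, root error = 1), making the grid scale-free.
#'
#' @param tree a classification `microclim_tree`.
#' @return object of class `prune_path`: list with `table` (data frame
#'   `alpha`, `cp`, `n_leaves`, strictly increasing alpha, non-increasing
#'   sizes) and `trees` (the nested subtree sequence).
#' @export
prune_path <- function(tree) {
  stopifnot(inherits(tree, "microclim_tree"), tree$type == "classification")
  n <- tree$n
  r_root <- leaf_risk(tree$root) / n

  subtree_stats <- function(node) {      # (risk of subtree, leaf count)
    if (node$leaf) return(c(leaf_risk(node) / n, 1))
    l <- subtree_stats(node$left); r <- subtree_stats(node$right)
    c(l[1] + r[1], l[2] + r[2])
  }
  min_g <- function(node) {
    if (node$leaf) return(Inf)
    st <- subtree_stats(node)
    g_here <- (leaf_risk(node) / n - st[1]) / (st[2] - 1)
    min(g_here, min_g(node$left), min_g(node$right))
  }
  collapse_at <- function(node, g_target) {
    if (node$leaf) return(node)
    st <- subtree_stats(node)
    g_here <- (leaf_risk(node) / n - st[1]) / (st[2] - 1)
    if (g_here <= g_target + 1e-12) {
      node$leaf <- TRUE
      node$left <- node$right <- node$feature <- node$threshold <- NULL
      return(node)
    }
    node$left <- collapse_at(node$left, g_target)
    node$right <- collapse_at(node$right, g_target)
    node
  }

  trees <- list(tree)
  alphas <- 0
  current <- tree
  while (!current$root$leaf) {
    g <- min_g(current$root)
    current$root <- collapse_at(current$root, g)
    trees[[length(trees) + 1L]] <- current
    alphas <- c(alphas, g)
  }
  # merge steps with equal alpha (simultaneous weakest links)
  keep <- !duplicated(alphas, fromLast = TRUE)
  trees <- trees[keep]; alphas <- alphas[keep]
  leaves <- vapply(trees, function(tr) subtree_stats(tr$root)[2], numeric(1))
  cp <- if (r_root > 0) alphas / r_root else alphas
  structure(list(table = data.frame(alpha = alphas, cp = cp, n_leaves = leaves),
                 trees = trees, r_root = r_root),
            class = "prune_path")
}

#' Extract the subtree of a pruning path for a given complexity penalty
#'
#' @param path a [prune_path()].
#' @param cp complexity parameter (relative-error scale).
#' @return the `microclim_tree` optimal at penalty `cp` (the last path
#'   element whose cp does not exceed it).
#' @export
prune_at <- function(path, cp) {
  stopifnot(inherits(path, "prune_path"))
  idx <- max(which(path$table$cp <= cp + 1e-12))
  path$trees[[idx]]
}

#' Expanding-window (rolling-origin) cross-validation plan
#'
#' Training always starts at the first row; validation blocks are the `k`
#' contiguous, near-equal segments that partition the rows after an initial
#' window of `initial_frac * n`.
#'
#' @param n number of time-ordered rows.
#' @param k number of folds.
#' @param initial_frac fraction of rows in the first training window.
#' @return data frame `fold`, `train_end`, `val_start`, `val_end`.
#' @examples
#' rolling_origin_plan(100, k = 5)  # train ends 50, 60, 70, 80, 90
#' @export
rolling_origin_plan <- function(n, k = 5L, initial_frac = 0.5) {
  n0 <- floor(initial_frac * n)
  if (n - n0 < k)
    stop("rolling_origin_plan(): too few rows for the requested folds", call. = FALSE)
  bounds <- n0 + round((n - n0) * seq(0, 1, length.out = k + 1L))
  data.frame(fold = seq_len(k),
             train_end = bounds[-(k + 1L)],
             val_start = bounds[-(k + 1L)] + 1L,
             val_end = bounds[-1L])
}

#' Rolling-origin cross-validated error over a cp grid
#'
#' For each expanding-window fold, grows a tree on the training window,
#' prunes it at every cp in the grid and scores misclassification on the
#' next contiguous validation block. The grid defaults to the cp values of
#' the pruning path of a tree grown on all supplied rows.
#'
#' @param x features (time-ordered rows).
#' @param y labels.
#' @param k number of folds.
#' @param initial_frac initial training window fraction.
#' @param cp_grid numeric vector of cp values (optional).
#' @param timestamps optional vector used to verify the rows are
#'   time-sorted; non-monotone timestamps raise a warning.
#' @param ... growth controls passed to [grow_tree()].
#' @return object of class `rolling_cv`: data frame `cp`, `mean_error`,
#'   `se_error` plus the plan as attribute `"plan"`.
#' @export
rolling_origin_cv <- function(x, y, k = 5L, initial_frac = 0.5,
                              cp_grid = NULL, timestamps = NULL, ...) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (!is.null(timestamps) && is.unsorted(timestamps, strictly = FALSE))
    warning("rolling_origin_cv(): rows are not in time order; expanding-window CV assumes a sorted series")
  plan <- rolling_origin_plan(n, k, initial_frac)
  if (is.null(cp_grid)) {
    full <- grow_tree(x, y, ...)
    cp_grid <- prune_path(full)$table$cp
  }
  cp_grid <- sort(unique(cp_grid))
  errs <- matrix(NA_real_, nrow = length(cp_grid), ncol = k)
  for (f in seq_len(k)) {
    tr <- seq_len(plan$train_end[f])
    va <- plan$val_start[f]:plan$val_end[f]
    fit <- grow_tree(x[tr, , drop = FALSE], y[tr], ...)
    path <- prune_path(fit)
    for (ci in seq_along(cp_grid)) {
      pred <- predict(prune_at(path, cp_grid[ci]), x[va, , drop = FALSE])
      errs[ci, f] <- mean(as.character(pred) != as.character(y[va]))
    }
  }
  out <- data.frame(cp = cp_grid,
                    mean_error = rowMeans(errs),
                    se_error = apply(errs, 1, stats::sd) / sqrt(k))
  attr(out, "plan") <- plan
  class(out) <- c("rolling_cv", "data.frame")
  out
}

#' 1-SE model selection
#'
#' The largest cp (simplest tree) whose mean cross-validated error does not
#' exceed the minimum mean error plus the standard error at that minimum.
#'
#' @param cv a [rolling_origin_cv()] result, or any data frame with `cp`,
#'   `mean_error`, `se_error`.
#' @return the selected cp (scalar).
#' @export
one_se_select <- function(cv) {
  stopifnot(all(c("cp", "mean_error", "se_error") %in% names(cv)), nrow(cv) >= 1L)
  i_min <- which.min(cv$mean_error)
  thr <- cv$mean_error[i_min] + cv$se_error[i_min]
  max(cv$cp[cv$mean_error <= thr + 1e-12])
}

#' Temporal holdout split
#'
#' The last `ceiling(fraction * n)` time-ordered rows form the test set; no
#' shuffling.
#'
#' @param rows data frame of time-ordered rows.
#' @param fraction test fraction (default 0.30).
#' @return list with `train` and `test` data frames.
#' @export
temporal_holdout <- function(rows, fraction = 0.30) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  if (n < 4L) stop("temporal_holdout(): need at least 4 rows", call. = FALSE)
  n_test <- ceiling(fraction * n)
  list(train = rows[seq_len(n - n_test), , drop = FALSE],
       test = rows[(n - n_test + 1L):n, , drop = FALSE])
}

#' Classification evaluation report
#'
#' Confusion matrix (rows = truth, columns = prediction) with overall
#' accuracy, balanced accuracy (mean per-class recall over classes present
#' in the truth), macro F1 (unweighted mean of per-class F1 over classes
#' present in the truth; a class with no predictions and no true positives
#' contributes 0) and Cohen's kappa (`NA` with a warning when the expected
#' agreement is 1).
#'
#' @param truth,predictions equal-length label vectors.
#' @param class_order label order for the matrix (default
#'   [category_levels()]).
#' @return object of class `eval_report`.
#' @export
evaluate_classification <- function(truth, predictions,
                                    class_order = category_levels()) {
  truth <- as.character(truth); predictions <- as.character(predictions)
  if (length(truth) != length(predictions))
    stop("evaluate_classification(): length mismatch", call. = FALSE)
  if (!all(c(truth, predictions) %in% class_order))
    stop("evaluate_classification(): labels outside class_order", call. = FALSE)
  tf <- factor(truth, levels = class_order)
  pf <- factor(predictions, levels = class_order)
  cm <- table(truth = tf, prediction = pf)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  present <- rowSums(cm) > 0
  recall <- diag(cm)[present] / rowSums(cm)[present]
  bal_acc <- mean(recall)
  f1 <- vapply(which(present), function(k) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  macro_f1 <- mean(f1)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    warning("evaluate_classification(): expected agreement is 1; kappa undefined")
    NA_real_
  } else (acc - pe) / (1 - pe)
  structure(list(confusion = cm, accuracy = acc, balanced_accuracy = bal_acc,
                 macro_f1 = macro_f1, kappa = kappa, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("accuracy %.3f | balanced accuracy %.3f | macro F1 %.3f | kappa %s\n",
              x$accuracy, x$balanced_accuracy, x$macro_f1,
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa))))
  invisible(x)
}

#' Fit and validate a daily microclimate status tree
#'
#' End-to-end modelling of the daily status: a temporal holdout reserves
#' the last `holdout_fraction` of days; on the training window a tree on
#' the nine daily category-percentage predictors is grown, its complexity
#' tuned by rolling-origin cross-validation with the 1-SE rule, pruned at
#' the selected cp, and finally scored on the untouched holdout.
#'
#' @param daily a [daily_status_table()] (or any time-ordered data frame
#'   with the predictor columns and a `status` column).
#' @param holdout_fraction temporal holdout share (default 0.30).
#' @param k,initial_frac cross-validation plan parameters.
#' @param min_split,min_leaf,max_depth growth controls.
#' @param seed optional seed (growth is deterministic; the seed only
#'   matters if `mtry` subsampling were used).
#' @return object of class `microclimate_tree_fit`: list with `tree`
#'   (pruned), `full_tree`, `cv`, `cp_selected`, `report` (holdout
#'   [evaluate_classification()]), `holdout` and `features`.
#' @export
fit_microclimate_tree <- function(daily, holdout_fraction = 0.30, k = 5L,
                                  initial_frac = 0.5, min_split = 20L,
                                  min_leaf = 7L, max_depth = 30L, seed = NULL) {
  stopifnot(is.data.frame(daily), "status" %in% names(daily))
  features <- grep("^pct_", names(daily), value = TRUE)
  if (length(features) == 0L)
    stop("fit_microclimate_tree(): no pct_* predictor columns", call. = FALSE)
  run <- function() {
    split <- temporal_holdout(daily, holdout_fraction)
    y_tr <- factor(as.character(split$train$status), levels = category_levels())
    full <- grow_tree(split$train[features], y_tr,
                      min_split = min_split, min_leaf = min_leaf,
                      max_depth = max_depth, class_levels = category_levels())
    cv <- rolling_origin_cv(split$train[features], y_tr, k = k,
                            initial_frac = initial_frac,
                            min_split = min_split, min_leaf = min_leaf,
                            max_depth = max_depth, class_levels = category_levels())
    cp_sel <- one_se_select(cv)
    pruned <- prune_at(prune_path(full), cp_sel)
    pred <- predict(pruned, split$test[features])
    report <- evaluate_classification(split$test$status, pred)
    structure(list(tree = pruned, full_tree = full, cv = cv,
                   cp_selected = cp_sel, report = report,
                   holdout = split, features = features),
              class = "microclimate_tree_fit")
  }
  if (is.null(seed)) run() else with_seed(as.integer(seed), run())
}

#' @export
print.microclimate_tree_fit <- function(x, ...) {
  cat("Daily microclimate status tree (1-SE cp =",
      signif(x$cp_selected, 3), ")\n")
  print(x$tree)
  cat("Holdout performance:\n")
  print(x$report)
  invisible(x)
}

# plain nested-list rendering of a tree for JSON reports
tree_to_list <- function(tree) {
  strip <- function(node) {
    if (node$leaf) {
      list(leaf = TRUE, n = node$n,
           predict = if (!is.null(tree$class_levels))
             tree$class_levels[node$pred] else node$pred,
           counts = node$counts)
    } else {
      list(leaf = FALSE, n = node$n,
           split = list(feature = tree$features[node$feature],
                        threshold = node$threshold),
           left = strip(node$left), right = strip(node$right))
    }
  }
  strip(tree$root)
}
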