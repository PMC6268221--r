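#' Gini impurity of a class-count vector
#'
#' `1 - sum(p_k^2)` with `p_k` the class proportions; 0 for a pure node and
#' approaching `1 - 1/k` for a uniform k-class node.
#'
#' @param class_counts Non-negative counts with positive sum.
#' @return A number in `[0, 1)`.
#' @examples
#' gini_impurity(c(3, 3))   # 0.5
#' @export
gini_impurity <- function(class_counts) {
  class_counts <- as.numeric(class_counts)
  if (any(class_counts < 0) || sum(class_counts) <= 0) {
    abort("class counts must be non-negative with positive sum",
          class = "glyco_validation_error")
  }
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

#' Best single-descriptor binary split
#'
#' Scans the candidate descriptors and, for each, the midpoints of
#' consecutive sorted distinct values, and returns the split maximizing the
#' weighted decrease in Gini impurity. Objects with descriptor value strictly
#' below the threshold go left. Ties are resolved in favour of the lowest
#' descriptor index, then the lowest threshold.
#'
#' @param X Numeric matrix (n x p) of descriptors.
#' @param y Class labels (length n, at least two distinct).
#' @param candidates Descriptor (column) indices to scan; default all.
#' @return A list with `descriptor`, `threshold` and `decrease`, or `NULL`
#'   when no descriptor admits a split (all candidates constant).
#' @export
best_split <- function(X, y, candidates = seq_len(ncol(X))) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  if (n < 2 || length(unique(y)) < 2) {
    abort("best_split needs >= 2 objects from >= 2 classes",
          class = "glyco_validation_error")
  }
  classes <- sort(unique(y))
  parent <- gini_impurity(table(factor(y, classes)))
  best <- NULL
  for (j in sort(candidates)) {
    v <- X[, j]
    uq <- sort(unique(v))
    if (length(uq) < 2) next
    thresholds <- (uq[-1] + uq[-length(uq)]) / 2
    for (t in thresholds) {
      left <- v < t
      nl <- sum(left)
      gl <- gini_impurity(table(factor(y[left], classes)))
      gr <- gini_impurity(table(factor(y[!left], classes)))
      dec <- parent - (nl / n) * gl - ((n - nl) / n) * gr
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(descriptor = j, threshold = t, decrease = dec)
      }
    }
  }
  best
}

#' Train a pruned CART classification tree for one task
#'
#' Grows a binary tree by recursive Gini splitting and prunes it by
#' cost-complexity with an internal seeded cross-validation, selecting the
#' nested subtree with minimal cross-validated misclassification (no 1-SE
#' rule). The growing and pruning engine is the rpart implementation of
#' CART; the defaults (`min_split = 20`, `complexity = 0.01`,
#' `cv_folds = 10`) are its canonical defaults.
#'
#' @param x A `glyco_records` tibble or n x 23 descriptor matrix.
#' @param task Task name (one of [task_names()]); required when `x` is a
#'   records tibble and `y` is missing.
#' @param y Class labels; default taken from `x[[task]]`.
#' @param min_split Minimum node size eligible for splitting.
#' @param complexity Complexity parameter for growing.
#' @param cv_folds Internal cross-validation folds for pruning.
#' @param seed Integer seed (the internal CV is randomized).
#' @return An object of class `glyco_cart` wrapping the pruned rpart fit.
#' @examples
#' recs <- generate_dataset(30, 30, seed = 1)
#' fit <- train_cart(recs, task = "ano_r", seed = 1)
#' predict(fit, recs[1:3, ])
#' @export
train_cart <- function(x, task = NULL, y = NULL, min_split = 20,
                       complexity = 0.01, cv_folds = 10, seed = 1) {
  X <- as_descriptor_matrix(x)
  if (is.null(y)) {
    if (is.null(task) || !is.data.frame(x)) {
      abort("supply y, or a records tibble plus a task name",
            class = "glyco_validation_error")
    }
    y <- x[[task]]
  }
  y <- factor(y)
  df <- data.frame(y = y, X)
  if (nlevels(droplevels(y)) < 2) {
    fit <- NULL  # single-class: root leaf
  } else {
    fit <- withr::with_seed(as.integer(seed), {
      tree <- rpart::rpart(
        y ~ ., data = df, method = "class",
        control = rpart::rpart.control(minsplit = min_split, cp = complexity,
                                       xval = cv_folds)
      )
      cp_tab <- tree$cptable
      best <- cp_tab[which.min(cp_tab[, "xerror"]), "CP"]
      rpart::prune(tree, cp = best)
    })
  }
  structure(
    list(fit = fit, task = task, levels = levels(y),
         majority = names(sort(table(y), decreasing = TRUE))[1],
         min_split = min_split, complexity = complexity,
         cv_folds = cv_folds, seed = seed),
    class = "glyco_cart"
  )
}

#' @export
predict.glyco_cart <- function(object, newdata, ...) {
  X <- as_descriptor_matrix(newdata)
  if (is.null(object$fit)) {
    return(rep(object$majority, nrow(X)))
  }
  as.character(predict(object$fit, data.frame(X), type = "class"))
}

#' @export
print.glyco_cart <- function(x, ...) {
  cat("<glyco_cart>", if (is.null(x$task)) "" else x$task, "\n")
  cat(cart_rules(x), sep = "\n")
  invisible(x)
}

#' @export
glance.glyco_cart <- function(x, ...) {
  fr <- if (is.null(x$fit)) NULL else x$fit$frame
  tibble(
    n_nodes = if (is.null(fr)) 1L else nrow(fr),
    n_leaves = if (is.null(fr)) 1L else sum(fr$var == "<leaf>"),
    depth = cart_depth(x),
    task = x$task %||% NA_character_, seed = x$seed
  )
}

cart_depth <- function(model) {
  if (is.null(model$fit)) return(0L)
  nodes <- as.integer(rownames(model$fit$frame))
  max(floor(log2(nodes)))
}

#' Indented decision rules of a CART model
#'
#' @param model A [train_cart()] fit.
#' @return Character vector of indented rule lines.
#' @export
cart_rules <- function(model) {
  if (is.null(model$fit)) {
    return(sprintf("predict %s (single-class training data)", model$majority))
  }
  fr <- model$fit$frame
  nodes <- as.integer(rownames(fr))
  labs <- labels(model$fit)
  cls <- attr(model$fit, "ylevels")[fr$yval]
  recurse <- function(node, depth) {
    i <- match(node, nodes)
    pad <- strrep("  ", depth)
    if (fr$var[i] == "<leaf>") {
      return(sprintf("%s%s -> predict %s (n = %d)", pad, labs[i], cls[i], fr$n[i]))
    }
    head_line <- sprintf("%s%s (n = %d)", pad, labs[i], fr$n[i])
    c(head_line,
      recurse(2L * node, depth + 1L),
      recurse(2L * node + 1L, depth + 1L))
  }
  recurse(1L, 0L)
}

#' Reference reducing-end anomer rule cascade
#'
#' The shipped fixture classifier encoding the published decision rules for
#' the reducing-end anomeric configuration of trisaccharides, operating on
#' the sorted 23-descriptor vector:
#' \enumerate{
#'   \item `C16 < 72.52` ppm: class A (alpha).
#'   \item otherwise, `C6 < 57.16` ppm marks the branch containing 6-deoxy
#'     (Fuc/Rha) methyl or similar upfield carbons; within it:
#'     `C21 >= 96.52` ppm predicts B (beta), otherwise `C23 >= 175.3` ppm
#'     (an N-acetyl carbonyl) still predicts B, and anything else A.
#'   \item on the `C6 >= 57.16` (hexose-rich) branch the anomeric-region rule
#'     alone decides: `C21 >= 96.52` ppm predicts B, otherwise A.
#' }
#' The thresholds are frozen constants, not retrained values.
#'
#' @param x A 23-descriptor vector (raw shift lists are encoded first).
#' @return `"A"` or `"B"`.
#' @examples
#' apply_reference_tree(encode_shifts(c(rep(70, 15), 71, rep(99, 2))))
#' @export
apply_reference_tree <- function(x) {
  if (length(x) != 23) x <- encode_shifts(x)
  x <- as.numeric(x)
  if (x[16] < 72.52) return("A")
  if (x[6] < 57.16) {
    if (x[21] >= 96.52) return("B")
    if (x[23] >= 175.3) return("B")
    return("A")
  }
  if (x[21] >= 96.52) "B" else "A"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
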