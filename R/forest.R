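#' Train a random forest for one task
#'
#' An ensemble of unpruned classification trees, each grown on a bootstrap
#' sample of the training compounds with the best Gini split chosen among
#' `mtry` randomly drawn descriptors per node; prediction is by majority
#' vote, and performance is assessed internally on the out-of-bag (OOB)
#' compounds of each tree. Defaults: 1000 trees and
#' `mtry = floor(sqrt(23)) = 4`. The fit is a seeded wrapper around the
#' randomForest ensemble engine with in-bag bookkeeping retained, so OOB
#' reports, permutation/Gini importance and proximities are available.
#'
#' @param x A `glyco_records` tibble or n x 23 descriptor matrix.
#' @param task Task name (one of [task_names()]); required when `x` is a
#'   records tibble and `y` is missing.
#' @param y Class labels; default `x[[task]]`.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Descriptors sampled per split (default 4).
#' @param seed Integer seed.
#' @return An object of class `glyco_rf`.
#' @examples
#' recs <- generate_dataset(30, 30, seed = 1)
#' fit <- train_rf(recs, task = "ano_r", n_trees = 100, seed = 1)
#' glance(fit)
#' @export
train_rf <- function(x, task = NULL, y = NULL, n_trees = 1000,
                     mtry = floor(sqrt(23)), seed = 1) {
  X <- as_descriptor_matrix(x)
  if (is.null(y)) {
    if (is.null(task) || !is.data.frame(x)) {
      abort("supply y, or a records tibble plus a task name",
            class = "glyco_validation_error")
    }
    y <- x[[task]]
  }
  y <- droplevels(factor(y))
  if (nrow(X) < 2) abort("need at least 2 training compounds",
                         class = "glyco_validation_error")
  rf <- withr::with_seed(as.integer(seed), {
    if (nlevels(y) < 2) {
      NULL  # degenerate single-class training set: forest of root leaves
    } else {
      randomForest::randomForest(
        x = X, y = y, ntree = n_trees, mtry = mtry,
        importance = TRUE, keep.inbag = TRUE, keep.forest = TRUE
      )
    }
  })
  structure(
    list(rf = rf, task = task, X = X, y = y, n_trees = n_trees,
         mtry = mtry, seed = seed),
    class = "glyco_rf"
  )
}

#' @export
print.glyco_rf <- function(x, ...) {
  cat(sprintf("<glyco_rf> %s: %d trees, mtry %d, %d compounds\n",
              x$task %||% "", x$n_trees, x$mtry, nrow(x$X)))
  invisible(x)
}

#' @export
predict.glyco_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_descriptor_matrix(newdata)
  if (is.null(object$rf)) {
    if (type == "class") return(rep(as.character(object$y[1]), nrow(X)))
    return(matrix(1, nrow(X), 1, dimnames = list(NULL, as.character(object$y[1]))))
  }
  prob <- predict(object$rf, X, type = "prob")
  if (type == "prob") return(prob)
  # majority vote with a deterministic alphabetical tie-break (the engine's
  # own response type resolves vote ties randomly)
  colnames(prob)[apply(prob, 1, which.max)]
}

#' Out-of-bag performance report
#'
#' Every training compound is predicted only by the trees in whose bootstrap
#' sample it did not appear; the aggregated confusion counts give the
#' internal (OOB) estimate of performance. Vote shares over those trees are
#' the per-object class probabilities (attached as attribute `"votes"`,
#' rows summing to 1). Compounds that were in-bag in every tree (possible
#' with very few trees) are excluded with a warning.
#'
#' @param model A [train_rf()] fit.
#' @return A `task_report` (see [task_report()]) with a `"votes"` attribute.
#' @export
oob_report <- function(model) {
  stopifnot(inherits(model, "glyco_rf"))
  if (is.null(model$rf)) {
    abort("OOB report undefined for a single-class forest",
          class = "glyco_validation_error")
  }
  pred <- model$rf$predicted
  keep <- !is.na(pred)
  if (any(!keep)) {
    warn(sprintf("%d compounds were never out-of-bag and are excluded",
                 sum(!keep)))
  }
  rep <- task_report(as.character(model$y)[keep], as.character(pred)[keep],
                     task = model$task %||% "task")
  attr(rep, "votes") <- model$rf$votes[keep, , drop = FALSE]
  rep
}

#' Descriptor importance of a random forest
#'
#' Two measures: mean decrease in accuracy (the average increase in OOB
#' misclassification when the descriptor's values are randomly permuted) and
#' mean decrease in Gini (the total impurity decrease attributed to the
#' descriptor over all splits, averaged over trees). A descriptor never used
#' by any tree has zero Gini importance.
#'
#' @param model A [train_rf()] fit.
#' @param top Optionally keep only the `top` descriptors by each ranking.
#' @return A tibble with columns `descriptor`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`, `rank_mda`, `rank_mdg`.
#' @export
rf_importance <- function(model, top = NULL) {
  stopifnot(inherits(model, "glyco_rf"))
  if (is.null(model$rf)) abort("importance undefined for a single-class forest",
                               class = "glyco_validation_error")
  imp <- randomForest::importance(model$rf)
  out <- tibble(
    descriptor = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"])
  )
  out$rank_mda <- rank(-out$mean_decrease_accuracy, ties.method = "first")
  out$rank_mdg <- rank(-out$mean_decrease_gini, ties.method = "first")
  if (!is.null(top)) out <- dplyr::filter(out, .data$rank_mda <= top |
                                            .data$rank_mdg <= top)
  out
}

#' Table of the most important descriptors per task
#'
#' @param models Named list of [train_rf()] fits (one per task).
#' @param top How many descriptors to list (default 10).
#' @return A tibble `task` x `rank` with descriptor names by mean decrease in
#'   Gini and by mean decrease in accuracy.
#' @export
importance_table <- function(models, top = 10) {
  purrr::map_dfr(names(models), function(t) {
    imp <- rf_importance(models[[t]])
    tibble(
      task = t,
      top_by_gini = paste(imp$descriptor[order(imp$rank_mdg)][1:top],
                          collapse = "; "),
      top_by_accuracy = paste(imp$descriptor[order(imp$rank_mda)][1:top],
                              collapse = "; ")
    )
  })
}

#' Forest proximity matrix
#'
#' `prox[i, j]` is the fraction of trees in which compounds i and j land in
#' the same terminal node; it is a supervised similarity because the trees
#' were grown to separate the task's classes. Symmetric with unit diagonal.
#'
#' @param model A [train_rf()] fit.
#' @param x Compounds to compare; default the training set.
#' @return An n x n numeric matrix in `[0, 1]`.
#' @export
rf_proximity <- function(model, x = NULL) {
  stopifnot(inherits(model, "glyco_rf"))
  if (is.null(model$rf)) abort("proximity undefined for a single-class forest",
                               class = "glyco_validation_error")
  X <- if (is.null(x)) model$X else as_descriptor_matrix(x)
  pr <- predict(model$rf, X, proximity = TRUE)$proximity
  dimnames(pr) <- list(rownames(X), rownames(X))
  pr
}

#' @export
tidy.glyco_rf <- function(x, ...) rf_importance(x)

#' @export
glance.glyco_rf <- function(x, ...) {
  oob_err <- if (is.null(x$rf)) 0 else
    mean(x$rf$predicted != x$y, na.rm = TRUE)
  tibble(task = x$task %||% NA_character_, n_trees = x$n_trees,
         mtry = x$mtry, n = nrow(x$X), oob_error = oob_err, seed = x$seed)
}

#' Importance lollipop plot
#'
#' @param object A `glyco_rf` fit.
#' @param measure `"gini"` or `"accuracy"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_rf <- function(object, measure = c("gini", "accuracy"), ...) {
  measure <- match.arg(measure)
  imp <- rf_importance(object)
  col <- if (measure == "gini") "mean_decrease_gini" else "mean_decrease_accuracy"
  imp$descriptor <- factor(imp$descriptor, paste0("C", 1:23))
  ggplot2::ggplot(imp, ggplot2::aes(.data$descriptor, .data[[col]])) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$descriptor, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = col,
                  title = paste("Descriptor importance", object$task %||% "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
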