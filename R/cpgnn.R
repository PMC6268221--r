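#' Kohonen-layer size heuristic
#'
#' The counterpropagation network's square Kohonen layer is sized so that the
#' neuron count is approximately `factor` (default 1.3) times the number of
#' training cases: the side is the smallest integer whose square reaches
#' `factor * n_train`. A training set of 92 compounds therefore gets an
#' 11 x 11 map (121 neurons).
#'
#' @param n_train Number of training compounds (>= 1).
#' @param factor Oversizing factor (default 1.3).
#' @return Integer vector `c(side, side)`.
#' @examples
#' grid_size_for(92)
#' @export
grid_size_for <- function(n_train, factor = 1.3) {
  stopifnot(n_train >= 1)
  side <- as.integer(ceiling(sqrt(factor * n_train)))
  while (side > 1L && (side - 1L)^2 >= factor * n_train) side <- side - 1L
  if (side^2 < factor * n_train) side <- side + 1L
  c(side, side)
}

task_blocks <- function() {
  tasks <- glyco_tasks()
  offsets <- cumsum(c(0, lengths(tasks)))
  lapply(seq_along(tasks), function(i) {
    setNames(offsets[i] + seq_along(tasks[[i]]), tasks[[i]])
  }) |> setNames(names(tasks))
}

check_labels <- function(labels) {
  tasks <- glyco_tasks()
  missing <- setdiff(names(tasks), names(labels))
  if (length(missing)) {
    abort(paste0("missing label columns: ", paste(missing, collapse = ", ")),
          class = "glyco_validation_error")
  }
  for (t in names(tasks)) {
    bad <- !labels[[t]] %in% tasks[[t]]
    if (any(bad)) {
      abort(sprintf("task %s has classes outside {%s}: %s", t,
                    paste(tasks[[t]], collapse = ","),
                    paste(unique(labels[[t]][bad]), collapse = ",")),
            class = "glyco_validation_error")
    }
  }
  labels[names(tasks)]
}

one_hot_targets <- function(labels) {
  labels <- check_labels(labels)
  blocks <- task_blocks()
  D <- max(unlist(blocks))
  Y <- matrix(0, nrow(labels), D)
  for (t in names(blocks)) {
    Y[cbind(seq_len(nrow(labels)), blocks[[t]][labels[[t]]])] <- 1
  }
  Y
}

#' Train a counterpropagation neural network
#'
#' A CPGNN couples a toroidal Kohonen input layer (one 23-element weight
#' vector per neuron, trained on the shift descriptors exactly as in
#' [train_som()]) with an output layer aligned neuron-for-neuron with the
#' map. The output layer acts as a look-up table: for every neuron it holds,
#' per classification task, one entry per class. During training the winning
#' neuron and its shrinking Gaussian neighbourhood move their input weights
#' toward the presented descriptor vector and their output weights toward the
#' one-hot encoding of the compound's nine labels, with the same decaying
#' learning rate. Output entries therefore stay in [0, 1]; neurons never
#' visited retain their small uniform initial values and predictions from
#' them fall back to the alphabetical tie rule.
#'
#' @param x A `glyco_records` tibble (labels taken from it) or an n x 23
#'   descriptor matrix (then `labels` is required).
#' @param labels Data frame with the nine label columns of [task_names()];
#'   defaults to the label columns of `x`.
#' @param width,height Kohonen layer size; default [grid_size_for()] on the
#'   training-set size.
#' @param epochs Training cycles (default 100).
#' @param lr,radius,toroidal,seed As in [train_som()].
#' @return An object of class `cpgnn`.
#' @examples
#' recs <- generate_dataset(15, 15, seed = 1)
#' net <- train_cpgnn(recs, epochs = 30, seed = 1)
#' predict(net, recs[1:2, ])
#' @export
train_cpgnn <- function(x, labels = NULL, width = NULL, height = NULL,
                        epochs = 100, lr = c(0.5, 0.01), radius = NULL,
                        toroidal = TRUE, seed = 1) {
  X <- as_descriptor_matrix(x)
  if (is.null(labels)) {
    if (!is.data.frame(x)) abort("labels required when x is a matrix",
                                 class = "glyco_validation_error")
    labels <- x
  }
  labels <- check_labels(labels)
  if (nrow(X) < 1 || nrow(X) != nrow(labels)) {
    abort("need one label row per descriptor row",
          class = "glyco_validation_error")
  }
  if (is.null(width) || is.null(height)) {
    side <- grid_size_for(nrow(X))[1]
    if (is.null(width)) width <- side
    if (is.null(height)) height <- side
  }
  if (is.null(radius)) radius <- max(width, height) / 2
  K <- width * height
  Y <- one_hot_targets(labels)
  fit <- withr::with_seed(as.integer(seed), {
    W0 <- matrix(rep(colMeans(X), K), nrow = ncol(X)) +
      matrix(runif(ncol(X) * K, -0.5, 0.5), nrow = ncol(X))
    O0 <- matrix(runif(ncol(Y) * K, 0, 0.1), nrow = ncol(Y))
    ord <- matrix(unlist(replicate(epochs, sample.int(nrow(X)) - 1L,
                                   simplify = FALSE)),
                  nrow = epochs, byrow = TRUE)
    kohonen_train_cpp(X, W0, O0, Y, ord, width, height,
                      lr[1], lr[2], radius, toroidal)
  })
  W <- fit$weights
  rownames(W) <- colnames(X)
  kohonen <- structure(
    list(weights = W, width = width, height = height, toroidal = toroidal,
         epochs = epochs, lr = lr, radius = radius, seed = seed),
    class = "som_grid"
  )
  structure(
    list(kohonen = kohonen, output = fit$output, blocks = task_blocks(),
         tasks = glyco_tasks(), epochs = epochs, seed = seed),
    class = "cpgnn"
  )
}

#' @export
print.cpgnn <- function(x, ...) {
  cat(sprintf("<cpgnn> %d x %d toroidal Kohonen layer + 9-task output layer, %d epochs\n",
              x$kohonen$height, x$kohonen$width, x$epochs))
  invisible(x)
}

#' Predict the nine labels with a CPGNN
#'
#' Each compound is routed to its best-matching Kohonen neuron; per task the
#' predicted class is the argmax of that neuron's output-layer block, ties
#' resolved in favour of the alphabetically first class.
#'
#' @param object A trained [train_cpgnn()] model.
#' @param newdata A `glyco_records` tibble or n x 23 descriptor matrix.
#' @param ... Unused.
#' @return A tibble with an `id` column (when available) and one column per
#'   task.
#' @export
predict.cpgnn <- function(object, newdata, ...) {
  X <- as_descriptor_matrix(newdata)
  win <- winners_matrix(object$kohonen, X)
  out <- lapply(names(object$blocks), function(t) {
    block <- object$output[object$blocks[[t]], , drop = FALSE]
    classes <- names(object$blocks[[t]])
    # which.max returns the first maximum: alphabetical tie-break for free
    classes[apply(block[, win, drop = FALSE], 2, which.max)]
  })
  names(out) <- names(object$blocks)
  res <- as_tibble(out)
  if (is.data.frame(newdata) && "id" %in% names(newdata)) {
    res <- dplyr::bind_cols(tibble(id = newdata$id), res)
  } else if (!is.null(rownames(X))) {
    res <- dplyr::bind_cols(tibble(id = rownames(X)), res)
  }
  res
}

#' @export
glance.cpgnn <- function(x, ...) {
  tibble(width = x$kohonen$width, height = x$kohonen$height,
         neurons = x$kohonen$width * x$kohonen$height,
         epochs = x$epochs, seed = x$seed)
}

#' @export
tidy.cpgnn <- function(x, ...) {
  K <- x$kohonen$width * x$kohonen$height
  purrr::map_dfr(names(x$blocks), function(t) {
    block <- x$output[x$blocks[[t]], , drop = FALSE]
    tidyr::expand_grid(neuron = seq_len(K), task = t,
                       class = names(x$blocks[[t]])) |>
      dplyr::mutate(weight = as.vector(block))
  })
}

#' Stratified 10-fold cross-validation of a CPGNN
#'
#' Folds are assigned with a seeded shuffle stratified on `chain_type` (the
#' coarsest label), sizes differing by at most one. Each fold is predicted by
#' a network trained on the other folds (map sized by [grid_size_for()] on
#' the fold-training size); out-of-fold confusion counts are aggregated into
#' a [task_report()].
#'
#' @param records A labelled `glyco_records` tibble with at least 10 rows.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (fold assignment and per-fold training).
#' @param ... Passed to [train_cpgnn()] (e.g. `epochs`).
#' @return A `task_report` (see [task_report()]); predictions are attached as
#'   attribute `"predictions"`.
#' @export
cpgnn_crossvalidate <- function(records, folds = 10, seed = 1, ...) {
  records <- validate_records(records)
  labels <- check_labels(records)
  n <- nrow(records)
  if (n < folds) {
    abort(sprintf(paste0("%d compounds cannot fill %d folds; ",
                         "consider leave-one-out (folds = n)"), n, folds),
          class = "glyco_validation_error")
  }
  fold_id <- integer(n)
  ord <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(n), labels$chain_type), sample), use.names = FALSE)
  })
  fold_id[ord] <- rep(seq_len(folds), length.out = n)
  X <- descriptor_matrix(records)
  pred <- vector("list", folds)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    net <- train_cpgnn(X[!hold, , drop = FALSE], labels[!hold, ],
                       seed = seed + f, ...)
    p <- predict(net, X[hold, , drop = FALSE])
    p$id <- records$id[hold]
    pred[[f]] <- p
  }
  pred <- dplyr::arrange(dplyr::bind_rows(pred), match(.data$id, records$id))
  rep <- task_report(labels, pred[task_names()])
  attr(rep, "predictions") <- pred
  rep
}
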