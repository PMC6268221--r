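as_descriptor_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 23) abort("descriptor matrix must have 23 columns",
                             class = "glyco_validation_error")
    if (!all(is.finite(x))) abort("descriptors must be finite",
                                  class = "glyco_validation_error")
    return(x)
  }
  descriptor_matrix(x)
}

#' Train a toroidal Kohonen self-organizing map
#'
#' Classic online SOM on the 23-descriptor encoding: each presented compound
#' pulls its best-matching unit (minimal Euclidean distance; ties go to the
#' smallest (row, col)) and a Gaussian neighbourhood of it toward itself.
#' The learning rate decays linearly from `lr[1]` to `lr[2]` and the
#' neighbourhood radius from `radius` to 0 over `epochs`. On the default
#' toroidal grid, map edges wrap, so all neurons are topologically
#' equivalent. Weights are initialised at the data mean plus small seeded
#' uniform noise; presentation order is reshuffled every epoch. The whole
#' procedure is deterministic given `seed`.
#'
#' @param x A `glyco_records` tibble or an n x 23 descriptor matrix.
#' @param width,height Grid dimensions. Default: the smallest square whose
#'   neuron count is at least 1.3 times the number of compounds (see
#'   [grid_size_for()]).
#' @param epochs Training cycles over the data (default 100).
#' @param lr Length-2 numeric: initial and final learning rate.
#' @param radius Initial neighbourhood radius; default `max(width, height)/2`.
#' @param toroidal Wrap the grid edges (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `som_grid`.
#' @examples
#' X <- descriptor_matrix(generate_dataset(10, 10, seed = 1))
#' som <- train_som(X, width = 4, height = 4, epochs = 20, seed = 1)
#' @export
train_som <- function(x, width = NULL, height = NULL, epochs = 100,
                      lr = c(0.5, 0.01), radius = NULL, toroidal = TRUE,
                      seed = 1) {
  X <- as_descriptor_matrix(x)
  if (nrow(X) == 0) abort("cannot train a SOM on an empty dataset",
                          class = "glyco_validation_error")
  if (is.null(width) || is.null(height)) {
    side <- grid_size_for(nrow(X))[1]
    if (is.null(width)) width <- side
    if (is.null(height)) height <- side
  }
  if (is.null(radius)) radius <- max(width, height) / 2
  K <- width * height
  fit <- withr::with_seed(as.integer(seed), {
    W0 <- matrix(rep(colMeans(X), K), nrow = ncol(X)) +
      matrix(runif(ncol(X) * K, -0.5, 0.5), nrow = ncol(X))
    ord <- matrix(unlist(replicate(epochs, sample.int(nrow(X)) - 1L,
                                   simplify = FALSE)),
                  nrow = epochs, byrow = TRUE)
    kohonen_train_cpp(X, W0, matrix(numeric(0), 0, K),
                      matrix(numeric(0), nrow(X), 0), ord,
                      width, height, lr[1], lr[2], radius, toroidal)
  })
  W <- fit$weights
  rownames(W) <- colnames(X)
  structure(
    list(weights = W, width = width, height = height, toroidal = toroidal,
         epochs = epochs, lr = lr, radius = radius, seed = seed),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d%s, %d epochs, seed %d\n",
              x$height, x$width, if (x$toroidal) " toroidal" else "",
              x$epochs, x$seed))
  invisible(x)
}

# neuron index k (1-based, row-major) <-> (row, col), 1-based
neuron_row <- function(g, k) (k - 1L) %/% g$width + 1L
neuron_col <- function(g, k) (k - 1L) %% g$width + 1L

#' Toroidal distance between two neurons
#'
#' Euclidean distance in grid coordinates with wrap-around on toroidal maps.
#'
#' @param grid A `som_grid`.
#' @param a,b Neuron indices (1-based, row-major) or `c(row, col)` pairs.
#' @return A non-negative number.
#' @export
neuron_distance <- function(grid, a, b) {
  coord <- function(z) {
    if (length(z) == 2) as.numeric(z)
    else c(neuron_row(grid, z), neuron_col(grid, z))
  }
  a <- coord(a); b <- coord(b)
  dr <- abs(a[1] - b[1]); dc <- abs(a[2] - b[2])
  if (grid$toroidal) {
    dr <- min(dr, grid$height - dr)
    dc <- min(dc, grid$width - dc)
  }
  sqrt(dr^2 + dc^2)
}

winners_matrix <- function(grid, X) {
  W <- grid$weights
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- colSums((W - X[i, ])^2)
    which.min(d2)  # first minimum = smallest row-major index = lex (row, col)
  }, integer(1))
}

#' Best-matching unit for one compound
#'
#' @param grid A trained `som_grid`.
#' @param x A 23-descriptor vector (raw shift lists are encoded with
#'   [encode_shifts()] first).
#' @return Named integer vector `c(row, col, neuron)` (1-based).
#' @export
som_winner <- function(grid, x) {
  if (length(x) != 23) x <- encode_shifts(x)
  k <- winners_matrix(grid, matrix(x, 1))
  c(row = neuron_row(grid, k), col = neuron_col(grid, k), neuron = k)
}

#' @export
tidy.som_grid <- function(x, ...) {
  K <- x$width * x$height
  tibble(neuron = seq_len(K),
         row = neuron_row(x, seq_len(K)),
         col = neuron_col(x, seq_len(K))) |>
    dplyr::bind_cols(as_tibble(t(x$weights)))
}

#' SOM-assisted diversity split into training and test sets
#'
#' Reproduces the map-based approximate 3:1 partition procedure: all
#' compounds are mapped on a SOM trained from their unassigned shifts alone
#' (no structural information), test candidates are taken from singly
#' occupied neurons (compounds that represent a region of chemical space on
#' their own), and `n_test` of them are picked with a seeded greedy
#' maximum-minimum toroidal-distance spread so the test set covers distinct
#' map regions. When fewer singly occupied neurons exist than requested, a
#' warning is emitted and the least-occupied multi-compound neurons
#' contribute one seeded representative each.
#'
#' @param records A `glyco_records` tibble.
#' @param n_test Number of test compounds (must be < number of records).
#' @param grid Optional pre-trained `som_grid`; by default a map sized by
#'   [grid_size_for()] is trained on all records.
#' @param seed Integer seed (SOM training, candidate fallback and spread).
#' @param ... Passed to [train_som()].
#' @return An object of class `diversity_split` with elements `train_ids`,
#'   `test_ids`, `train` and `test` (record subsets), `som`, and
#'   `assignments` (tibble: id, neuron, row, col, occupancy, set).
#' @examples
#' recs <- generate_dataset(20, 20, seed = 1)
#' sp <- diversity_split(recs, n_test = 10, seed = 1, epochs = 30)
#' nrow(sp$train); nrow(sp$test)
#' @export
diversity_split <- function(records, n_test, grid = NULL, seed = 1, ...) {
  records <- validate_records(records)
  n <- nrow(records)
  if (n_test >= n) abort("n_test must be smaller than the number of records",
                         class = "glyco_validation_error")
  X <- descriptor_matrix(records)
  if (is.null(grid)) grid <- train_som(X, seed = seed, ...)
  win <- winners_matrix(grid, X)
  occ <- table(win)
  occupancy <- as.integer(occ[as.character(win)])
  assignments <- tibble(
    id = records$id, neuron = win,
    row = neuron_row(grid, win), col = neuron_col(grid, win),
    occupancy = occupancy
  )

  test_ids <- character(0)
  if (n_test > 0) {
    candidates <- which(occupancy == 1L)
    if (length(candidates) < n_test) {
      warn(sprintf(paste0("only %d singly occupied neurons for %d test ",
                          "compounds; drawing one representative per ",
                          "least-occupied neuron"),
                   length(candidates), n_test))
      extra <- withr::with_seed(as.integer(seed) + 1L, {
        multi <- setdiff(unique(win), win[candidates])
        multi <- multi[order(occ[as.character(multi)], multi)]
        vapply(multi, function(k) {
          members <- which(win == k)
          members[sample.int(length(members), 1)]
        }, integer(1))
      })
      candidates <- c(candidates, extra)
    }
    if (length(candidates) < n_test) {
      abort("not enough distinct neurons to build the requested test set",
            class = "glyco_validation_error")
    }
    # greedy max-min spread over the toroidal map
    test_idx <- withr::with_seed(as.integer(seed) + 2L, {
      sel <- candidates[sample.int(length(candidates), 1)]
      pool <- setdiff(candidates, sel)
      while (length(sel) < n_test) {
        dmin <- vapply(pool, function(i) {
          min(vapply(sel, function(j) {
            neuron_distance(grid, win[i], win[j])
          }, numeric(1)))
        }, numeric(1))
        pick <- pool[order(-dmin, win[pool], pool)][1]
        sel <- c(sel, pick)
        pool <- setdiff(pool, pick)
      }
      sel
    })
    test_ids <- records$id[sort(test_idx)]
  }
  train_ids <- setdiff(records$id, test_ids)
  assignments$set <- ifelse(assignments$id %in% test_ids, "test", "train")
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         train = records[records$id %in% train_ids, ],
         test = records[records$id %in% test_ids, ],
         som = grid, assignments = assignments),
    class = "diversity_split"
  )
}

#' @export
print.diversity_split <- function(x, ...) {
  cat(sprintf("<diversity_split> %d train / %d test on a %d x %d map\n",
              length(x$train_ids), length(x$test_ids),
              x$som$height, x$som$width))
  invisible(x)
}

#' @export
tidy.diversity_split <- function(x, ...) x$assignments

#' Map-occupancy plot of a diversity split
#'
#' @param object A `diversity_split`.
#' @param ... Unused.
#' @return A ggplot: neuron occupancy tiles with test compounds marked.
#' @export
autoplot.diversity_split <- function(object, ...) {
  occ <- dplyr::count(object$assignments, .data$row, .data$col, name = "occupancy")
  test <- dplyr::filter(object$assignments, .data$set == "test")
  ggplot2::ggplot(occ, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$occupancy)) +
    ggplot2::geom_point(data = test, colour = "red", shape = 4, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "column", y = "row",
                  title = "SOM occupancy (x = test compounds)") +
    ggplot2::theme_minimal()
}
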