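# Independent oracles used by the property tests. They deliberately share no
# code with the package implementation.

# selection sort, the brute-force ordering oracle
selection_sort <- function(x) {
  out <- numeric(0)
  while (length(x) > 0) {
    i <- which.min(x)
    out <- c(out, x[i])
    x <- x[-i]
  }
  out
}

# exhaustive enumeration of every descriptor/threshold split by weighted
# Gini decrease; ties resolved to the lowest descriptor then lowest
# threshold (mirrors the documented contract, computed independently)
brute_force_best_split <- function(X, y) {
  gini <- function(v) {
    if (length(v) == 0) return(0)
    p <- table(v) / length(v)
    1 - sum(p^2)
  }
  n <- nrow(X)
  parent <- gini(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    uq <- sort(unique(X[, j]))
    if (length(uq) < 2) next
    for (t in (uq[-1] + uq[-length(uq)]) / 2) {
      left <- X[, j] < t
      dec <- parent - sum(left) / n * gini(y[left]) -
        sum(!left) / n * gini(y[!left])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(descriptor = j, threshold = t, decrease = dec)
      }
    }
  }
  best
}

# brute-force nearest-neuron scan
brute_force_winner <- function(grid, x) {
  K <- grid$width * grid$height
  d2 <- vapply(seq_len(K), function(k) sum((grid$weights[, k] - x)^2),
               numeric(1))
  which.min(d2)
}

# small labelled dataset shared across tests
small_records <- function(n_di = 15, n_tri = 15, seed = 42) {
  generate_dataset(n_di = n_di, n_tri = n_tri, seed = seed)
}

# two well-separated descriptor clusters with aligned labels (all nine
# tasks constant within a cluster)
two_cluster_data <- function(n_per = 20, seed = 99) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(60 + rnorm(n_per * 23, sd = 0.5), n_per, 23),
      matrix(160 + rnorm(n_per * 23, sd = 0.5), n_per, 23)
    )
    colnames(X) <- paste0("C", 1:23)
    labels <- tibble::as_tibble(lapply(glyco_tasks(), function(classes) {
      rep(classes[1:2], each = n_per)
    }))
    list(X = X, labels = labels,
         y = rep(c("A", "B"), each = n_per))
  })
}
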