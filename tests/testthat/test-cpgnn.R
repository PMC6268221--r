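test_that("the Kohonen layer sizing heuristic matches its contract", {
  expect_equal(grid_size_for(92), c(11, 11))
  expect_equal(prod(grid_size_for(92)), 121)
  expect_equal(grid_size_for(1), c(2, 2))
  expect_equal(grid_size_for(100, factor = 1), c(10, 10))
  # smallest side whose square reaches factor * n
  for (n in c(2, 7, 50, 204, 500)) {
    side <- grid_size_for(n)[1]
    expect_gte(side^2, 1.3 * n)
    expect_lt((side - 1)^2, 1.3 * n)
  }
})

test_that("a single object on a 1x1 grid drives the output to its one-hot encoding", {
  recs <- small_records(1, 0, seed = 3)
  net <- train_cpgnn(recs, width = 1, height = 1, epochs = 100, seed = 1)
  expect_true(all(net$output >= 0 & net$output <= 1))
  for (t in task_names()) {
    block <- net$output[net$blocks[[t]], 1]
    onehot <- as.numeric(names(net$blocks[[t]]) == recs[[t]][1])
    expect_true(all(abs(block - onehot) < 0.01))
  }
  expect_equal(predict(net, recs)$ano_r, recs$ano_r[1])
})

test_that("cluster-aligned labels are learned perfectly on separable data", {
  dat <- two_cluster_data()
  net <- train_cpgnn(dat$X, dat$labels, width = 3, height = 3,
                     epochs = 50, seed = 2)
  pred <- predict(net, dat$X)
  for (t in task_names()) {
    expect_identical(pred[[t]], dat$labels[[t]])
  }
})

test_that("training is deterministic given the seed", {
  recs <- small_records(8, 8)
  n1 <- train_cpgnn(recs, epochs = 20, seed = 5)
  n2 <- train_cpgnn(recs, epochs = 20, seed = 5)
  expect_identical(n1$output, n2$output)
  expect_identical(n1$kohonen$weights, n2$kohonen$weights)
})

test_that("uniform output vectors fall back to the alphabetically first class", {
  recs <- small_records(5, 5)
  net <- train_cpgnn(recs, epochs = 10, seed = 1)
  net$output[] <- 0.5
  pred <- predict(net, recs[1, ])
  for (t in task_names()) expect_equal(pred[[t]], "A")
})

test_that("prediction routes through the brute-force nearest neuron", {
  recs <- small_records(8, 8)
  net <- train_cpgnn(recs, epochs = 20, seed = 6)
  withr::with_seed(7, {
    for (i in 1:50) {
      x <- matrix(runif(23, 0, 200), 1)
      colnames(x) <- paste0("C", 1:23)
      k <- brute_force_winner(net$kohonen, x[1, ])
      classes <- names(net$blocks$red_end)
      expected <- classes[which.max(net$output[net$blocks$red_end, k])]
      expect_equal(predict(net, x)$red_end, expected)
    }
  })
})

test_that("prediction is invariant to presentation order", {
  recs <- small_records(10, 10)
  net <- train_cpgnn(recs, epochs = 15, seed = 2)
  perm <- withr::with_seed(3, sample(nrow(recs)))
  p_direct <- predict(net, recs)
  p_perm <- predict(net, recs[perm, ])
  expect_identical(p_perm[order(perm), ][task_names()], p_direct[task_names()])
})

test_that("cross-validation folds are balanced and small n is rejected", {
  recs <- small_records(15, 15)
  labels <- recs[task_names()]
  n <- nrow(recs)
  fold_sizes <- withr::with_seed(1, {
    ord <- unlist(lapply(split(seq_len(n), labels$chain_type), sample),
                  use.names = FALSE)
    fold <- integer(n); fold[ord] <- rep(1:10, length.out = n)
    table(fold)
  })
  expect_lte(diff(range(fold_sizes)), 1)
  expect_error(cpgnn_crossvalidate(recs[1:8, ], seed = 1),
               regexp = "leave-one-out", class = "glyco_validation_error")
})

test_that("cross-validated CPGNN is perfect on separable data and at chance under permuted labels", {
  dat <- two_cluster_data(n_per = 25)
  recs <- tibble::tibble(id = sprintf("c%02d", 1:50),
                         shifts = lapply(seq_len(50), function(i) {
                           dat$X[i, ][dat$X[i, ] > 0]
                         }))
  recs <- dplyr::bind_cols(recs, dat$labels)
  cv <- cpgnn_crossvalidate(recs, epochs = 40, seed = 4)
  expect_true(all(glance(cv)$mean_predictability == 100))

  # permuted labels: macro sensitivity collapses to the 100/k chance level
  perm <- withr::with_seed(8, {
    recs2 <- small_records(40, 40, seed = 31)
    recs2[task_names()] <- recs2[sample(nrow(recs2)), task_names()]
    recs2
  })
  cv_null <- cpgnn_crossvalidate(perm, epochs = 40, seed = 4)
  mp <- glance(cv_null)
  for (t in mp$task) {
    k <- length(unique(perm[[t]]))
    chance <- 100 / k
    se <- 100 * sqrt((1 / k) * (1 - 1 / k) / nrow(perm))
    expect_lt(abs(mp$mean_predictability[mp$task == t] - chance), 3 * se)
  }
})

test_that("output layer stays within [0, 1] after training", {
  recs <- small_records(10, 10)
  net <- train_cpgnn(recs, epochs = 30, seed = 9)
  expect_true(all(net$output >= 0 & net$output <= 1))
})
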