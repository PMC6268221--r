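test_that("Gini impurity matches its closed form", {
  expect_equal(gini_impurity(c(6, 0)), 0)
  expect_equal(gini_impurity(c(3, 3)), 0.5)
  expect_equal(gini_impurity(c(1, 1, 1, 1)), 0.75)
  expect_error(gini_impurity(c(0, 0)), class = "glyco_validation_error")
  expect_error(gini_impurity(c(-1, 2)), class = "glyco_validation_error")
})

test_that("a perfectly separating descriptor recovers the full parent impurity", {
  X <- cbind(c(1, 2, 3, 10, 11, 12), rep(5, 6))
  y <- rep(c("A", "B"), each = 3)
  sp <- best_split(X, y)
  expect_equal(sp$descriptor, 1)
  expect_equal(sp$threshold, 6.5)
  expect_equal(sp$decrease, gini_impurity(c(3, 3)))
})

test_that("best_split agrees with exhaustive enumeration on random instances", {
  withr::with_seed(10, {
    for (rep in 1:40) {
      n <- sample(4:10, 1)
      p <- sample(2:4, 1)
      X <- matrix(sample(1:6, n * p, replace = TRUE) + runif(n * p, 0, 0.01),
                  n, p)
      y <- sample(c("A", "B", "C"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      got <- best_split(X, y)
      want <- brute_force_best_split(X, y)
      expect_equal(got$descriptor, want$descriptor)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$decrease, want$decrease)
    }
  })
})

test_that("constant descriptors signal a leaf", {
  X <- matrix(1, 6, 3)
  expect_null(best_split(X, rep(c("A", "B"), 3)))
})

test_that("CART on separable data is a single split with zero training error", {
  X <- matrix(runif(23 * 60, 40, 60), 60, 23)
  X[, 7] <- rep(c(20, 120), each = 30)
  colnames(X) <- paste0("C", 1:23)
  y <- rep(c("A", "B"), each = 30)
  fit <- train_cart(X, y = y, seed = 1)
  expect_equal(glance(fit)$n_leaves, 2L)
  expect_equal(predict(fit, X), y)
})

test_that("extreme complexity prunes to a majority-vote root leaf", {
  recs <- small_records(15, 15)
  fit <- train_cart(recs, task = "red_end", complexity = 1, seed = 1)
  expect_equal(glance(fit)$n_leaves, 1L)
  expect_equal(length(unique(predict(fit, recs))), 1L)
})

test_that("single-class training data yields a root leaf", {
  recs <- small_records(6, 0)
  fit <- train_cart(recs, task = "chain_type", seed = 1)  # all X
  expect_equal(predict(fit, recs), rep("X", 6))
})

test_that("training error is non-increasing as the unpruned tree deepens", {
  recs <- small_records(40, 40, seed = 17)
  X <- descriptor_matrix(recs)
  df <- data.frame(y = factor(recs$red_end), X)
  tree <- withr::with_seed(1, rpart::rpart(y ~ ., df, method = "class",
                                           control = rpart::rpart.control(cp = 0, xval = 0)))
  rel_err <- tree$cptable[, "rel error"]
  expect_true(all(diff(rel_err) <= 1e-12))
})

# A training set constructed so that the published reducing-end rule
# cascade is recoverable: the tree must use four distinct descriptors with
# C6 reused once, at depth 4.
reference_style_training_set <- function() {
  withr::with_seed(20, {
    mk <- function(n, c6, c16, c21, c23, class) {
      X <- matrix(runif(n * 23, 49.9, 50.1), n, 23)
      X[, 6] <- runif(n, c6[1], c6[2])
      X[, 16] <- runif(n, c16[1], c16[2])
      X[, 21] <- runif(n, c21[1], c21[2])
      X[, 23] <- runif(n, c23[1], c23[2])
      list(X = X, y = rep(class, n))
    }
    regions <- list(
      mk(40, c(20, 55), c(65, 72), c(97, 105), c(150, 175), "A"),
      mk(30, c(20, 57), c(73.2, 80), c(97, 105), c(150, 175), "B"),
      mk(20, c(20, 57), c(73.2, 80), c(90, 96), c(176, 180), "B"),
      mk(10, c(20, 57), c(73.2, 80), c(90, 96), c(150, 175), "A"),
      mk(30, c(57.5, 60.5), c(73.2, 80), c(90, 96), c(150, 175), "A"),
      mk(12, c(61.2, 63.3), c(73.2, 80), c(90, 96), c(150, 175), "B"),
      mk(6, c(64.5, 67), c(73.2, 80), c(90, 96), c(150, 175), "A")
    )
    X <- do.call(rbind, lapply(regions, `[[`, "X"))
    colnames(X) <- paste0("C", 1:23)
    list(X = X, y = unlist(lapply(regions, `[[`, "y")))
  })
}

test_that("the reference-style training set reproduces the published tree shape", {
  dat <- reference_style_training_set()
  fit <- train_cart(dat$X, y = dat$y, seed = 2)
  vars <- fit$fit$frame$var
  internal <- as.character(vars[vars != "<leaf>"])
  expect_setequal(unique(internal), c("C16", "C6", "C21", "C23"))
  expect_equal(sum(internal == "C6"), 2L)
  expect_length(internal, 5L)
  expect_equal(cart_depth(fit), 4L)
})

test_that("the frozen reference cascade reproduces the published rule outcomes", {
  probe <- function(c6, c16, c21, c23) {
    v <- sort(c(1, 2, 3, 4, 5, c6, c6 + (1:9) * 0.5, c16,
                c16 + (c21 - c16) * (1:4) / 5, c21, (c21 + c23) / 2, c23))
    stopifnot(length(v) == 23)
    v
  }
  # first node: alpha side
  expect_equal(apply_reference_tree(probe(40, 70.10, 99, 150)), "A")
  expect_equal(apply_reference_tree(probe(40, 72.51, 99, 150)), "A")
  # deoxy branch: anomeric-region rule
  expect_equal(apply_reference_tree(probe(40, 80, 99, 150)), "B")
  expect_equal(apply_reference_tree(probe(40, 80, 96.53, 150)), "B")
  # deoxy branch: carbonyl rule
  expect_equal(apply_reference_tree(probe(40, 80, 96.51, 176)), "B")
  expect_equal(apply_reference_tree(probe(40, 80, 96.51, 175.31)), "B")
  expect_equal(apply_reference_tree(probe(40, 80, 96.51, 175.29)), "A")
  expect_equal(apply_reference_tree(probe(40, 80, 90, 150)), "A")
  # hexose-rich branch: the anomeric-region rule decides alone
  expect_equal(apply_reference_tree(probe(58, 80, 99, 150)), "B")
  expect_equal(apply_reference_tree(probe(58, 80, 90, 150)), "A")
})

test_that("cart_rules renders an indented, complete rule listing", {
  dat <- reference_style_training_set()
  fit <- train_cart(dat$X, y = dat$y, seed = 2)
  rules <- cart_rules(fit)
  expect_true(any(grepl("C16", rules)))
  expect_true(any(grepl("predict", rules)))
  expect_gte(sum(grepl("->", rules, fixed = TRUE)), glance(fit)$n_leaves)
})
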