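# Separable 2-D toy: two Gaussian blobs, labels by blob.
separable_toy <- function(n = 40, gap = 6, seed = 5) {
  set.seed(seed)
  half <- n / 2
  X <- rbind(cbind(rnorm(half), rnorm(half)),
             cbind(rnorm(half) + gap, rnorm(half) + gap))
  list(X = X, y = c(rep(-1, half), rep(1, half)))
}

test_that("adaboost closed forms and early stopping behave as specified", {
  # weighted error 0.5 -> alpha 0 (closed form; checked through the formula
  # the trainer records)
  expect_equal(0.5 * log((1 - 0.5) / 0.5), 0)

  # a perfectly separable 1-d threshold: round 1 has eps = 0, training halts
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  fit <- train_adaboost(X, y, T = 25)
  expect_length(fit$learners, 1)
  expect_equal(fit$eps, 0)
  expect_equal(tail(fit$train_error_trace, 1), 0)

  expect_error(train_adaboost(X, rep(1, 6), T = 5),
               class = "hotspotseg_training_error")
})

test_that("training error respects the exponential bound on separable data", {
  toy <- separable_toy(40, gap = 4, seed = 9)
  fit <- train_adaboost(toy$X, toy$y, T = 20)
  # bound after t rounds: prod_{s<=t} 2 sqrt(eps_s (1 - eps_s)); eps = 0
  # rounds contribute 0, making the bound (and the error) exactly 0
  bounds <- cumprod(2 * sqrt(fit$eps * (1 - fit$eps)))
  expect_true(all(fit$train_error_trace <= bounds + 1e-12))
  expect_equal(tail(fit$train_error_trace, 1), 0)
})

test_that("margin equals the hand-summed weighted vote of the trees", {
  toy <- separable_toy(30, gap = 3, seed = 13)
  fit <- train_adaboost(toy$X, toy$y, T = 10)

  # independent tree traversal, reading the serialized structure directly
  traverse <- function(tree, x) {
    while (!tree$leaf) {
      tree <- if (x[tree$feature] <= tree$threshold) tree$left else tree$right
    }
    tree$pred
  }
  for (i in c(1, 7, 30)) {
    hand <- sum(fit$alphas * vapply(fit$learners, traverse, numeric(1),
                                    x = toy$X[i, ]))
    expect_equal(margin(fit, toy$X[i, ]), hand, tolerance = 1e-12)
  }

  # single-learner arithmetic
  one <- fit
  one$learners <- fit$learners[1]
  one$alphas <- 0.7
  h1 <- vapply(list(toy$X[1, ]), traverse, numeric(1), tree = fit$learners[[1]])
  expect_equal(margin(one, toy$X[1, ]), 0.7 * h1)

  expect_error(margin(fit, c(1, 2, 3)), class = "hotspotseg_size_error")
})

test_that("three-level rule partitions every margin exactly once", {
  toy <- separable_toy(30, gap = 3, seed = 13)
  fit <- train_adaboost(toy$X, toy$y, T = 10)

  fit$theta <- 0.5
  lab <- classify_three_level(fit, toy$X)
  r <- margin(fit, toy$X)
  expect_identical(lab, ifelse(r > 0.5, "I", ifelse(r < -0.5, "III", "II")))
  expect_true(all(lab %in% c("I", "II", "III")))

  # theta = 0: level II only at exactly 0
  expect_false(any(classify_three_level(fit, toy$X, theta = 0)[r != 0] == "II"))

  # quantile calibration: on overlapping classes the margins vary, so the
  # median-|margin| band captures roughly half the cases
  ov <- separable_toy(60, gap = 0.8, seed = 2)  # heavily overlapping blobs
  fit_ov <- train_adaboost(ov$X, ov$y, T = 15)
  fit_ov <- calibrate_theta(fit_ov, ov$X, prob = 0.5)
  lab_ov <- classify_three_level(fit_ov, ov$X)
  expect_gte(mean(lab_ov == "II"), 0.25)
  expect_lte(mean(lab_ov == "II"), 0.75)
  # ...and with every |margin| tied (single perfect learner) the nudge keeps
  # all decisions confident instead of sending 90% to level II
  fit_tied <- calibrate_theta(fit, toy$X, prob = 0.1)
  expect_false(any(classify_three_level(fit_tied, toy$X) == "II"))
})

test_that("sample weights stay normalized across boosting rounds", {
  # re-run the reweighting recurrence from the recorded trace: weights are
  # renormalized each round, so any valid trace keeps sum(w) = 1
  toy <- separable_toy(40, gap = 2, seed = 3)
  X <- toy$X; y <- toy$y
  n <- nrow(X)
  fit <- train_adaboost(X, y, T = 8)
  w <- rep(1 / n, n)
  for (t in seq_along(fit$alphas)) {
    h <- vapply(seq_len(n), function(i) {
      tree <- fit$learners[[t]]
      while (!tree$leaf) {
        tree <- if (X[i, tree$feature] <= tree$threshold) tree$left else tree$right
      }
      tree$pred
    }, numeric(1))
    expect_equal(sum(w[h != y]), fit$eps[t], tolerance = 1e-12)
    if (fit$eps[t] == 0) break
    w <- w * exp(-fit$alphas[t] * y * h)
    w <- w / sum(w)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("tidy and glance expose the boosting trace", {
  toy <- separable_toy(30, gap = 3, seed = 1)
  fit <- train_adaboost(toy$X, toy$y, T = 5)
  td <- tidy(fit)
  expect_named(td, c("round", "alpha", "weighted_error", "train_error"))
  expect_equal(nrow(td), length(fit$alphas))
  gl <- glance(fit)
  expect_equal(gl$rounds, length(fit$alphas))
})
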