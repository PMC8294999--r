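# Synthetic bag world: feature 1 separates planted positives (x1 > 1)
# from everything else; remaining features are noise.
planted_bags <- function(n_pos = 20, n_neg = 20, per_bag = 8, d = 4,
                         seed = 17) {
  set.seed(seed)
  make_inst <- function(n, planted) {
    X <- matrix(rnorm(n * d, 0, 0.3), n, d)
    if (planted > 0) X[seq_len(planted), 1] <- 1.5 + abs(rnorm(planted, 0, 0.2))
    X
  }
  tibble::tibble(
    bag_id = seq_len(n_pos + n_neg),
    label = c(rep(1, n_pos), rep(-1, n_neg)),
    instances = c(lapply(seq_len(n_pos), function(i) make_inst(per_bag, 1)),
                  lapply(seq_len(n_neg), function(i) make_inst(per_bag, 0)))
  )
}

test_that("bag probability rules implement max and noisy-or", {
  expect_equal(bag_probability(0.3, "max"), 0.3)
  expect_equal(bag_probability(0.3, "noisy-or"), 0.3)
  expect_equal(bag_probability(c(0.5, 0.5), "noisy-or"), 0.75)
  expect_equal(bag_probability(c(0.2, 0.9, 0.4), "max"), 0.9)
  expect_error(bag_probability(numeric(0)), class = "hotspotseg_input_error")

  # noisy-or dominates max dominates any single instance
  for (k in 1:20) {
    p <- runif(5)
    expect_gte(bag_probability(p, "noisy-or"), bag_probability(p, "max"))
    expect_gte(bag_probability(p, "max"), max(p) - 1e-15)
  }
})

test_that("the bag loss has its closed-form values and floor", {
  expect_equal(mil_loss(1, 1), 0, tolerance = 1e-9)
  expect_equal(mil_loss(0.5, 1), -log(0.5))
  expect_equal(mil_loss(0, -1), 0, tolerance = 1e-9)
  expect_gte(mil_loss(c(0.2, 0.8), c(1, -1)), 0)
  # clipping keeps boundary probabilities finite
  expect_true(is.finite(mil_loss(c(0, 1), c(1, -1))))
  expect_error(mil_loss(0.5, c(1, -1)), class = "hotspotseg_input_error")
})

test_that("MILBoost descends the loss and recovers planted bags", {
  bags <- planted_bags()
  fit <- train_milboost(bags, T = 30, seed = 4)
  tr <- fit$loss_trace

  # loss after every accepted round strictly below its predecessor
  expect_true(all(diff(tr) < 0))
  # first entry: empty ensemble, all instance probs 0.5
  expect_equal(tr[1], mil_loss(
    vapply(bags$instances,
           function(X) bag_probability(rep(0.5, nrow(X)), "noisy-or"),
           numeric(1)),
    bags$label))

  # final loss matches an independent recomputation from the serialized model
  stump_score <- function(model, x) {
    s <- 0
    for (t in seq_along(model$stumps)) {
      st <- model$stumps[[t]]
      h <- if (x[st$feature] > st$threshold) st$polarity else -st$polarity
      s <- s + model$weights[t] * h
    }
    s
  }
  probs <- vapply(bags$instances, function(X) {
    p <- 1 / (1 + exp(-apply(X, 1, stump_score, model = fit$model)))
    bag_probability(p, "noisy-or")
  }, numeric(1))
  expect_equal(tail(tr, 1), mil_loss(probs, bags$label), tolerance = 1e-9)

  # perfect bag-level recovery within T = 30
  pred <- predict(fit$model, bags)
  expect_equal(mean((pred > 0.5) == (bags$label == 1)), 1)

  expect_error(train_milboost(dplyr::filter(bags, label == 1), T = 5),
               class = "hotspotseg_training_error")
})

test_that("the max rule also trains (subgradient at the argmax)", {
  bags <- planted_bags(n_pos = 10, n_neg = 10)
  fit <- train_milboost(bags, T = 15, seed = 2, rule = "max")
  expect_true(all(diff(fit$loss_trace) < 0))
  pred <- predict(fit$model, bags)
  expect_gte(mean((pred > 0.5) == (bags$label == 1)), 0.9)
})

test_that("bags built from phantoms respect the construction contract", {
  models <- trained_models()
  dict <- models$dictionary
  co <- generate_cohort(c(2, 0, 2), small_spec(), seed = 31)
  bags <- make_bags(co, dict, per_bag = 10, seed = 5)
  expect_equal(bags$label, c(1, 1, -1, -1))
  expect_true(all(vapply(bags$instances, nrow, integer(1)) == 10))
  # determinism
  bags2 <- make_bags(co, dict, per_bag = 10, seed = 5)
  expect_identical(bags$instances, bags2$instances)
  # no negative images available -> construction error
  expect_error(make_bags(generate_cohort(c(2, 0, 0), small_spec(), seed = 1),
                         dict, per_bag = 5, seed = 1),
               class = "hotspotseg_construction_error")
})

test_that("probability maps have image shape, unit range and correct pooling", {
  models <- trained_models()
  cs <- generate_phantom(small_spec(), seed = 401)
  pm <- scan_probability_map(models$mil, cs$image, models$dictionary,
                             stride = 4)
  expect_equal(dim(pm), dim(cs$image))
  expect_true(all(pm >= 0 & pm <= 1))

  # empty ensemble: uniform 0.5
  empty <- structure(list(stumps = list(), weights = numeric(0),
                          rule = "noisy-or",
                          n_features = ncol(models$dictionary$atoms)),
                     class = "mil_model")
  pm0 <- scan_probability_map(empty, cs$image[1:20, 1:20], models$dictionary,
                              stride = 4)
  expect_true(all(pm0 == 0.5))

  expect_error(scan_probability_map(models$mil, cs$image[1:4, 1:4],
                                    models$dictionary, stride = 2),
               class = "hotspotseg_size_error")

  # coverage averaging oracle on a two-window toy layout: an 8x9 image with
  # l = 8, stride 1 has two windows; columns 2..8 are covered by both
  toy <- cs$image[1:8, 1:9]
  pmt <- scan_probability_map(models$mil, toy, models$dictionary, stride = 1)
  P <- patches_at_oracle(toy, c(1, 1), c(1, 2), 8)
  mu <- rowMeans(P)
  C <- cbind(encode(P - mu, models$dictionary), mu)
  pr <- 1 / (1 + exp(-vapply(seq_len(2), function(i) {
    s <- 0
    for (t in seq_along(models$mil$stumps)) {
      st <- models$mil$stumps[[t]]
      h <- if (C[i, st$feature] > st$threshold) st$polarity else -st$polarity
      s <- s + models$mil$weights[t] * h
    }
    s
  }, numeric(1))))
  expect_equal(pmt[1, 1], pr[1], tolerance = 1e-12)          # only window 1
  expect_equal(pmt[1, 9], pr[2], tolerance = 1e-12)          # only window 2
  expect_equal(pmt[4, 5], mean(pr), tolerance = 1e-12)       # both windows
})
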