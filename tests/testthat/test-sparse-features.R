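test_that("patch extraction satisfies its shape and determinism contracts", {
  img <- matrix(runif(40 * 30), 40, 30)
  ps <- extract_patches(img, l = 8, n = 100, seed = 5)
  expect_equal(dim(ps$patches), c(100, 64))
  ps2 <- extract_patches(img, l = 8, n = 100, seed = 5)
  expect_identical(ps$patches, ps2$patches)

  # image exactly l x l: the single patch is the whole image (row-major)
  tiny <- matrix(1:9 / 10, 3, 3)
  one <- extract_patches(tiny, l = 3, n = 1, seed = 1)
  expect_equal(as.vector(one$patches),
               as.vector(t(tiny)))  # row-major flattening

  const <- matrix(0.4, 20, 20)
  pc <- extract_patches(const, l = 4, n = 10, seed = 2)
  expect_true(all(pc$patches == 0.4))

  expect_error(extract_patches(tiny, l = 5, n = 1, seed = 1),
               class = "hotspotseg_size_error")
})

test_that("dictionary learning descends the objective and keeps unit atoms", {
  set.seed(42)
  X <- matrix(rnorm(10 * 9), 10, 9)
  fit <- learn_dictionary(X, m = 4, lambda = 0.1, n_iters = 25, seed = 3,
                          center = FALSE, tol = 0)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9))
  # final trace value equals an independent plain-R re-evaluation
  expect_equal(tail(tr, 1),
               objective_oracle(X, fit$atoms, fit$codes, 0.1),
               tolerance = 1e-10)
  expect_equal(sqrt(colSums(fit$atoms^2)), rep(1, 4), tolerance = 1e-9)

  # all-zero patches: global minimum at the origin
  z <- learn_dictionary(matrix(0, 5, 4), m = 2, lambda = 0.1, n_iters = 3,
                        seed = 1, center = FALSE)
  expect_true(all(z$codes == 0))
  expect_equal(tail(z$objective_trace, 1), 0)

  # enormous l1 penalty: codes zero, objective = sum ||x||^2
  big <- learn_dictionary(X, m = 3, lambda = max(abs(X)) * 1e4, n_iters = 3,
                          seed = 1, center = FALSE)
  expect_true(all(big$codes == 0))
  expect_equal(tail(big$objective_trace, 1), sum(X^2), tolerance = 1e-12)
})

test_that("encode matches a brute-force grid-search oracle on 4-dim toys", {
  set.seed(7)
  Phi <- qr.Q(qr(matrix(rnorm(8), 4, 2)))  # orthonormal atoms
  lam <- 0.1
  for (rep in 1:3) {
    x <- rnorm(4, sd = 0.7)
    cc <- encode(matrix(x, 1, 4), Phi, lambda = lam)
    # 2-d brute force over coefficient pairs, coarse pass then 1e-3 refinement
    co <- expand.grid(a = seq(-2, 2, 0.05), b = seq(-2, 2, 0.05))
    v <- (co$a * 0)
    for (k in seq_len(nrow(co))) {
      v[k] <- sum((x - co$a[k] * Phi[, 1] - co$b[k] * Phi[, 2])^2) +
        lam * (abs(co$a[k]) + abs(co$b[k]))
    }
    k0 <- which.min(v)
    fine <- expand.grid(a = seq(co$a[k0] - 0.06, co$a[k0] + 0.06, 1e-3),
                        b = seq(co$b[k0] - 0.06, co$b[k0] + 0.06, 1e-3))
    vf <- numeric(nrow(fine))
    for (k in seq_len(nrow(fine))) {
      vf[k] <- sum((x - fine$a[k] * Phi[, 1] - fine$b[k] * Phi[, 2])^2) +
        lam * (abs(fine$a[k]) + abs(fine$b[k]))
    }
    kb <- which.min(vf)
    expect_lt(max(abs(cc - c(fine$a[kb], fine$b[kb]))), 2e-3)
  }

  # zero patch -> zero code; perfect single-atom representation at lambda 0
  expect_true(all(encode(matrix(0, 1, 4), Phi, lambda = 0.1) == 0))
  atom <- Phi[, 1, drop = FALSE]
  expect_equal(as.vector(encode(matrix(Phi[, 1], 1, 4), atom, lambda = 0)),
               1, tolerance = 1e-8)
  expect_error(encode(matrix(0, 1, 5), Phi), class = "hotspotseg_size_error")
})

test_that("pooled image features have the stated shape and invariances", {
  img <- generate_phantom(small_spec(), seed = 2)$image
  dict <- fixture("dict16", function() {
    ps <- extract_patches(img, l = 8, n = 400, seed = 1)
    learn_dictionary(ps, m = 16, lambda = 0.1, n_iters = 8, seed = 2)
  })
  fv <- image_feature(img, dict, stride = 6)
  expect_length(fv, 32)
  # max-pool half dominates mean-pool half coordinatewise
  expect_true(all(fv[1:16] >= fv[17:32] - 1e-12))
  expect_true(all(fv >= 0))

  # constant image -> zero feature (centered patches are all zero)
  expect_equal(image_feature(matrix(0.7, 32, 32), dict, stride = 4),
               rep(0, 32))

  # a global brightness shift (no clipping: 0.7-scaled image has headroom)
  # leaves the mean-subtracted features unchanged
  head_img <- img * 0.7
  expect_equal(image_feature(head_img + 0.2, dict, stride = 6),
               image_feature(head_img, dict, stride = 6),
               tolerance = 1e-8)
})

test_that("encode is invariant to atom sign flips up to code sign flips", {
  set.seed(11)
  X <- matrix(rnorm(6 * 9), 6, 9)
  Phi <- matrix(rnorm(9 * 3), 9, 3)
  Phi <- sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
  C1 <- encode(X, Phi, lambda = 0.2)
  flip <- c(1, -1, 1)
  C2 <- encode(X, sweep(Phi, 2, flip, "*"), lambda = 0.2)
  expect_equal(sweep(C1, 2, flip, "*"), C2, tolerance = 1e-8)
})
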