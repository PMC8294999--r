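# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_spec <- function(...) {
  phantom_spec(height = 96, width = 96, n_hotspots = 2,
               hotspot_radius_range = c(4, 9), ...)
}

small_config <- function(...) {
  pipeline_config(l = 8L, m = 16L, adaboost_T = 30L, mil_T = 30L,
                  stride = 2L, feature_stride = 4L, seed = 7L, ...)
}

# A small trained cascade shared by the MIL / pipeline / acceptance tests.
trained_models <- function() {
  fixture("models", function() {
    train <- generate_cohort(c(10, 4, 8), small_spec(), seed = 1001)
    train_pipeline(train, small_config(), n_patches = 3000L, dict_iters = 8L)
  })
}

# Independent connected-component count via breadth-first flood fill
# (4-connectivity), used as the oracle for mask topology.
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (mask[r0, c0] > 0 && !seen[r0, c0]) {
      ncomp <- ncomp + 1L
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r <- p[1] + d[1]; c <- p[2] + d[2]
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] > 0 && !seen[r, c]) {
            seen[r, c] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  ncomp
}

# Plain-R re-evaluation of the sparse-coding objective, independent of the
# compiled path.
objective_oracle <- function(X, Phi, C, lambda) {
  sum((X - C %*% t(Phi))^2) + lambda * sum(abs(C))
}

# Independent row-major patch flattening (matches the package convention).
patches_at_oracle <- function(image, rows, cols, l) {
  t(vapply(seq_along(rows), function(k) {
    as.vector(t(image[rows[k]:(rows[k] + l - 1), cols[k]:(cols[k] + l - 1)]))
  }, numeric(l * l)))
}
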