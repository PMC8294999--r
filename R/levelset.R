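# Chan-Vese region-based level set. Convention used throughout: the inside
# (hot-spot) region is {phi <= 0}. The probability-map binarization assigns
# phi = -g to high-probability pixels, so the literal three-way rule and the
# inside-is-negative convention agree.

#' Initialize the level-set field from a probability map
#'
#' Three-way thresholding of the hot-spot probability map at `rho`:
#' \eqn{\phi = -g} where \eqn{P(m) > \rho} (inside/hot), \eqn{0} where
#' \eqn{P(m) = \rho}, and \eqn{+g} where \eqn{P(m) < \rho}. The inside region
#' is \eqn{\{\phi \le 0\}}.
#'
#' @param prob_map Numeric matrix with values in \[0, 1\].
#' @param rho Threshold in (0, 1).
#' @param g Field amplitude (> 0); default 0.5.
#' @return The numeric matrix `phi`.
#' @export
initialize_phi <- function(prob_map, rho = 0.5, g = 0.5) {
  assert_image(prob_map, "prob_map")
  if (any(prob_map < 0 | prob_map > 1)) {
    abort("`prob_map` values must lie in [0, 1].",
          class = "hotspotseg_input_error")
  }
  check_scalar(rho, "rho", lower = 0, upper = 1, strict_lower = TRUE)
  if (rho >= 1) abort("`rho` must lie in (0, 1).", class = "hotspotseg_spec_error")
  check_scalar(g, "g", lower = 0, strict_lower = TRUE)
  phi <- matrix(0, nrow(prob_map), ncol(prob_map))
  phi[prob_map < rho] <- g
  phi[prob_map > rho] <- -g
  phi
}

#' Region means of the two-phase partition
#'
#' `g_a` is the mean intensity over the inside \eqn{\{\phi \le 0\}}, `g_b`
#' over the outside \eqn{\{\phi > 0\}} — the exact minimizers of the
#' piecewise-constant fitting energy for a fixed contour.
#'
#' @param image Numeric matrix.
#' @param phi Level-set field, same dimensions.
#' @return Named numeric vector `c(g_a, g_b)`.
#' @export
region_means <- function(image, phi) {
  assert_image(image)
  assert_same_dim(image, phi, c("image", "phi"))
  inside <- phi <= 0
  if (!any(inside) || all(inside)) {
    abort("degenerate partition: one region is empty.",
          class = "hotspotseg_degenerate_error")
  }
  c(g_a = mean(image[inside]), g_b = mean(image[!inside]))
}

#' Chan-Vese fitting energy
#'
#' \deqn{E = \lambda_a \sum_{\Omega_a} (P - g_a)^2 +
#'   \lambda_b \sum_{\Omega_b} (P - g_b)^2}
#' with \eqn{g_a, g_b} the region means of the current partition.
#'
#' @param image Numeric matrix.
#' @param phi Level-set field.
#' @param lambda_a,lambda_b Positive region weights.
#' @return Non-negative scalar energy.
#' @export
cv_energy <- function(image, phi, lambda_a = 1, lambda_b = 1) {
  g <- region_means(image, phi)
  inside <- phi <= 0
  lambda_a * sum((image[inside] - g[["g_a"]])^2) +
    lambda_b * sum((image[!inside] - g[["g_b"]])^2)
}

# Smoothed Dirac delta (width eps, in pixels of phi amplitude).
delta_eps <- function(phi, eps = 1) {
  eps / (pi * (eps^2 + phi^2))
}

# Mean curvature of phi by central differences, div(grad phi / |grad phi|).
curvature <- function(phi) {
  pad <- function(M) {
    M2 <- rbind(M[1, , drop = FALSE], M, M[nrow(M), , drop = FALSE])
    cbind(M2[, 1, drop = FALSE], M2, M2[, ncol(M2), drop = FALSE])
  }
  P <- pad(phi)
  H <- nrow(phi); W <- ncol(phi)
  ci <- 2:(H + 1); cj <- 2:(W + 1)
  px <- (P[ci, cj + 1] - P[ci, cj - 1]) / 2
  py <- (P[ci + 1, cj] - P[ci - 1, cj]) / 2
  pxx <- P[ci, cj + 1] - 2 * phi + P[ci, cj - 1]
  pyy <- P[ci + 1, cj] - 2 * phi + P[ci - 1, cj]
  pxy <- (P[ci + 1, cj + 1] - P[ci + 1, cj - 1] -
            P[ci - 1, cj + 1] + P[ci - 1, cj - 1]) / 4
  den <- (px^2 + py^2)^1.5 + 1e-8
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / den
}

new_levelset_state <- function(phi, params) {
  structure(list(phi = phi, g_a = NA_real_, g_b = NA_real_,
                 lambda_a = params$lambda_a, lambda_b = params$lambda_b,
                 g = params$g, rho = params$rho, dt = params$dt,
                 mu = params$mu, delta = params$delta, iter = 0L,
                 convention = "inside is {phi <= 0}"),
            class = "levelset_state")
}

#' One explicit Euler evolution step
#'
#' Refreshes the region means, then updates
#' \eqn{\phi \leftarrow \phi + \Delta t\, \delta_\epsilon(\phi)
#'   [\mu \kappa(\phi) + \lambda_a (P - g_a)^2 - \lambda_b (P - g_b)^2]}.
#' Under the inside-is-negative convention this expels pixels that fit the
#' inside mean poorly (their \eqn{\phi} grows positive) and draws in pixels
#' that fit it well. With \eqn{\mu = 0} every step can only lower the fitting
#' energy.
#'
#' @param state A `levelset_state` (from [segment_cv()]'s internals or
#'   built around a `phi` matrix via the unexported constructor).
#' @param image Numeric matrix, same dimensions as `state$phi`.
#' @return The advanced `levelset_state` (means refreshed, counter bumped).
#' @export
evolve_step <- function(state, image) {
  g <- region_means(image, state$phi)
  fit <- state$lambda_a * (image - g[["g_a"]])^2 -
    state$lambda_b * (image - g[["g_b"]])^2
  vel <- fit
  if (state$mu != 0) vel <- vel + state$mu * curvature(state$phi)
  d <- if (identical(state$delta, "sharp")) {
    (abs(state$phi) <= 2) * 1
  } else {
    delta_eps(state$phi, eps = 1)
  }
  state$phi <- state$phi + state$dt * d * vel
  state$g_a <- g[["g_a"]]
  state$g_b <- g[["g_b"]]
  state$iter <- state$iter + 1L
  state
}

default_cv_params <- function() {
  # tol_stable: with dt = 0.13 and amplitude g = 0.5 a pixel needs O(100)
  # steps to cross zero, so consecutive mask changes can be > 10 apart;
  # a 10-step patience would stop at the initialization.
  # max_iters: with dt = 0.13 and g = 0.5 zero crossings need O(100-1000)
  # steps; 500 truncates the evolution before the mask stabilizes
  list(rho = 0.5, g = 0.5, dt = 0.13, lambda_a = 1, lambda_b = 1,
       mu = 0, max_iters = 2000L, tol_stable = 100L, delta = "smooth")
}

#' Chan-Vese segmentation from a hot-spot probability map
#'
#' Binarizes the probability map at `rho` into the initial level-set field
#' (high-probability pixels inside), then evolves the field by explicit Euler
#' steps until the binary mask is unchanged for `tol_stable` consecutive
#' iterations or `max_iters` is reached. If the initial inside region is
#' empty, the field is re-initialized from a 3-pixel disk at the map's
#' maximum and the fallback is flagged in the diagnostics.
#'
#' @param image Numeric matrix, intensities in \[0, 1\].
#' @param prob_map Probability map with the image's dimensions.
#' @param params Optional list overriding any of: `rho` (0.5), `g` (0.5),
#'   `dt` (0.13), `lambda_a`/`lambda_b` (1), `mu` (0, length penalty off;
#'   set > 0 to suppress speckle on noisy images), `max_iters` (2000),
#'   `tol_stable` (100), `delta` (`"smooth"` or `"sharp"`).
#' @return A `cv_segmentation`: `mask` (integer 0/1, the final
#'   \eqn{\{\phi \le 0\}}), and `diagnostics` (energy trace, iterations,
#'   final `g_a`/`g_b`, fallback flag, parameters).
#' @export
segment_cv <- function(image, prob_map, params = list()) {
  assert_image(image)
  assert_same_dim(image, prob_map, c("image", "prob_map"))
  p <- utils::modifyList(default_cv_params(), params)
  phi <- initialize_phi(prob_map, rho = p$rho, g = p$g)
  fallback <- FALSE
  if (!any(phi <= 0)) {
    fallback <- TRUE
    phi <- matrix(p$g, nrow(image), ncol(image))
    peak <- which(prob_map == max(prob_map), arr.ind = TRUE)[1, ]
    rr <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
    cc <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
    phi[(rr - peak[1])^2 + (cc - peak[2])^2 <= 9] <- -p$g
  }
  state <- new_levelset_state(phi, p)
  energy <- numeric(0)
  stable <- 0L
  moved <- FALSE  # patience starts only after the first flip: the initial
                  # plateau crossing can take longer than the patience itself
  mask_prev <- state$phi <= 0
  for (it in seq_len(p$max_iters)) {
    if (all(mask_prev) || !any(mask_prev)) break  # partition collapsed
    energy <- c(energy, cv_energy(image, state$phi, p$lambda_a, p$lambda_b))
    state <- evolve_step(state, image)
    mask_now <- state$phi <= 0
    if (identical(mask_now, mask_prev)) {
      stable <- stable + 1L
      if (moved && stable >= p$tol_stable) { mask_prev <- mask_now; break }
    } else {
      moved <- TRUE
      stable <- 0L
    }
    mask_prev <- mask_now
  }
  structure(
    list(mask = matrix(as.integer(mask_prev), nrow(image), ncol(image)),
         diagnostics = list(energy_trace = energy, iterations = state$iter,
                            g_a = state$g_a, g_b = state$g_b,
                            fallback = fallback, params = p)),
    class = "cv_segmentation"
  )
}

#' @export
print.cv_segmentation <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<cv_segmentation> %d mask pixel(s) after %d iteration(s); g_a %.4g, g_b %.4g%s\n",
              sum(x$mask), d$iterations, d$g_a, d$g_b,
              if (d$fallback) " [fallback init]" else ""))
  invisible(x)
}
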