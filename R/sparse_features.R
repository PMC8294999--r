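#' Randomly extract square patches from an image
#'
#' Samples `n` patches of side `l` uniformly over all valid top-left
#' positions. Patches are returned flattened (row-major within the patch) as
#' rows of an `n x l^2` matrix together with their source positions.
#'
#' @param image Numeric matrix (grayscale intensities).
#' @param l Patch side in pixels.
#' @param n Number of patches to draw.
#' @param seed Integer seed.
#' @return A `patch_set`: list with `patches` (`n x l^2` matrix), `positions`
#'   (tibble of top-left `row`, `col`), and `l`.
#' @export
extract_patches <- function(image, l = 8L, n = 1000L, seed = 1L) {
  assert_image(image)
  check_scalar(l, "l", lower = 1, integerish = TRUE)
  check_scalar(n, "n", lower = 1, integerish = TRUE)
  if (l > min(dim(image))) {
    abort(sprintf("patch side l = %d exceeds the smallest image dimension (%d).",
                  l, min(dim(image))),
          class = "hotspotseg_size_error")
  }
  nr <- nrow(image) - l + 1L
  nc <- ncol(image) - l + 1L
  pos <- with_seed(seed, {
    idx <- sample.int(nr * nc, n, replace = TRUE)
    tibble::tibble(row = ((idx - 1L) %% nr) + 1L,
                   col = ((idx - 1L) %/% nr) + 1L)
  })
  patches <- patches_at(image, pos$row, pos$col, l)
  structure(list(patches = patches, positions = pos, l = as.integer(l)),
            class = "patch_set")
}

# Flatten the l x l windows with top-left corners (rows, cols) into a matrix,
# row-major within each patch.
patches_at <- function(image, rows, cols, l) {
  n <- length(rows)
  out <- matrix(0, n, l * l)
  offs <- expand.grid(dc = 0:(l - 1L), dr = 0:(l - 1L))  # row-major flatten
  for (k in seq_len(l * l)) {
    out[, k] <- image[cbind(rows + offs$dr[k], cols + offs$dc[k])]
  }
  out
}

center_patches <- function(patches) {
  patches - rowMeans(patches)
}

#' Sparse-coding objective
#'
#' The dictionary-learning objective
#' \deqn{\sum_i \|x_i - \sum_j c_{ij} \phi_j\|_2^2 + \lambda \sum_{ij} |c_{ij}|}
#' evaluated exactly on a patch matrix, dictionary and code matrix. Used both
#' by the learner and as an independent check of its trace.
#'
#' @param patches `n x d` matrix of patch rows.
#' @param dictionary `sc_dictionary` or a `d x m` atom matrix.
#' @param codes `n x m` code matrix.
#' @param lambda Sparsity weight.
#' @return The scalar objective value.
#' @export
sc_objective <- function(patches, dictionary, codes, lambda) {
  atoms <- if (inherits(dictionary, "sc_dictionary")) dictionary$atoms else dictionary
  sc_objective_cpp(patches, atoms, codes, lambda)
}

#' Learn a patch dictionary by alternating minimization
#'
#' Classical sparse dictionary learning: alternate (i) lasso coding of all
#' patches with the atoms fixed (coordinate descent with soft-thresholding)
#' and (ii) sequential single-atom updates with the codes fixed, each the
#' exact minimizer over the unit sphere (least-squares direction followed by
#' renormalization). Both half-steps can only lower the objective, so the
#' recorded trace is non-increasing by construction.
#'
#' Patches are mean-subtracted before learning when `center = TRUE`
#' (default), which removes the slowly varying MRI bias field and makes the
#' learned atoms contrast patterns.
#'
#' @param patches A `patch_set` from [extract_patches()] or an `n x d` matrix.
#' @param m Number of atoms.
#' @param lambda Sparsity weight (>= 0).
#' @param n_iters Maximum number of full alternations.
#' @param seed Seed for the atom initialization (random training patches).
#' @param center Mean-subtract each patch first.
#' @param tol Relative objective change below which alternation stops.
#' @return An `sc_dictionary`: `atoms` (`d x m`, unit columns), `lambda`,
#'   `l` (patch side if known), `codes` (final code matrix), `objective_trace`
#'   (value after every full alternation), `center`, `seed`.
#' @export
learn_dictionary <- function(patches, m = 64L, lambda = 0.1, n_iters = 30L,
                             seed = 1L, center = TRUE, tol = 1e-4) {
  l <- NULL
  if (inherits(patches, "patch_set")) {
    l <- patches$l
    patches <- patches$patches
  }
  if (!is.matrix(patches) || nrow(patches) < 1L) {
    abort("`patches` must be a non-empty patch matrix or patch_set.",
          class = "hotspotseg_input_error")
  }
  check_scalar(m, "m", lower = 1, integerish = TRUE)
  check_scalar(lambda, "lambda", lower = 0)
  check_scalar(n_iters, "n_iters", lower = 1, integerish = TRUE)
  X <- if (center) center_patches(patches) else patches
  n <- nrow(X); d <- ncol(X)

  atoms <- with_seed(seed, {
    A <- t(X[sample.int(n, m, replace = n < m), , drop = FALSE])
    A <- A + matrix(rnorm(length(A), 0, 1e-3), nrow(A), ncol(A))
    sweep(A, 2, pmax(sqrt(colSums(A^2)), 1e-12), "/")
  })

  C <- matrix(0, n, m)
  trace <- numeric(0)
  for (it in seq_len(n_iters)) {
    # (i) codes given atoms: warm-started lasso coordinate descent
    C <- encode_cd(X, atoms, C, lambda, max_sweeps = 200L, tol = 1e-8)
    # (ii) atoms given codes: per-atom exact unit-sphere update
    atoms <- update_atoms(X, atoms, C)
    obj <- sc_objective_cpp(X, atoms, C, lambda)
    trace <- c(trace, obj)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (prev <= 0 || abs(prev - obj) / max(prev, .Machine$double.eps) < tol) break
    }
  }
  structure(
    list(atoms = atoms, lambda = lambda, l = l, codes = C,
         objective_trace = trace, center = center, seed = as.integer(seed)),
    class = "sc_dictionary"
  )
}

# Sequential block-coordinate atom updates with the codes fixed. For atom j
# the residual-fit minimizer over the unit sphere is the normalized
# correlation R_j^T c_j; atoms with no active code are left unchanged.
update_atoms <- function(X, atoms, C) {
  R <- X - C %*% t(atoms)  # n x d residual
  for (j in seq_len(ncol(atoms))) {
    cj <- C[, j]
    if (all(cj == 0)) next
    R <- R + outer(cj, atoms[, j])        # remove atom j's contribution
    u <- drop(crossprod(R, cj))           # d-vector, direction of best fit
    nu <- sqrt(sum(u^2))
    if (nu > 1e-12) atoms[, j] <- u / nu
    R <- R - outer(cj, atoms[, j])
  }
  atoms
}

#' @export
print.sc_dictionary <- function(x, ...) {
  cat(sprintf("<sc_dictionary> %d atoms of length %d, lambda %.3g, %d alternation(s), final objective %.6g\n",
              ncol(x$atoms), nrow(x$atoms), x$lambda,
              length(x$objective_trace),
              if (length(x$objective_trace)) utils::tail(x$objective_trace, 1) else NA))
  invisible(x)
}

#' Sparse-code patches against a fixed dictionary
#'
#' Solves, independently for each patch row,
#' \deqn{\min_c \|x - \Phi c\|_2^2 + \lambda \|c\|_1}
#' by cyclic coordinate descent with soft-thresholding (the dictionary is held
#' fixed). Converges to within `1e-6` on the objective for the default
#' controls.
#'
#' @param patches A `patch_set` or an `n x d` matrix (rows are patches).
#' @param dictionary An `sc_dictionary` (or a bare `d x m` atom matrix).
#' @param lambda Sparsity weight; defaults to the dictionary's.
#' @return The `n x m` code matrix.
#' @export
encode <- function(patches, dictionary, lambda = NULL) {
  if (inherits(patches, "patch_set")) patches <- patches$patches
  if (is.numeric(patches) && !is.matrix(patches)) patches <- matrix(patches, nrow = 1)
  atoms <- if (inherits(dictionary, "sc_dictionary")) dictionary$atoms else dictionary
  if (is.null(lambda)) {
    lambda <- if (inherits(dictionary, "sc_dictionary")) dictionary$lambda else 0
  }
  if (ncol(patches) != nrow(atoms)) {
    abort(sprintf("patch length (%d) does not match atom length (%d).",
                  ncol(patches), nrow(atoms)),
          class = "hotspotseg_size_error")
  }
  encode_cd(patches, atoms, matrix(0, nrow(patches), ncol(atoms)),
            lambda, max_sweeps = 1000L, tol = 1e-10)
}

#' Pooled sparse-code feature vector for a whole image
#'
#' Encodes every patch on a stride grid (patches mean-subtracted when the
#' dictionary was trained that way), then pools the absolute codes per atom by
#' max and by mean and concatenates: a length-`2m` image descriptor. The
#' max-pool half responds to the strongest local activation (a focal lesion),
#' the mean-pool half to global texture.
#'
#' @param image Numeric matrix.
#' @param dictionary An `sc_dictionary`.
#' @param l Patch side; defaults to the dictionary's.
#' @param stride Grid stride in pixels (>= 1).
#' @return Numeric vector of length `2m`: `c(maxpool, meanpool)`.
#' @export
image_feature <- function(image, dictionary, l = NULL, stride = 4L) {
  assert_image(image)
  if (is.null(l)) l <- dictionary$l
  if (is.null(l)) {
    l <- as.integer(round(sqrt(nrow(dictionary$atoms))))
  }
  check_scalar(stride, "stride", lower = 1, integerish = TRUE)
  if (l > min(dim(image))) {
    abort(sprintf("patch side l = %d exceeds the smallest image dimension (%d).",
                  l, min(dim(image))),
          class = "hotspotseg_size_error")
  }
  pos <- stride_grid(dim(image), l, stride)
  P <- patches_at(image, pos$row, pos$col, l)
  if (isTRUE(dictionary$center)) P <- center_patches(P)
  C <- abs(encode(P, dictionary))
  c(apply(C, 2, max), colMeans(C))
}

# Top-left positions of an l x l sliding window on a stride grid, always
# including the last valid row/column so the whole image is covered.
stride_grid <- function(dims, l, stride) {
  last_r <- dims[1] - l + 1L
  last_c <- dims[2] - l + 1L
  rows <- unique(c(seq(1L, last_r, by = stride), last_r))
  cols <- unique(c(seq(1L, last_c, by = stride), last_c))
  expand.grid(row = rows, col = cols)
}
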