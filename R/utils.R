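# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "hotspotseg_spec_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)  # x first: keeps dim

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg),
          class = "hotspotseg_input_error")
  }
  if (any(!is.finite(image))) {
    abort(sprintf("`%s` contains non-finite values.", arg),
          class = "hotspotseg_input_error")
  }
  invisible(image)
}

assert_same_dim <- function(a, b, what = c("mask", "mask")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s dimensions (%s) differ from %s dimensions (%s).",
                  what[1], paste(dim(a), collapse = "x"),
                  what[2], paste(dim(b), collapse = "x")),
          class = "hotspotseg_size_error")
  }
  invisible(TRUE)
}

# Positive scalar / count checks used by the public constructors.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper &&
    (!integerish || x == round(x))
  if (!ok) {
    abort(sprintf("`%s` must be a %s in %s%s, %s%s.",
                  name,
                  if (integerish) "whole number" else "number",
                  if (strict_lower) "(" else "[", lower, upper, "]"),
          class = "hotspotseg_spec_error")
  }
  invisible(x)
}
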