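# Image, mask and configuration I/O. Grayscale PNG (8-bit, via the png
# package) and plain-text CSV matrices are supported; MRI intensities carry
# no absolute scale, so images are min-max rescaled to [0, 1] on read with
# the original range kept as an attribute.

#' Read a grayscale image
#'
#' Reads PNG (any channel layout; multi-channel images are averaged to
#' grayscale) or a headerless CSV matrix, and min-max rescales intensities to
#' \[0, 1\]. A constant image cannot be rescaled: it is returned as all zeros
#' with a warning. The pre-rescale range is attached as attribute `range`.
#'
#' @param path File path ending in `.png` or `.csv`.
#' @return Numeric matrix in \[0, 1\] with attribute `range`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "hotspotseg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw_img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
      a
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    abort(sprintf("unrecognized image format \"%s\" for %s (use .png or .csv).",
                  ext, path), class = "hotspotseg_io_error")
  )
  storage.mode(raw_img) <- "double"
  if (any(!is.finite(raw_img))) {
    abort(sprintf("corrupt image (non-finite values): %s", path),
          class = "hotspotseg_io_error")
  }
  rng <- range(raw_img)
  out <- if (rng[2] > rng[1]) {
    (raw_img - rng[1]) / (rng[2] - rng[1])
  } else {
    warn(sprintf("constant image %s: rescaling degenerate, returning zeros.", path))
    matrix(0, nrow(raw_img), ncol(raw_img))
  }
  dimnames(out) <- NULL
  attr(out, "range") <- rng
  out
}

#' Write a grayscale image or probability map
#'
#' `.png` writes 8-bit grayscale (values clipped to \[0, 1\]); `.csv` writes
#' the exact values as plain text (the lossless route for probability maps).
#'
#' @param image Numeric matrix.
#' @param path Output path ending in `.png` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(clip01(unclass(image)[, , drop = FALSE]), path)
  } else if (ext == "csv") {
    utils::write.table(unclass(image), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    abort(sprintf("unrecognized image format \"%s\" (use .png or .csv).", ext),
          class = "hotspotseg_io_error")
  }
  invisible(path)
}

#' Write / read a binary mask
#'
#' Masks are stored as 8-bit PNG with values \{0, 255\} (or exact CSV 0/1)
#' and round-trip exactly.
#'
#' @param mask Integer/logical 0-1 matrix.
#' @param path Path ending in `.png` or `.csv`.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns an
#'   integer 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    abort(sprintf("unrecognized mask format \"%s\" (use .png or .csv).", ext),
          class = "hotspotseg_io_error")
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    abort(sprintf("unrecognized mask format \"%s\" (use .png or .csv).", ext),
          class = "hotspotseg_io_error")
  )
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  out
}

# Allowed configuration keys, default values and validation ranges.
config_schema <- function() {
  list(
    l            = list(default = 8L,    lower = 2,    upper = 64,  int = TRUE),
    m            = list(default = 64L,   lower = 1,    upper = 4096, int = TRUE),
    lambda       = list(default = 0.1,   lower = 0,    upper = Inf),
    adaboost_T   = list(default = 100L,  lower = 1,    upper = 1e4, int = TRUE),
    theta        = list(default = NA,    lower = 0,    upper = Inf),
    mil_T        = list(default = 30L,   lower = 1,    upper = 1e4, int = TRUE),
    bag_rule     = list(default = "noisy-or", choices = c("noisy-or", "max")),
    per_bag      = list(default = 50L,   lower = 1,    upper = 1e4, int = TRUE),
    stride       = list(default = 2L,    lower = 1,    upper = 64,  int = TRUE),
    feature_stride = list(default = 4L,  lower = 1,    upper = 64,  int = TRUE),
    rho          = list(default = 0.5,   lower = 1e-6, upper = 1 - 1e-6),
    g            = list(default = 0.5,   lower = 1e-6, upper = Inf),
    dt           = list(default = 0.13,  lower = 1e-6, upper = Inf),
    lambda_a     = list(default = 1,     lower = 1e-9, upper = Inf),
    lambda_b     = list(default = 1,     lower = 1e-9, upper = Inf),
    # length penalty: 0 is the literal fitting-only evolution; the pipeline
    # default 0.05 suppresses speckle from sensor noise (vignette, sec.
    # "numerical choices")
    mu           = list(default = 0.05,  lower = 0,    upper = Inf),
    max_iters    = list(default = 2000L, lower = 1,    upper = 1e6, int = TRUE),
    rg_tau       = list(default = 0.15,  lower = 0,    upper = 1),
    seed         = list(default = 1L,    lower = 0,    upper = 2^31 - 1, int = TRUE),
    out_dir      = list(default = NULL, path = TRUE),
    segment_level_II = list(default = TRUE, flag = TRUE)
  )
}

#' Pipeline configuration
#'
#' `pipeline_config()` builds a validated configuration from defaults plus
#' overrides; `read_config()` reads one from a YAML file with strict schema
#' validation (unknown keys are rejected, every numeric field is
#' range-checked).
#'
#' Fields: `l` (patch/window side, 8), `m` (dictionary atoms, 64), `lambda`
#' (sparse weight, 0.1), `adaboost_T` (100), `theta` (uncertain band;
#' calibrated when `NA`), `mil_T` (30), `bag_rule` (`"noisy-or"`),
#' `per_bag` (10), `stride` (MIL scan stride, 2), `feature_stride` (image
#' feature grid, 4), `rho` (0.5), `g` (0.5), `dt` (0.13), `lambda_a`,
#' `lambda_b` (1), `mu` (0), `max_iters` (500), `rg_tau` (region-growing
#' tolerance, 0.15), `seed`, `out_dir`, `segment_level_II` (TRUE: level-II
#' images proceed to scanning/segmentation as "suspicious").
#'
#' @param ... Named overrides of the fields above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  schema <- config_schema()
  unknown <- setdiff(names(overrides), names(schema))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "hotspotseg_config_error")
  }
  cfg <- lapply(schema, `[[`, "default")
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  for (k in names(schema)) {
    s <- schema[[k]]
    v <- cfg[[k]]
    if (isTRUE(s$path) || is.null(v)) next
    if (isTRUE(s$flag)) {
      if (!is.logical(v) || length(v) != 1L || is.na(v)) {
        abort(sprintf("`%s` must be TRUE or FALSE.", k),
              class = "hotspotseg_config_error")
      }
      next
    }
    if (!is.null(s$choices)) {
      if (!is.character(v) || length(v) != 1L || !v %in% s$choices) {
        abort(sprintf("`%s` must be one of: %s.", k,
                      paste(s$choices, collapse = ", ")),
              class = "hotspotseg_config_error")
      }
      next
    }
    if (length(v) == 1L && is.na(v)) next  # theta: calibrate later
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      v >= s$lower && v <= s$upper && (!isTRUE(s$int) || v == round(v))
    if (!ok) {
      abort(sprintf("configuration value `%s` out of range [%g, %g]%s.",
                    k, s$lower, s$upper,
                    if (isTRUE(s$int)) " (integer required)" else ""),
            class = "hotspotseg_config_error")
    }
    if (isTRUE(s$int)) cfg[[k]] <- as.integer(v)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration file not found: %s", path),
          class = "hotspotseg_config_error")
  }
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) {
    abort(sprintf("configuration file %s is not a YAML mapping.", path),
          class = "hotspotseg_config_error")
  }
  do.call(pipeline_config, vals)
}

#' Write the resolved configuration next to run outputs (provenance copy).
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  vals <- lapply(vals, function(v) if (length(v) == 1L && is.na(v)) NULL else v)
  yaml::write_yaml(vals[!vapply(vals, is.null, logical(1))], path)
  invisible(path)
}
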