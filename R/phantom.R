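#' Specify a synthetic spine-slice phantom
#'
#' Describes the synthetic 2-D "spine MRI" world used throughout the package:
#' a banded vertebra/disc background with a smooth bias field, zero or more
#' bright elliptical hot spots (metastatic lesions), and additive Gaussian
#' noise clipped to \[0, 1\]. Phantoms stand in for clinical slices, which are
#' not publicly available, and come with exact ground-truth masks.
#'
#' @param height,width Image size in pixels.
#' @param n_hotspots Number of planted hot spots (0 for a lesion-free slice).
#' @param hotspot_radius_range Length-2 numeric, min and max lesion radius in
#'   pixels.
#' @param hotspot_contrast Intensity offset of a lesion over its local
#'   background, on the \[0, 1\] intensity scale.
#' @param background_bands Number of vertebra/disc-like horizontal bands.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param ambiguous If `TRUE`, lesions are rendered at a contrast just above
#'   the noise floor (`2 * noise_sigma`), producing the genuinely uncertain
#'   "level II" appearance.
#'
#' @return A `phantom_spec` object (a validated list).
#' @examples
#' spec <- phantom_spec(height = 64, width = 64, n_hotspots = 2)
#' case <- generate_phantom(spec, seed = 1)
#' range(case$image)
#' @export
phantom_spec <- function(height = 256, width = 256,
                         n_hotspots = 3,
                         hotspot_radius_range = c(5, 12),
                         hotspot_contrast = 0.35,
                         background_bands = 4,
                         noise_sigma = 0.05,
                         ambiguous = FALSE) {
  check_scalar(height, "height", lower = 8, integerish = TRUE)
  check_scalar(width, "width", lower = 8, integerish = TRUE)
  check_scalar(n_hotspots, "n_hotspots", lower = 0, integerish = TRUE)
  if (!is.numeric(hotspot_radius_range) || length(hotspot_radius_range) != 2L ||
      any(!is.finite(hotspot_radius_range)) || hotspot_radius_range[1] <= 0 ||
      hotspot_radius_range[1] > hotspot_radius_range[2]) {
    abort("`hotspot_radius_range` must be (min, max) with 0 < min <= max.",
          class = "hotspotseg_spec_error")
  }
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  check_scalar(background_bands, "background_bands", lower = 1,
               integerish = TRUE)
  check_scalar(hotspot_contrast, "hotspot_contrast", lower = 0, upper = 1)
  if (n_hotspots > 0 && hotspot_contrast <= 0) {
    abort("`hotspot_contrast` must be > 0 when `n_hotspots` > 0.",
          class = "hotspotseg_spec_error")
  }
  if (!is.logical(ambiguous) || length(ambiguous) != 1L || is.na(ambiguous)) {
    abort("`ambiguous` must be TRUE or FALSE.",
          class = "hotspotseg_spec_error")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_hotspots = as.integer(n_hotspots),
         hotspot_radius_range = as.numeric(hotspot_radius_range),
         hotspot_contrast = as.numeric(hotspot_contrast),
         background_bands = as.integer(background_bands),
         noise_sigma = as.numeric(noise_sigma),
         ambiguous = isTRUE(ambiguous)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d, %d hot spot(s) r in [%g, %g] contrast %.3g%s, %d bands, noise sigma %.3g\n",
    x$height, x$width, x$n_hotspots,
    x$hotspot_radius_range[1], x$hotspot_radius_range[2],
    x$hotspot_contrast, if (x$ambiguous) " (ambiguous)" else "",
    x$background_bands, x$noise_sigma))
  invisible(x)
}

# Banded background plus a smooth bias field, deterministic given the RNG
# state. Bands run horizontally (vertebral bodies alternate with discs along
# the cranio-caudal axis of a sagittal slice).
phantom_background <- function(height, width, n_bands) {
  rows <- seq_len(height)
  cols <- seq_len(width)
  phase <- runif(1, 0, 2 * pi)
  band <- 0.08 * sin(2 * pi * n_bands * rows / height + phase)
  # low-frequency bias field: tilted plane + one broad bump
  cx <- runif(1, 0.3, 0.7) * width
  cy <- runif(1, 0.3, 0.7) * height
  gx <- runif(1, -1, 1); gy <- runif(1, -1, 1)
  plane <- outer(rows / height - 0.5, cols / width - 0.5,
                 function(r, c) gy * r + gx * c) * 0.04
  bump <- 0.04 * exp(-(outer((rows - cy)^2, (cols - cx)^2, "+")) /
                       (2 * (0.6 * max(height, width))^2))
  0.35 + matrix(band, height, width) + plane + bump
}

# Sample non-overlapping ellipse parameters; falls back to accepting overlap
# after 200 rejected draws so pathological specs still terminate.
sample_hotspots <- function(spec) {
  n <- spec$n_hotspots
  if (n == 0L) return(NULL)
  rmin <- spec$hotspot_radius_range[1]
  rmax <- spec$hotspot_radius_range[2]
  out <- vector("list", n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    r1 <- runif(1, rmin, rmax)
    r2 <- runif(1, rmin, rmax)
    margin <- max(r1, r2) + 2
    if (spec$height - 2 * margin < 1 || spec$width - 2 * margin < 1) {
      abort("hotspot radius too large for the image size (`hotspot_radius_range`).",
            class = "hotspotseg_spec_error")
    }
    cy <- runif(1, margin, spec$height - margin)
    cx <- runif(1, margin, spec$width - margin)
    theta <- runif(1, 0, pi)
    ok <- TRUE
    if (placed > 0L && tries < 200L) {
      for (h in out[seq_len(placed)]) {
        sep <- sqrt((cy - h$cy)^2 + (cx - h$cx)^2)
        if (sep < (max(r1, r2) + max(h$r1, h$r2) + 3)) { ok <- FALSE; break }
      }
    }
    tries <- tries + 1L
    if (ok) {
      placed <- placed + 1L
      out[[placed]] <- list(cy = cy, cx = cx, r1 = r1, r2 = r2, theta = theta)
    }
  }
  out
}

hotspot_mask_matrix <- function(height, width, hotspots) {
  mask <- matrix(0L, height, width)
  if (is.null(hotspots)) return(mask)
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  for (h in hotspots) {
    dy <- rows - h$cy
    dx <- cols - h$cx
    u <- dy * cos(h$theta) + dx * sin(h$theta)
    v <- -dy * sin(h$theta) + dx * cos(h$theta)
    mask[(u / h$r1)^2 + (v / h$r2)^2 <= 1] <- 1L
  }
  mask
}

#' Generate one synthetic spine slice with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: banded background,
#' bright elliptical hot spots, Gaussian noise clipped to \[0, 1\]. The
#' ground-truth mask is the exact union of the planted ellipses, and the gold
#' three-level label follows the lesion construction: level `"I"` (certain hot
#' spot) for ordinary lesions, `"II"` (uncertain) for ambiguous low-contrast
#' lesions, `"III"` (no hot spot) for lesion-free slices.
#'
#' Identical `(spec, seed)` pairs give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed controlling every random draw.
#' @return A `phantom_case` list: `image` (numeric matrix in \[0, 1\]),
#'   `mask` (integer 0/1 matrix), `gold_label` (`"I"`, `"II"` or `"III"`),
#'   `seed`.
#' @export
generate_phantom <- function(spec, seed) {
  if (!inherits(spec, "phantom_spec")) {
    abort("`spec` must be a `phantom_spec` object.",
          class = "hotspotseg_spec_error")
  }
  with_seed(seed, {
    bg <- phantom_background(spec$height, spec$width, spec$background_bands)
    hotspots <- sample_hotspots(spec)
    mask <- hotspot_mask_matrix(spec$height, spec$width, hotspots)
    contrast <- if (spec$ambiguous) {
      # just above the noise floor: triage confidence is genuinely low
      min(spec$hotspot_contrast, 2 * spec$noise_sigma)
    } else {
      spec$hotspot_contrast
    }
    image <- bg + contrast * mask
    if (spec$noise_sigma > 0) {
      image <- image + matrix(rnorm(length(image), 0, spec$noise_sigma),
                              nrow(image), ncol(image))
    }
    image <- clip01(image)
    label <- if (spec$n_hotspots == 0L) "III" else if (spec$ambiguous) "II" else "I"
    structure(
      list(image = image, mask = mask, gold_label = label,
           seed = as.integer(seed), spec = spec),
      class = "phantom_case"
    )
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %dx%d, gold level %s, %d mask pixel(s), seed %d\n",
              nrow(x$image), ncol(x$image), x$gold_label,
              sum(x$mask), x$seed))
  invisible(x)
}

#' Generate a labelled phantom cohort
#'
#' Builds a cohort mirroring the three-level reading of a radiologist panel:
#' `n_I` slices with certain hot spots, `n_II` ambiguous low-contrast slices,
#' and `n_III` lesion-free slices. The clinical study this emulates read 87
#' slices as 45 level-I, 19 level-II and 23 level-III, which is the default.
#'
#' @param counts_by_level Integer vector `c(nI, nII, nIII)`.
#' @param base_spec The [phantom_spec()] used for level-I cases; level II uses
#'   its `ambiguous` variant, level III its `n_hotspots = 0` variant.
#' @param seed Integer master seed; each case receives its own sub-seed.
#' @return A tibble with one row per case: `case_id`, `gold_label`, `seed`,
#'   and a `case` list-column of `phantom_case` objects.
#' @examples
#' cohort <- generate_cohort(c(2, 1, 1), phantom_spec(height = 64, width = 64),
#'                           seed = 7)
#' table(cohort$gold_label)
#' @export
generate_cohort <- function(counts_by_level = c(45L, 19L, 23L),
                            base_spec = phantom_spec(),
                            seed = 1L) {
  if (!is.numeric(counts_by_level) || length(counts_by_level) != 3L ||
      any(counts_by_level < 0) || any(counts_by_level != round(counts_by_level))) {
    abort("`counts_by_level` must be three non-negative integers (nI, nII, nIII).",
          class = "hotspotseg_spec_error")
  }
  counts <- as.integer(counts_by_level)
  spec_I <- base_spec
  spec_I$ambiguous <- FALSE
  spec_II <- base_spec
  spec_II$ambiguous <- TRUE
  if (spec_II$n_hotspots == 0L) spec_II$n_hotspots <- max(1L, base_spec$n_hotspots)
  spec_III <- base_spec
  spec_III$n_hotspots <- 0L
  spec_III$ambiguous <- FALSE

  levels_vec <- rep(c("I", "II", "III"), counts)
  n <- length(levels_vec)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  cases <- purrr::map2(levels_vec, case_seeds, function(lv, s) {
    sp <- switch(lv, I = spec_I, II = spec_II, III = spec_III)
    generate_phantom(sp, s)
  })
  tibble::tibble(
    case_id = sprintf("case_%03d", seq_len(n)),
    gold_label = levels_vec,
    seed = case_seeds,
    case = cases
  )
}

#' Write a phantom cohort to disk
#'
#' Writes each image as grayscale PNG, each non-empty mask as an 8-bit
#' \{0, 255\} PNG, and a `manifest.csv` (`case_id`, `image_path`, `mask_path`,
#' `gold_label`, `seed`).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::pmap_dfr(
    cohort[c("case_id", "gold_label", "seed", "case")],
    function(case_id, gold_label, seed, case) {
      image_path <- file.path(dir, paste0(case_id, "_image.png"))
      write_image(case$image, image_path)
      mask_path <- ""
      if (sum(case$mask) > 0) {
        mask_path <- file.path(dir, paste0(case_id, "_mask.png"))
        write_mask(case$mask, mask_path)
      }
      tibble::tibble(case_id = case_id, image_path = image_path,
                     mask_path = mask_path, gold_label = gold_label,
                     seed = seed)
    })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
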