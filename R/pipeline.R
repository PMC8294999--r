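# End-to-end cascade: sparse features -> AdaBoost triage -> MIL scan ->
# Chan-Vese segmentation, with level III halting the flow.

#' Train all models of the cascade on a phantom cohort
#'
#' Fits, in order: the sparse-coding dictionary on patches pooled from the
#' training images; the AdaBoost triage classifier on pooled image features
#' (+1 for gold I/II, -1 for III) with the uncertain band `theta` calibrated
#' on held-out cases when not supplied; and the MILBoost instance classifier
#' on one bag per training image.
#'
#' @param cohort Training cohort tibble from [generate_cohort()].
#' @param config A [pipeline_config()].
#' @param holdout Fraction of the cohort reserved for `theta` calibration
#'   when `config$theta` is `NA` (default 0.25).
#' @param n_patches Patches pooled for dictionary learning.
#' @param dict_iters Dictionary-learning alternations.
#' @return A `hotspot_models` list: `dictionary`, `adaboost`, `mil`,
#'   `mil_loss_trace`, `config`.
#' @export
train_pipeline <- function(cohort, config = pipeline_config(),
                           holdout = 0.25, n_patches = 10000L,
                           dict_iters = 15L) {
  cases <- cohort$case
  n <- length(cases)
  seeds <- with_seed(config$seed, sample.int(2^31 - 2, 4))

  # pool random patches across training images
  per_img <- ceiling(n_patches / n)
  patch_mats <- purrr::imap(cases, function(cs, i) {
    ps <- extract_patches(cs$image, l = config$l, n = per_img,
                          seed = seeds[1] + i)
    ps$patches
  })
  patches <- do.call(rbind, patch_mats)[seq_len(min(n_patches, per_img * n)), ,
                                        drop = FALSE]
  dict <- learn_dictionary(patches, m = config$m, lambda = config$lambda,
                           n_iters = dict_iters, seed = seeds[2])
  dict$l <- config$l

  feats <- t(vapply(cases, function(cs) {
    image_feature(cs$image, dict, l = config$l, stride = config$feature_stride)
  }, numeric(2L * config$m)))
  y <- ifelse(cohort$gold_label %in% c("I", "II"), 1, -1)

  theta_known <- !is.null(config$theta) && !is.na(config$theta)
  idx_hold <- integer(0)
  if (!theta_known) {
    idx_hold <- with_seed(seeds[3], {
      h <- sort(sample.int(n, max(2L, round(holdout * n))))
      # keep both classes in the training part
      while (length(unique(y[-h])) < 2L && length(h) > 2L) h <- h[-1]
      h
    })
  }
  idx_train <- setdiff(seq_len(n), idx_hold)
  ada <- train_adaboost(feats[idx_train, , drop = FALSE], y[idx_train],
                        T = config$adaboost_T, seed = seeds[3])
  ada <- if (theta_known) {
    ada$theta <- config$theta
    ada
  } else {
    calibrate_theta(ada, feats[idx_hold, , drop = FALSE])
  }

  bags <- make_bags(cases, dict, l = config$l, per_bag = config$per_bag,
                    seed = seeds[4])
  milfit <- train_milboost(bags, T = config$mil_T, seed = seeds[4],
                           rule = config$bag_rule)
  structure(list(dictionary = dict, adaboost = ada, mil = milfit$model,
                 mil_loss_trace = milfit$loss_trace, config = config),
            class = "hotspot_models")
}

#' @export
print.hotspot_models <- function(x, ...) {
  cat("<hotspot_models>\n  ")
  print(x$dictionary)
  cat("  ")
  print(x$adaboost)
  cat("  ")
  print(x$mil)
  invisible(x)
}

#' Run the detection/segmentation cascade on one image
#'
#' Computes the pooled sparse-code feature, applies the three-level triage
#' rule, and: for level III (no hot spot) halts — no probability map and no
#' mask are produced; for levels I and II (certain/suspicious) scans the
#' image into a hot-spot probability map and segments it with the Chan-Vese
#' level set. With `config$segment_level_II = FALSE` level II also halts.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param models A `hotspot_models` from [train_pipeline()].
#' @param config Optional [pipeline_config()] override; defaults to the one
#'   the models were trained with.
#' @return A `pipeline_result`: `triage` (level), `margin`, `prob_map`
#'   (`NULL` when halted), `mask` (`NULL` when halted), `diagnostics`.
#' @export
run_pipeline <- function(image, models, config = NULL) {
  if (!inherits(models, "hotspot_models")) {
    abort("`models` must come from train_pipeline().",
          class = "hotspotseg_config_error")
  }
  config <- config %||% models$config
  assert_image(image)
  fv <- image_feature(image, models$dictionary, l = config$l,
                      stride = config$feature_stride)
  mg <- margin(models$adaboost, fv)
  level <- classify_three_level(models$adaboost, fv)
  halted <- level == "III" ||
    (level == "II" && !isTRUE(config$segment_level_II))
  prob_map <- NULL
  mask <- NULL
  diagnostics <- list(margin = mg, theta = models$adaboost$theta)
  if (!halted) {
    prob_map <- scan_probability_map(models$mil, image, models$dictionary,
                                     l = config$l, stride = config$stride)
    seg <- segment_cv(image, prob_map,
                      params = list(rho = config$rho, g = config$g,
                                    dt = config$dt,
                                    lambda_a = config$lambda_a,
                                    lambda_b = config$lambda_b,
                                    mu = config$mu,
                                    max_iters = config$max_iters))
    mask <- seg$mask
    diagnostics <- c(diagnostics, seg$diagnostics)
  }
  structure(list(triage = level, margin = mg, prob_map = prob_map,
                 mask = mask, halted = halted, diagnostics = diagnostics),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> triage level %s (margin %.3g)%s\n",
              x$triage, x$margin,
              if (x$halted) "; halted, no segmentation" else
                sprintf("; mask with %d pixel(s)", sum(x$mask))))
  invisible(x)
}

#' Run the cascade over a cohort and write artifacts
#'
#' Applies [run_pipeline()] to every case, optionally writing the
#' probability map, mask and a JSON diagnostics file per case plus a
#' resolved-configuration provenance copy.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param models A `hotspot_models`.
#' @param config Optional configuration override.
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @return A tibble: `case_id`, `gold_label`, `triage`, `margin`, `halted`,
#'   `prob_map_path`, `mask_path`, and a `result` list-column.
#' @export
run_cohort <- function(cohort, models, config = NULL, out_dir = NULL) {
  config <- config %||% models$config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "resolved_config.yaml"))
  }
  purrr::pmap_dfr(cohort[c("case_id", "gold_label", "case")],
                  function(case_id, gold_label, case) {
    res <- run_pipeline(case$image, models, config)
    pm_path <- ""
    mk_path <- ""
    if (!is.null(out_dir) && !res$halted) {
      pm_path <- file.path(out_dir, paste0(case_id, "_probmap.csv"))
      write_image(unclass(res$prob_map), pm_path)
      mk_path <- file.path(out_dir, paste0(case_id, "_mask.png"))
      write_mask(res$mask, mk_path)
    }
    tibble::tibble(case_id = case_id, gold_label = gold_label,
                   triage = res$triage, margin = res$margin,
                   halted = res$halted, prob_map_path = pm_path,
                   mask_path = mk_path, result = list(res))
  })
}

#' Segment one image with all three methods from a shared probability map
#'
#' Gives every segmenter the same detection input: the Chan-Vese route uses
#' the probability map as its initialization, region growing is seeded at the
#' map's local maxima above `rho`, and Otsu thresholding is restricted to the
#' dilated bounding box of the map's support (use `otsu_whole_image = TRUE`
#' for the global-histogram variant).
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param prob_map Hot-spot probability map with the image's dimensions.
#' @param config A [pipeline_config()].
#' @param otsu_whole_image Use the whole-image histogram for Otsu.
#' @return Named list of masks: `cv`, `region_growing`, `otsu`.
#' @export
segment_all_methods <- function(image, prob_map, config = pipeline_config(),
                                otsu_whole_image = FALSE) {
  seg <- segment_cv(image, prob_map,
                    params = list(rho = config$rho, g = config$g,
                                  dt = config$dt, lambda_a = config$lambda_a,
                                  lambda_b = config$lambda_b, mu = config$mu,
                                  max_iters = config$max_iters))
  seeds <- probmap_seeds(prob_map, rho = config$rho, image = image)
  rg <- if (nrow(seeds)) {
    region_grow(image, seeds, tau = config$rg_tau)
  } else {
    matrix(0L, nrow(image), ncol(image))
  }
  roi <- if (otsu_whole_image) NULL else probmap_roi(prob_map, rho = config$rho)
  ot <- tryCatch(otsu_segment(image, roi = roi)$mask,
                 hotspotseg_degenerate_error = function(e) {
                   matrix(0L, nrow(image), ncol(image))
                 })
  list(cv = seg$mask, region_growing = rg, otsu = ot)
}
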