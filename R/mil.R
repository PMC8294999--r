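#' Build multi-instance bags from phantom cases
#'
#' One bag per image. A positive bag (image with a hot spot) draws at least
#' 30% of its instances from patch positions centered inside the ground-truth
#' mask and the rest anywhere; a negative bag draws only from lesion-free
#' images. Instances are sparse-code vectors of the mean-subtracted patches,
#' so only bag-level supervision is used downstream — instance positivity
#' never enters training.
#'
#' Instance feature vectors: the sparse code of the mean-subtracted patch
#' plus the raw patch mean as the last coordinate. The centered code carries
#' texture; the mean carries the absolute brightness that defines a hot
#' spot.
#'
#' @param cases List of `phantom_case` objects or a cohort tibble from
#'   [generate_cohort()].
#' @param dictionary An `sc_dictionary` used to encode instance patches.
#' @param l Patch side; defaults to the dictionary's.
#' @param per_bag Instances per bag.
#' @param seed Integer seed.
#' @return A tibble with one row per bag: `bag_id`, `label` (+1/-1), and
#'   `instances` (list-column of `per_bag x m` code matrices).
#' @export
make_bags <- function(cases, dictionary, l = NULL, per_bag = 50L, seed = 1L) {
  if (tibble::is_tibble(cases)) cases <- cases$case
  if (is.null(l)) l <- dictionary$l %||% as.integer(round(sqrt(nrow(dictionary$atoms))))
  check_scalar(per_bag, "per_bag", lower = 1, integerish = TRUE)
  labels <- vapply(cases, function(cs) if (sum(cs$mask) > 0) 1 else -1, numeric(1))
  if (!any(labels < 0)) {
    abort("no negative (lesion-free) images available to form negative bags.",
          class = "hotspotseg_construction_error")
  }
  if (!any(labels > 0)) {
    abort("no positive (lesioned) images available to form positive bags.",
          class = "hotspotseg_construction_error")
  }
  half <- (l - 1L) %/% 2L
  n_pos_min <- ceiling(0.3 * per_bag)
  bag_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(cases)))
  rows <- purrr::map2(cases, bag_seeds, function(cs, s) {
    img <- cs$image
    nr <- nrow(img) - l + 1L
    nc <- ncol(img) - l + 1L
    with_seed(s, {
      if (sum(cs$mask) > 0) {
        # centers inside the mask whose window fits in the image
        idx <- which(cs$mask == 1L, arr.ind = TRUE)
        ok <- idx[, 1] > half & idx[, 1] <= nrow(img) - (l - half - 1L) &
          idx[, 2] > half & idx[, 2] <= ncol(img) - (l - half - 1L)
        idx <- idx[ok, , drop = FALSE]
        if (nrow(idx) == 0L) {
          # mask hugs the border: clamp centers into the valid window range
          idx <- which(cs$mask == 1L, arr.ind = TRUE)
          idx[, 1] <- pmin(pmax(idx[, 1], half + 1L), nrow(img) - (l - half - 1L))
          idx[, 2] <- pmin(pmax(idx[, 2], half + 1L), ncol(img) - (l - half - 1L))
        }
        n_in <- min(per_bag, n_pos_min)
        pick <- idx[sample.int(nrow(idx), n_in, replace = nrow(idx) < n_in), ,
                    drop = FALSE]
        r_in <- pick[, 1] - half
        c_in <- pick[, 2] - half
        n_out <- per_bag - n_in
        r_out <- if (n_out > 0) sample.int(nr, n_out, replace = TRUE) else integer(0)
        c_out <- if (n_out > 0) sample.int(nc, n_out, replace = TRUE) else integer(0)
        rows_tl <- c(r_in, r_out)
        cols_tl <- c(c_in, c_out)
      } else {
        rows_tl <- sample.int(nr, per_bag, replace = TRUE)
        cols_tl <- sample.int(nc, per_bag, replace = TRUE)
      }
      instance_features(patches_at(img, rows_tl, cols_tl, l), dictionary)
    })
  })
  tibble::tibble(
    bag_id = seq_along(cases),
    label = labels,
    instances = rows
  )
}

# Instance representation shared by bag construction and scanning: the
# sparse code of the (optionally centered) patch with the raw patch mean
# appended as the last column.
instance_features <- function(P, dictionary) {
  mu <- rowMeans(P)
  if (isTRUE(dictionary$center)) P <- center_patches(P)
  cbind(encode(P, dictionary), mu, deparse.level = 0)
}

#' Bag-level probability from instance probabilities
#'
#' Aggregates per-instance hot-spot probabilities into the probability that
#' the bag is positive. `rule = "max"` is the literal bag classifier
#' \eqn{\max_l p_{jl}}; `rule = "noisy-or"` is the differentiable
#' \eqn{1 - \prod_l (1 - p_{jl})} used by default during boosting.
#'
#' @param instance_probs Numeric vector of probabilities in \[0, 1\].
#' @param rule `"noisy-or"` or `"max"`.
#' @return A single probability.
#' @export
bag_probability <- function(instance_probs, rule = c("noisy-or", "max")) {
  rule <- match.arg(rule)
  if (!length(instance_probs)) {
    abort("`instance_probs` must be non-empty.",
          class = "hotspotseg_input_error")
  }
  if (any(instance_probs < 0 | instance_probs > 1)) {
    abort("instance probabilities must lie in [0, 1].",
          class = "hotspotseg_input_error")
  }
  switch(rule,
         "max" = max(instance_probs),
         "noisy-or" = 1 - prod(1 - instance_probs))
}

#' Negative log-likelihood bag loss
#'
#' \deqn{\mathrm{Loss} = -\sum_j [\mathbf{1}(y_j = 1)\log p_j +
#'   \mathbf{1}(y_j = -1)\log(1 - p_j)]}
#' with probabilities clipped to \[1e-12, 1 - 1e-12\] before the logs.
#'
#' @param bag_probs Probabilities that each bag is positive.
#' @param labels Bag labels, +1/-1.
#' @return Non-negative scalar loss.
#' @export
mil_loss <- function(bag_probs, labels) {
  if (length(bag_probs) != length(labels)) {
    abort("`bag_probs` and `labels` lengths differ.",
          class = "hotspotseg_input_error")
  }
  p <- clip01(bag_probs, eps = 1e-12)
  -sum(ifelse(labels == 1, log(p), log(1 - p)))
}

# Instance scores under the current ensemble for a stacked instance matrix.
mil_scores <- function(model, X) {
  s <- numeric(nrow(X))
  for (t in seq_along(model$stumps)) {
    st <- model$stumps[[t]]
    h <- ifelse(X[, st$feature] > st$threshold, st$polarity, -st$polarity)
    s <- s + model$weights[t] * h
  }
  s
}

# Best decision stump maximizing sum(w * h(x)) over features, thresholds and
# polarity; w may be signed. Ties resolved toward the lowest feature index
# then lowest threshold (scan order).
fit_stump <- function(X, w) {
  best <- list(score = -Inf)
  for (f in seq_len(ncol(X))) {
    ord <- order(X[, f])
    xs <- X[ord, f]
    ws <- w[ord]
    total <- sum(ws)
    # h = +1 for x > thr: score(thr) = total - 2 * cumsum(w up to thr)
    cw <- cumsum(ws)
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    thr <- (xs[distinct] + xs[distinct + 1L]) / 2
    sc <- total - 2 * cw[distinct]  # score of h = +1{x > thr} with polarity +1
    k <- which.max(abs(sc))         # polarity flips the sign, so |sc| decides
    if (abs(sc[k]) > best$score + 1e-15) {
      best <- list(score = abs(sc[k]), feature = f, threshold = thr[k],
                   polarity = if (sc[k] >= 0) 1 else -1)
    }
  }
  if (!is.finite(best$score)) return(NULL)
  best
}

#' Train a MILBoost hot-spot instance classifier
#'
#' Gradient boosting under the bag-level negative-log-likelihood loss.
#' Instance probabilities use the logistic link \eqn{p = \sigma(m(x))} on the
#' additive instance score \eqn{m(x) = \sum_t \partial_t m_t(x)}. Each round
#' computes the per-instance weights \eqn{w_{jl} = -\partial\mathrm{Loss} /
#' \partial m(x_{jl})} under the chosen bag rule, fits a decision stump to the
#' weight signs with importance \eqn{|w_{jl}|}, and sets the stump weight by a
#' line search that minimizes the loss; a round that cannot lower the loss
#' stops training, so the recorded loss trace is non-increasing.
#'
#' @param bags Tibble from [make_bags()] (or list with `label`, `instances`).
#' @param T Number of boosting rounds.
#' @param seed Integer seed (training itself is deterministic).
#' @param rule Bag rule, `"noisy-or"` (default, differentiable) or `"max"`
#'   (literal, subgradient at the first argmax).
#' @return A list: `model` (`mil_model` with `stumps`, `weights`, `rule`) and
#'   `loss_trace` (loss after every accepted round, preceded by the initial
#'   loss).
#' @export
train_milboost <- function(bags, T = 30L, seed = 1L,
                           rule = c("noisy-or", "max")) {
  rule <- match.arg(rule)
  check_scalar(T, "T", lower = 1, integerish = TRUE)
  labels <- bags$label
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2L) {
    abort("bags must carry +1/-1 labels with both classes present.",
          class = "hotspotseg_training_error")
  }
  inst <- bags$instances
  X <- do.call(rbind, inst)
  bag_of <- rep(seq_along(inst), vapply(inst, nrow, integer(1)))

  model <- structure(list(stumps = list(), weights = numeric(0), rule = rule,
                          n_features = ncol(X), seed = as.integer(seed)),
                     class = "mil_model")
  s <- numeric(nrow(X))  # current instance scores m(x)

  bag_probs_from <- function(p_inst) {
    vapply(split(p_inst, bag_of), bag_probability, numeric(1), rule = rule)
  }
  loss_from_scores <- function(sc) {
    mil_loss(bag_probs_from(sigmoid(sc)), labels)
  }

  trace <- loss_from_scores(s)
  for (t in seq_len(T)) {
    p_inst <- sigmoid(s)
    p_bag <- bag_probs_from(p_inst)
    p_bag_c <- clip01(p_bag, eps = 1e-12)
    w <- numeric(nrow(X))
    for (j in seq_along(labels)) {
      idx <- which(bag_of == j)
      pj <- p_inst[idx]
      if (rule == "noisy-or") {
        if (labels[j] == 1) {
          w[idx] <- pj * (1 - p_bag_c[j]) / p_bag_c[j]
        } else {
          w[idx] <- -pj
        }
      } else {
        # subgradient: only the first argmax instance carries weight
        k <- idx[which.max(pj)]
        g <- pj[which.max(pj)] * (1 - pj[which.max(pj)])
        w[k] <- if (labels[j] == 1) g / p_bag_c[j] else -g / (1 - p_bag_c[j])
      }
    }
    st <- fit_stump(X, w)
    if (is.null(st)) break
    h <- ifelse(X[, st$feature] > st$threshold, st$polarity, -st$polarity)
    cur <- utils::tail(trace, 1)
    opt <- optimize(function(a) loss_from_scores(s + a * h),
                    interval = c(0, 3))
    if (opt$objective >= cur - 1e-12) break  # no descent possible: stop
    model$stumps[[length(model$stumps) + 1L]] <- st
    model$weights <- c(model$weights, opt$minimum)
    s <- s + opt$minimum * h
    trace <- c(trace, opt$objective)
  }
  list(model = model, loss_trace = trace)
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> %d stump(s), rule %s, %d feature(s)\n",
              length(x$stumps), x$rule, x$n_features))
  invisible(x)
}

#' @export
tidy.mil_model <- function(x, ...) {
  if (!length(x$stumps)) {
    return(tibble::tibble(round = integer(0), feature = integer(0),
                          threshold = numeric(0), polarity = numeric(0),
                          weight = numeric(0)))
  }
  tibble::tibble(
    round = seq_along(x$stumps),
    feature = vapply(x$stumps, `[[`, numeric(1), "feature"),
    threshold = vapply(x$stumps, `[[`, numeric(1), "threshold"),
    polarity = vapply(x$stumps, `[[`, numeric(1), "polarity"),
    weight = x$weights
  )
}

#' @export
glance.mil_model <- function(x, ...) {
  tibble::tibble(rounds = length(x$stumps), rule = x$rule,
                 n_features = x$n_features)
}

#' Predict bag probabilities with a MIL model
#'
#' @param object A `mil_model`.
#' @param bags Tibble from [make_bags()].
#' @param ... Unused.
#' @return Numeric vector, one probability per bag.
#' @export
predict.mil_model <- function(object, bags, ...) {
  vapply(bags$instances, function(Xb) {
    bag_probability(sigmoid(mil_scores(object, Xb)), rule = object$rule)
  }, numeric(1))
}

#' Sliding-window hot-spot probability map
#'
#' Scans the image with an `l x l` window on a stride grid (the last valid
#' row/column is always included), sparse-codes each window against the
#' dictionary, scores it with the MIL instance classifier, and maps the score
#' through the logistic link. Each pixel receives the mean probability of all
#' windows covering it, so the map has the image's dimensions and values in
#' \[0, 1\]. An empty ensemble gives the uninformative map 0.5.
#'
#' @param model A `mil_model`.
#' @param image Numeric matrix.
#' @param dictionary The `sc_dictionary` used at training time.
#' @param l Window side; defaults to the dictionary's patch side.
#' @param stride Scan stride in pixels.
#' @return A `prob_map`: numeric matrix in \[0, 1\] with attribute
#'   `stride`.
#' @export
scan_probability_map <- function(model, image, dictionary, l = NULL,
                                 stride = 2L) {
  assert_image(image)
  if (is.null(l)) l <- dictionary$l %||% as.integer(round(sqrt(nrow(dictionary$atoms))))
  check_scalar(stride, "stride", lower = 1, integerish = TRUE)
  if (l > min(dim(image))) {
    abort(sprintf("image (%s) smaller than the %dx%d scan window.",
                  paste(dim(image), collapse = "x"), l, l),
          class = "hotspotseg_size_error")
  }
  pos <- stride_grid(dim(image), l, stride)
  C <- instance_features(patches_at(image, pos$row, pos$col, l), dictionary)
  probs <- sigmoid(mil_scores(model, C))
  acc <- matrix(0, nrow(image), ncol(image))
  cov <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(nrow(pos))) {
    rr <- pos$row[k]:(pos$row[k] + l - 1L)
    cc <- pos$col[k]:(pos$col[k] + l - 1L)
    acc[rr, cc] <- acc[rr, cc] + probs[k]
    cov[rr, cc] <- cov[rr, cc] + 1
  }
  out <- acc / pmax(cov, 1)
  out[cov == 0] <- 0.5  # unreachable with the inclusive grid; safety only
  structure(out, stride = stride, class = c("prob_map", "matrix", "array"))
}
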