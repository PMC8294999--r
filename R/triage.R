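# Depth-limited weighted CART (Gini) weak learner, written in-package:
# sample-weighted splits, ties broken by the lowest feature index then the
# lowest threshold, leaves vote the weighted-majority sign.

# Best single split on weighted +/-1 labels. Returns NULL if no split
# strictly reduces weighted Gini impurity.
best_split <- function(X, y, w) {
  n <- nrow(X)
  wt <- sum(w)
  wp <- sum(w[y > 0])
  parent_gini <- {
    p <- wp / wt
    2 * p * (1 - p)
  }
  best <- NULL
  best_gain <- 1e-12
  for (f in seq_len(ncol(X))) {
    ord <- order(X[, f])
    xs <- X[ord, f]
    ws <- w[ord]
    wsp <- ws * (y[ord] > 0)
    cl <- cumsum(ws)          # weight in the left child per cut position
    clp <- cumsum(wsp)
    # valid cuts lie between distinct consecutive values
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    wl <- cl[distinct]; wlp <- clp[distinct]
    wr <- wt - wl; wrp <- wp - wlp
    pl <- wlp / wl; pr <- wrp / wr
    child <- (wl * 2 * pl * (1 - pl) + wr * 2 * pr * (1 - pr)) / wt
    gain <- parent_gini - child
    k <- which.max(gain)      # lowest qualifying index on ties
    if (gain[k] > best_gain) {
      best_gain <- gain[k]
      best <- list(feature = f,
                   threshold = (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2)
    }
  }
  best
}

leaf_node <- function(y, w) {
  s <- sum(w * y)
  list(leaf = TRUE, pred = if (s >= 0) 1 else -1)
}

grow_cart <- function(X, y, w, depth, max_depth = 3L) {
  if (depth >= max_depth || length(unique(y)) == 1L) return(leaf_node(y, w))
  sp <- best_split(X, y, w)
  if (is.null(sp)) return(leaf_node(y, w))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_cart(X[left, , drop = FALSE], y[left], w[left],
                        depth + 1L, max_depth),
       right = grow_cart(X[!left, , drop = FALSE], y[!left], w[!left],
                         depth + 1L, max_depth))
}

predict_cart_one <- function(tree, x) {
  while (!tree$leaf) {
    tree <- if (x[tree$feature] <= tree$threshold) tree$left else tree$right
  }
  tree$pred
}

predict_cart <- function(tree, X) {
  apply(X, 1, function(x) predict_cart_one(tree, x))
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (is.data.frame(features)) return(as.matrix(features))
  if (is.list(features)) return(do.call(rbind, features))
  matrix(features, nrow = 1)
}

#' Train an AdaBoost triage classifier
#'
#' Classic discrete AdaBoost over depth-3 CART weak learners with weighted
#' Gini splits. Per round the weak learner is fit on the current sample
#' weights, its weighted error \eqn{\epsilon_t} is recorded, the learner
#' weight is \eqn{\alpha_t = \frac12 \ln((1-\epsilon_t)/\epsilon_t)}, and
#' sample weights are multiplied by \eqn{e^{\pm\alpha_t}} and renormalized.
#' Training halts early when a round is perfect (\eqn{\epsilon_t = 0}) or no
#' better than chance (\eqn{\epsilon_t \ge 0.5}).
#'
#' @param features List of feature vectors, matrix (rows = samples), or data
#'   frame.
#' @param labels Numeric vector of +1 (hot spot present) / -1 (absent).
#' @param T Maximum number of boosting rounds.
#' @param seed Integer seed (kept for interface uniformity; training is
#'   deterministic).
#' @param theta Half-width of the uncertain band on the boosted margin; if
#'   `NULL` it must be set later via [calibrate_theta()] before three-level
#'   classification.
#' @param max_depth Maximum CART depth.
#' @return An `adaboost_model`: `learners`, `alphas`, `eps` (per-round
#'   weighted errors), `theta`, `train_error_trace`.
#' @export
train_adaboost <- function(features, labels, T = 100L, seed = 1L,
                           theta = NULL, max_depth = 3L) {
  X <- as_feature_matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) {
    abort("`labels` must be +1/-1.", class = "hotspotseg_input_error")
  }
  if (length(unique(y)) < 2L) {
    abort("training needs at least one sample of each label.",
          class = "hotspotseg_training_error")
  }
  if (nrow(X) != length(y)) {
    abort("`features` and `labels` lengths differ.",
          class = "hotspotseg_input_error")
  }
  check_scalar(T, "T", lower = 1, integerish = TRUE)

  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  eps_trace <- numeric(0)
  err_trace <- numeric(0)
  agg <- numeric(n)

  for (t in seq_len(T)) {
    tree <- grow_cart(X, y, w, depth = 0L, max_depth = max_depth)
    h <- predict_cart(tree, X)
    eps <- sum(w[h != y])
    if (eps >= 0.5) break  # no better than chance: stop, discard
    eps_c <- max(eps, 1e-10)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    eps_trace <- c(eps_trace, eps)
    agg <- agg + alpha * h
    err_trace <- c(err_trace, mean(sign(agg) != y))
    if (eps == 0) break
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  if (!length(learners)) {
    abort("no weak learner beat chance on round 1.",
          class = "hotspotseg_training_error")
  }
  structure(
    list(learners = learners, alphas = alphas, eps = eps_trace,
         theta = theta, train_error_trace = err_trace,
         n_features = ncol(X), seed = as.integer(seed)),
    class = "adaboost_model"
  )
}

#' Boosted margin (signed confidence)
#'
#' The raw AdaBoost output \eqn{\mathrm{Result} = \sum_t \alpha_t h_t(x)}.
#' A positive sign means a hot spot is present, negative means absent; the
#' magnitude is the confidence consumed by the three-level rule.
#'
#' @param model An `adaboost_model`.
#' @param x A feature vector or matrix of rows.
#' @return Numeric margin(s).
#' @export
margin <- function(model, x) {
  X <- as_feature_matrix(x)
  if (ncol(X) != model$n_features) {
    abort(sprintf("feature length %d does not match model (%d).",
                  ncol(X), model$n_features),
          class = "hotspotseg_size_error")
  }
  H <- vapply(model$learners, function(tr) predict_cart(tr, X), numeric(nrow(X)))
  if (nrow(X) == 1L) H <- matrix(H, nrow = 1)
  drop(H %*% model$alphas)
}

#' Calibrate the uncertain band
#'
#' Sets `theta` to the 10th percentile of the absolute margin on a held-out
#' set: the 10% least-confident decisions fall into the uncertain level II.
#'
#' @param model An `adaboost_model`.
#' @param features Held-out features (matrix/list/data frame).
#' @param prob Quantile of `|margin|` to use (default 0.1).
#' @return The model with `theta` set.
#' @export
calibrate_theta <- function(model, features, prob = 0.1) {
  m <- abs(margin(model, features))
  q <- as.numeric(quantile(m, prob, names = FALSE, type = 7))
  # nudge just below the percentile: margins tied at the percentile (common
  # when one weak learner separates perfectly) stay confident
  model$theta <- max(0, q - 1e-8 * (1 + q))
  model
}

#' Three-level triage decision
#'
#' Applies the confidence band to the boosted margin: `Result > theta` gives
#' level `"I"` (certain hot spot), `Result < -theta` gives `"III"` (no hot
#' spot), and `|Result| <= theta` gives `"II"` (uncertain). Levels I and II
#' proceed to multi-instance scanning and segmentation; level III halts the
#' cascade.
#'
#' @param model An `adaboost_model` with `theta` set.
#' @param x Feature vector or matrix of rows.
#' @param theta Optional override of the model's band half-width.
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @export
classify_three_level <- function(model, x, theta = NULL) {
  th <- theta %||% model$theta
  if (is.null(th)) {
    abort("`theta` is not set; call calibrate_theta() or pass `theta`.",
          class = "hotspotseg_input_error")
  }
  check_scalar(th, "theta", lower = 0)
  r <- margin(model, x)
  out <- rep("II", length(r))
  out[r > th] <- "I"
  out[r < -th] <- "III"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adaboost_model <- function(x, ...) {
  cat(sprintf("<adaboost_model> %d round(s), final training error %.4g, theta %s\n",
              length(x$learners), utils::tail(x$train_error_trace, 1),
              if (is.null(x$theta)) "unset" else format(x$theta, digits = 4)))
  invisible(x)
}

#' @export
tidy.adaboost_model <- function(x, ...) {
  tibble::tibble(round = seq_along(x$alphas),
                 alpha = x$alphas,
                 weighted_error = x$eps,
                 train_error = x$train_error_trace)
}

#' @export
glance.adaboost_model <- function(x, ...) {
  tibble::tibble(rounds = length(x$alphas),
                 train_error = utils::tail(x$train_error_trace, 1),
                 theta = if (is.null(x$theta)) NA_real_ else x$theta,
                 exp_bound = prod(2 * sqrt(x$eps * (1 - x$eps))))
}
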