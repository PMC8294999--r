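#' Dice and Jaccard overlap between two masks
#'
#' \eqn{J(M,N) = |M \cap N| / |M \cup N|},
#' \eqn{D(M,N) = 2|M \cap N| / (|M| + |N|)}. Two empty masks score 1.0 (a
#' correct rejection); an empty mask against a non-empty one scores 0.0.
#'
#' @param M,N Binary masks (0/1 or logical matrices) of equal dimensions.
#' @return Named numeric vector `c(dice, jaccard)`.
#' @export
overlap_scores <- function(M, N) {
  assert_same_dim(M, N, c("M", "N"))
  m <- M > 0; n <- N > 0
  inter <- sum(m & n)
  uni <- sum(m | n)
  sm <- sum(m); sn <- sum(n)
  if (uni == 0) return(c(dice = 1, jaccard = 1))
  c(dice = 2 * inter / (sm + sn), jaccard = inter / uni)
}

#' Triage performance report
#'
#' Compares predicted three-level labels against the gold standard. Reports
#' exact-level accuracy, the 3x3 confusion table, the "excluding level-II
#' reassignments" accuracy (cases predicted II whose gold is I or III are
#' dropped from the denominator — the convention behind the clinical study's
#' headline accuracy), and binary TPR/FNR on the hot-spot-present dichotomy:
#' gold I is positive, gold III negative, and predictions of II on those
#' cases are counted separately as `n_uncertain`, not as detections or
#' misses.
#'
#' @param pred,gold Character vectors of `"I"`, `"II"`, `"III"`.
#' @return A list: `accuracy` (%), `accuracy_excluding_II` (% or `NA` when
#'   every case was reassigned to II), `tpr` (%), `fnr` (%), `n_uncertain`,
#'   `confusion` (3x3 table, rows = gold), `n`.
#' @export
triage_report <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    abort("`pred` and `gold` lengths differ.", class = "hotspotseg_input_error")
  }
  lv <- c("I", "II", "III")
  if (!all(pred %in% lv) || !all(gold %in% lv)) {
    abort("labels must be \"I\", \"II\" or \"III\".",
          class = "hotspotseg_input_error")
  }
  pred <- factor(pred, levels = lv)
  gold <- factor(gold, levels = lv)
  confusion <- table(gold = gold, pred = pred)
  accuracy <- 100 * mean(pred == gold)
  reassigned <- pred == "II" & gold != "II"
  denom <- sum(!reassigned)
  accuracy_excl <- if (denom == 0) NA_real_ else {
    100 * sum(pred == gold & !reassigned) / denom
  }
  # binary dichotomy: gold I positive, gold III negative; pred II set aside
  pos <- gold == "I"
  neg <- gold == "III"
  n_uncertain <- sum((pos | neg) & pred == "II")
  tp <- sum(pos & pred == "I")
  fn <- sum(pos & pred == "III")
  tpr <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  fnr <- if (tp + fn == 0) NA_real_ else 100 * fn / (tp + fn)
  list(accuracy = accuracy, accuracy_excluding_II = accuracy_excl,
       tpr = tpr, fnr = fnr, n_uncertain = n_uncertain,
       confusion = confusion, n = length(gold))
}

#' Benchmark segmentation methods against ground truth
#'
#' Scores every method's masks against the gold masks of the level-I cases
#' (certain lesions — the clinical comparison used exactly these) with
#' per-case Dice/Jaccard, and ranks methods by mean Dice. Scores are per-case
#' means, not pooled over pixels.
#'
#' @param cases Cohort tibble from [generate_cohort()] or list of
#'   `phantom_case` objects.
#' @param masks_by_method Named list; each element is a list of masks, one
#'   per case, aligned with `cases`.
#' @param levels Gold levels to score (default `"I"`).
#' @return A list: `per_case` tibble (`method`, `case_id`, `dice`,
#'   `jaccard`), and `summary` tibble (`method`, `mean_dice`,
#'   `mean_jaccard`, `n_cases`, `rank`), ranked by mean Dice.
#' @export
benchmark_methods <- function(cases, masks_by_method, levels = "I") {
  if (tibble::is_tibble(cases)) {
    ids <- cases$case_id
    gold_labels <- cases$gold_label
    case_list <- cases$case
  } else {
    ids <- sprintf("case_%03d", seq_along(cases))
    gold_labels <- vapply(cases, `[[`, character(1), "gold_label")
    case_list <- cases
  }
  if (is.null(names(masks_by_method)) || any(names(masks_by_method) == "")) {
    abort("`masks_by_method` must be a named list of mask lists.",
          class = "hotspotseg_input_error")
  }
  keep <- which(gold_labels %in% levels)
  per_case <- purrr::imap_dfr(masks_by_method, function(masks, method) {
    if (length(masks) != length(case_list)) {
      abort(sprintf("method \"%s\" supplied %d masks for %d cases.",
                    method, length(masks), length(case_list)),
            class = "hotspotseg_input_error")
    }
    purrr::map_dfr(keep, function(i) {
      sc <- overlap_scores(case_list[[i]]$mask, masks[[i]])
      tibble::tibble(method = method, case_id = ids[i],
                     dice = sc[["dice"]], jaccard = sc[["jaccard"]])
    })
  })
  summary <- per_case |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_dice = mean(.data$dice),
                     mean_jaccard = mean(.data$jaccard),
                     n_cases = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_dice)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(per_case = per_case, summary = summary,
                 scoring = "per-case mean over gold level(s): I"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> per-case mean Dice/Jaccard\n")
  print(x$summary)
  invisible(x)
}
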