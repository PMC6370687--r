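#' Cohort-level three-way judgment rates
#'
#' Summarizes a vector of three-way judgments against ground truth the way
#' CIT operating characteristics are conventionally reported: the
#' inconclusive rate over *all* cases, the hit rate among *conclusive*
#' truth-recognizing cases (judged recognized), and the correct-rejection
#' rate among *conclusive* truth-unrecognizing cases (judged unrecognized).
#' A rate with an empty denominator is reported as `NA`, never as 0 or 100.
#'
#' @param judgments Character vector (or list of `cit_judgment`) of labels
#'   in `recognized / inconclusive / unrecognized`.
#' @param truth Logical vector: is each examinee truly recognizing?
#' @return List with `inconclusive_rate`, `hit_rate`,
#'   `correct_rejection_rate`, all percentages in `[0, 100]` (or `NA`), and
#'   the underlying `counts` table.
#' @export
#' @examples
#' cohort_rates(c("recognized", "inconclusive", "unrecognized",
#'                "unrecognized"),
#'              c(TRUE, TRUE, FALSE, FALSE))
cohort_rates <- function(judgments, truth) {
  labels <- judgment_labels(judgments)
  truth <- as.logical(truth)
  if (length(labels) != length(truth))
    stop("'judgments' and 'truth' must have equal length", call. = FALSE)
  counts <- table(factor(labels, levels = c("recognized", "inconclusive",
                                            "unrecognized")),
                  factor(truth, levels = c(TRUE, FALSE)))
  dimnames(counts) <- list(judgment = rownames(counts),
                           truth_recognizing = c("yes", "no"))
  conclusive_R <- counts["recognized", "yes"] + counts["unrecognized", "yes"]
  conclusive_U <- counts["recognized", "no"] + counts["unrecognized", "no"]
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    inconclusive_rate = pct(sum(labels == "inconclusive"), length(labels)),
    hit_rate = pct(counts["recognized", "yes"], conclusive_R),
    correct_rejection_rate = pct(counts["unrecognized", "no"], conclusive_U),
    counts = counts)
}

judgment_labels <- function(judgments) {
  if (is.list(judgments))
    vapply(judgments, function(j)
      if (inherits(j, "cit_judgment")) j$label else as.character(j),
      character(1))
  else as.character(judgments)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC of a score against a binary truth, sweeping all score
#' thresholds; tied scores contribute half a concordance, so the value
#' equals the normalized Mann-Whitney U statistic. Scores for which
#' *smaller* means more-recognizing (p-values, ranks) are handled by
#' `direction = "less"`, which negates them first.
#'
#' @param scores Numeric vector.
#' @param truth Logical (or 0/1) vector: truly recognizing?
#' @param direction `"greater"` if large scores indicate recognition (d,
#'   Lykken), `"less"` if small scores do (p).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))  # 0.75
roc_auc <- function(scores, truth, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  if (!any(truth) || all(truth))
    stop("both classes must be present to compute an AUC", call. = FALSE)
  s <- if (direction == "less") -scores else scores
  # trapezoid over the empirical ROC at every distinct threshold
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- truth[ord]
  n1 <- sum(pos); n0 <- sum(!pos)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(s[-1] != s[-length(s)], TRUE)   # close groups of tied scores
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Binned score distribution by truth group
#'
#' The Fig.-style summary of a cohort's scores: for each score range, the
#' share of all examinees whose score falls in it, and among those, the
#' shares that are truly recognizing and truly unrecognizing. Bins are
#' left-closed, right-open, with open-ended extremes; the published bin
#' edges are the defaults (`type = "d"`:
#' `-Inf, -0.2, 0, 0.2, 0.4, 0.6, Inf`; `type = "p"`:
#' `0, 0.025, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1`).
#'
#' @param scores Numeric vector.
#' @param truth Logical vector: truly recognizing?
#' @param type `"d"` or `"p"`, selecting the published default edges.
#' @param edges Optional numeric vector of bin edges overriding `type`.
#' @return Data frame with one row per bin: `bin` (label), `n`,
#'   `share_of_all`, `share_recognizing`, `share_unrecognizing`
#'   (percentages; conditional shares are `NA` for empty bins).
#' @export
binned_recognition_ratios <- function(scores, truth, type = c("d", "p"),
                                      edges = NULL) {
  type <- match.arg(type)
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (is.null(edges))
    edges <- if (type == "d") c(-Inf, -0.2, 0, 0.2, 0.4, 0.6, Inf)
             else c(0, 0.025, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1)
  if (any(scores < edges[1]) || any(scores > edges[length(edges)]))
    stop("scores fall outside the outermost bin edges", call. = FALSE)
  # left-closed right-open; the last bin absorbs the upper boundary
  bin <- findInterval(scores, edges, rightmost.closed = TRUE)
  n_bins <- length(edges) - 1L
  out <- lapply(seq_len(n_bins), function(b) {
    inb <- bin == b
    n <- sum(inb)
    data.frame(
      bin = paste0("[", edges[b], ", ", edges[b + 1], ")"),
      n = n,
      share_of_all = 100 * n / length(scores),
      share_recognizing = if (n == 0) NA_real_ else
        100 * sum(truth[inb]) / n,
      share_unrecognizing = if (n == 0) NA_real_ else
        100 * sum(!truth[inb]) / n)
  })
  do.call(rbind, out)
}

#' Error decomposition for searching-CIT cohort judgments
#'
#' The searching CIT must control two kinds of false positive: a
#' recognizing examinee judged as recognizing the *wrong* (irrelevant) item,
#' and an unrecognizing examinee judged as recognizing *any* item. A
#' recognized judgment therefore counts as a hit only when the identified
#' item equals the true relevant item. Rates use the conventional
#' denominators: hit and false-positive-type-1 rates among conclusive
#' recognizing cases, correct-rejection and type-2 rates among conclusive
#' unrecognizing cases, inconclusive rate over all cases.
#'
#' @param judgments List of `cit_judgment` objects from
#'   [judge_searching()] (or a data frame with columns `label` and
#'   `identified_item`).
#' @param truth Logical vector: truly recognizing?
#' @param true_items Integer vector of true relevant item indices (required
#'   for recognizing cases; ignored elsewhere).
#' @return List with `counts` (named integer vector: `hit`,
#'   `false_positive_wrong_item`, `false_negative`,
#'   `inconclusive_recognizing`, `correct_rejection`,
#'   `false_positive_unrecognizing`, `inconclusive_unrecognizing`) and
#'   `rates` (percentages: `hit_rate`, `wrong_item_rate`,
#'   `correct_rejection_rate`, `false_alarm_rate`, `inconclusive_rate`).
#' @export
searching_error_decomposition <- function(judgments, truth, true_items) {
  if (is.data.frame(judgments)) {
    labels <- judgments$label
    items <- judgments$identified_item
  } else {
    labels <- judgment_labels(judgments)
    items <- vapply(judgments, function(j) as.integer(j$identified_item),
                    integer(1))
  }
  truth <- as.logical(truth)
  stopifnot(length(labels) == length(truth),
            length(items) == length(truth))
  if (any(truth & labels == "recognized" & is.na(true_items)))
    stop("'true_items' must be known for recognizing cases", call. = FALSE)

  rec <- truth
  counts <- c(
    hit = sum(rec & labels == "recognized" & items == true_items,
              na.rm = TRUE),
    false_positive_wrong_item =
      sum(rec & labels == "recognized" & items != true_items,
          na.rm = TRUE),
    false_negative = sum(rec & labels == "unrecognized"),
    inconclusive_recognizing = sum(rec & labels == "inconclusive"),
    correct_rejection = sum(!rec & labels == "unrecognized"),
    false_positive_unrecognizing = sum(!rec & labels == "recognized"),
    inconclusive_unrecognizing = sum(!rec & labels == "inconclusive"))
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  conclusive_R <- counts[["hit"]] + counts[["false_positive_wrong_item"]] +
    counts[["false_negative"]]
  conclusive_U <- counts[["correct_rejection"]] +
    counts[["false_positive_unrecognizing"]]
  rates <- c(
    hit_rate = pct(counts[["hit"]], conclusive_R),
    wrong_item_rate = pct(counts[["false_positive_wrong_item"]],
                          conclusive_R),
    correct_rejection_rate = pct(counts[["correct_rejection"]],
                                 conclusive_U),
    false_alarm_rate = pct(counts[["false_positive_unrecognizing"]],
                           conclusive_U),
    inconclusive_rate = pct(counts[["inconclusive_recognizing"]] +
                              counts[["inconclusive_unrecognizing"]],
                            length(labels)))
  list(counts = counts, rates = rates)
}
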