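#' Threshold configuration for three-way CIT judgments
#'
#' A judgment configuration carries the two cutoffs that partition a
#' statistic into the three decision bands. For the effect size d the
#' recognized band lies *above* the upper cutoff and the unrecognized band
#' *below* the lower cutoff; for the randomization p the orientation is
#' reversed (recognized below the lower cutoff, unrecognized above the
#' upper). Values falling exactly on a cutoff are judged inconclusive: the
#' published bands are open intervals on both sides, and inconclusive is the
#' conservative assignment for the boundary.
#'
#' @param mode `"known_solution"` or `"searching"`.
#' @param statistic `"d"` or `"p"`.
#' @param recognized Cutoff of the recognized band (d: recognized when
#'   `d > recognized`; p: recognized when `p < recognized`).
#' @param unrecognized Cutoff of the unrecognized band (d: unrecognized when
#'   `d < unrecognized`; p: unrecognized when `p > unrecognized`).
#' @return Object of class `cit_judgment_config`.
#' @seealso [cit_preset()] for the published threshold presets.
#' @export
cit_judgment_config <- function(mode = c("known_solution", "searching"),
                                statistic = c("d", "p"),
                                recognized, unrecognized) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(recognized), is.numeric(unrecognized))
  if (statistic == "d" && recognized < unrecognized)
    stop("for d, the recognized cutoff must be >= the unrecognized cutoff",
         call. = FALSE)
  if (statistic == "p" && recognized > unrecognized)
    stop("for p, the recognized cutoff must be <= the unrecognized cutoff",
         call. = FALSE)
  structure(list(mode = mode, statistic = statistic,
                 recognized = recognized, unrecognized = unrecognized),
            class = "cit_judgment_config")
}

#' Published threshold presets for CIT judgments
#'
#' The shipped presets are exactly the published threshold pairs:
#'
#' | preset               | statistic | recognized | unrecognized |
#' |----------------------|-----------|------------|--------------|
#' | `known_d`            | d         | > 0.4      | < 0          |
#' | `known_d_lenient`    | d         | > 0.3      | < 0.1        |
#' | `known_p`            | p         | < 0.025    | > 0.6        |
#' | `known_p_lenient`    | p         | < 0.05     | > 0.4        |
#' | `searching_d`        | d         | > 0.6      | < 0.2        |
#' | `searching_p`        | p         | < 0.01     | > 0.2        |
#'
#' The lenient known-solution presets trade a lower inconclusive rate for a
#' slightly lower hit/correct-rejection rate; no lenient searching preset is
#' published. The searching cutoffs are stricter than the known-solution
#' ones because the searching CIT scores every item and must control two
#' kinds of false positive (see [searching_error_decomposition()]).
#'
#' @param name One of the preset names above.
#' @return A [cit_judgment_config].
#' @export
#' @examples
#' cit_preset("known_d")
cit_preset <- function(name = c("known_d", "known_d_lenient", "known_p",
                                "known_p_lenient", "searching_d",
                                "searching_p")) {
  name <- match.arg(name)
  switch(name,
    known_d = cit_judgment_config("known_solution", "d", 0.4, 0),
    known_d_lenient = cit_judgment_config("known_solution", "d", 0.3, 0.1),
    known_p = cit_judgment_config("known_solution", "p", 0.025, 0.6),
    known_p_lenient = cit_judgment_config("known_solution", "p", 0.05, 0.4),
    searching_d = cit_judgment_config("searching", "d", 0.6, 0.2),
    searching_p = cit_judgment_config("searching", "p", 0.01, 0.2))
}

#' @export
print.cit_judgment_config <- function(x, ...) {
  rel <- if (x$statistic == "d") c(">", "<") else c("<", ">")
  cat("CIT judgment thresholds (", x$mode, ", statistic ", x$statistic,
      ")\n", sep = "")
  cat("  recognized:   ", x$statistic, rel[1], x$recognized, "\n")
  cat("  unrecognized: ", x$statistic, rel[2], x$unrecognized, "\n")
  cat("  inconclusive:  otherwise (boundaries inconclusive)\n")
  invisible(x)
}

# band membership for a single statistic value under a config
band_label <- function(value, config) {
  if (config$statistic == "d") {
    if (value > config$recognized) "recognized"
    else if (value < config$unrecognized) "unrecognized"
    else "inconclusive"
  } else {
    if (value < config$recognized) "recognized"
    else if (value > config$unrecognized) "unrecognized"
    else "inconclusive"
  }
}

new_judgment <- function(label, basis, config, value,
                         identified_item = NA_integer_) {
  structure(list(label = label, basis = basis, value = value,
                 identified_item = identified_item,
                 thresholds_used = config),
            class = "cit_judgment")
}

#' @export
print.cit_judgment <- function(x, ...) {
  cat("CIT judgment: ", toupper(x$label), " (basis: ", x$basis, ")\n",
      sep = "")
  if (!is.na(x$identified_item))
    cat("  identified item:", x$identified_item, "\n")
  invisible(x)
}

#' Three-way judgment for a known-solution CIT
#'
#' Assigns recognized / inconclusive / unrecognized from an integrated
#' statistic and a threshold configuration ([cit_preset()]). Exact boundary
#' values are inconclusive.
#'
#' @param integrated_stat The integrated d or integrated p of the session.
#' @param config A [cit_judgment_config] with `mode = "known_solution"`.
#' @return Object of class `cit_judgment`: list with `label`, `basis`,
#'   `value`, `identified_item` (always `NA` here), `thresholds_used`.
#' @export
#' @examples
#' judge_known(0.5, cit_preset("known_d"))$label   # "recognized"
#' judge_known(0.7, cit_preset("known_p"))$label   # "unrecognized"
judge_known <- function(integrated_stat, config) {
  stopifnot(inherits(config, "cit_judgment_config"))
  if (config$mode != "known_solution")
    stop("config is not a known-solution configuration", call. = FALSE)
  new_judgment(band_label(integrated_stat, config), config$statistic,
               config, integrated_stat)
}

#' Conjunctive judgment from both statistics
#'
#' The d value measures the response difference quantitatively while the p
#' value measures it stochastically, so the two can disagree; the
#' conjunctive rule is recognized only when both statistics say recognized,
#' unrecognized only when both say unrecognized, and inconclusive otherwise.
#'
#' @param integrated_d,integrated_p The session's integrated statistics.
#' @param d_config,p_config Threshold configurations for each statistic;
#'   default to the strict known-solution presets.
#' @return A `cit_judgment` with `basis = "both"`.
#' @export
judge_both <- function(integrated_d, integrated_p,
                       d_config = cit_preset("known_d"),
                       p_config = cit_preset("known_p")) {
  ld <- band_label(integrated_d, d_config)
  lp <- band_label(integrated_p, p_config)
  label <- if (ld == "recognized" && lp == "recognized") "recognized"
           else if (ld == "unrecognized" && lp == "unrecognized")
             "unrecognized"
           else "inconclusive"
  structure(list(label = label, basis = "both",
                 value = c(d = integrated_d, p = integrated_p),
                 identified_item = NA_integer_,
                 thresholds_used = list(d = d_config, p = p_config)),
            class = "cit_judgment")
}

#' Per-item scores for a searching CIT
#'
#' When the crime-relevant item is unknown, every item is scored as if it
#' were the relevant one: for each item the integrated d and integrated p
#' are computed exactly as in the known-solution analysis. All items share a
#' single relabeling draw (the relabelings depend only on the design and
#' seed), so the per-item p-values are comparable and the whole table is
#' reproducible from the seed. Items whose effect size is undefined
#' (pooled SD zero) get `NA` d values with a warning rather than an error.
#'
#' @param session A [cit_session]; its designated relevant item, if any, is
#'   ignored.
#' @param B Number of relabelings (default 1000).
#' @param seed Integer seed.
#' @param exhaustive Passed to [cit_relabelings()].
#' @return A data frame with one row per item: `item` (index), `label`,
#'   `integrated_d`, `integrated_p`.
#' @export
searching_scores <- function(session, B = 1000, seed = NULL,
                             exhaustive = NULL) {
  stopifnot(inherits(session, "cit_session"))
  if (session$n_items < 2L)
    stop("searching CIT needs at least 2 items", call. = FALSE)
  relab <- cit_relabelings(session$n_items, session$n_reps, B = B,
                           seed = seed, exhaustive = exhaustive)
  d_i <- vapply(seq_len(session$n_items), function(i) {
    tryCatch(cit_d(session, relevant = i)$integrated_d,
             error = function(e) {
               warning("item ", i, ": ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  p_i <- vapply(seq_len(session$n_items), function(i)
    cit_p(session, relevant = i, relabelings = relab)$integrated_p,
    numeric(1))
  data.frame(item = seq_len(session$n_items), label = session$items,
             integrated_d = d_i, integrated_p = p_i)
}

#' Three-way judgment for a searching CIT
#'
#' The decision statistic is the maximum integrated d (or the minimum
#' integrated p) over the items of [searching_scores()]. If it falls in the
#' recognized band, the extremal item is reported as the identified item;
#' exact ties for the extremum are broken toward the lowest item index with
#' a warning.
#'
#' @param scores Data frame from [searching_scores()].
#' @param config A [cit_judgment_config] with `mode = "searching"`.
#' @return A `cit_judgment`; `identified_item` is set (1-based item index)
#'   iff the label is `"recognized"`.
#' @export
judge_searching <- function(scores, config) {
  stopifnot(inherits(config, "cit_judgment_config"))
  if (config$mode != "searching")
    stop("config is not a searching-CIT configuration", call. = FALSE)
  col <- if (config$statistic == "d") "integrated_d" else "integrated_p"
  v <- scores[[col]]
  if (all(is.na(v)))
    stop("all per-item statistics are undefined", call. = FALSE)
  extreme <- if (config$statistic == "d") max(v, na.rm = TRUE)
             else min(v, na.rm = TRUE)
  hits <- which(v == extreme)
  if (length(hits) > 1L)
    warning("tie for the extremal item; reporting the lowest index",
            call. = FALSE)
  item <- scores$item[hits[1L]]
  label <- band_label(extreme, config)
  new_judgment(label, config$statistic, config, extreme,
               identified_item = if (label == "recognized") item
                                 else NA_integer_)
}
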