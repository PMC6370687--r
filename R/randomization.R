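#' Generate random relabelings for the CIT randomization test
#'
#' A relabeling picks `n_reps` of the `n_items * n_reps` response cells and
#' calls them the responses to the relevant item; the remaining cells become
#' the irrelevant responses. Only the relevant/irrelevant partition matters
#' for a mean difference, so relabelings are unordered cell subsets. The same
#' set of relabelings is applied to every measure of a session, which
#' preserves cross-measure dependence in the permutation null -- a
#' requirement for the multiplied-p calibration to be valid.
#'
#' When the number of distinct subsets `choose(n_items * n_reps, n_reps)` is
#' at most `exhaustive_cap` (and `exhaustive` is not `FALSE`), all subsets
#' are enumerated instead of sampled.
#'
#' @param n_items,n_reps Session design.
#' @param B Number of Monte-Carlo relabelings (default 1000).
#' @param seed Integer seed for reproducible sampling (ignored in exhaustive
#'   mode).
#' @param exhaustive `TRUE` to force enumeration, `FALSE` to force
#'   Monte-Carlo sampling, `NULL` (default) to enumerate automatically when
#'   feasible.
#' @param exhaustive_cap Auto-enumeration threshold on the subset count.
#' @return Object of class `cit_relabelings`: list with `idx` (a `B` x
#'   `n_reps` integer matrix of cell indices in column-major order of the
#'   item-by-repetition grid), `B`, `exhaustive`, `seed`, `n_items`,
#'   `n_reps`.
#' @export
#' @examples
#' r <- cit_relabelings(3, 2)  # C(6,2) = 15 subsets, enumerated
#' r$B
cit_relabelings <- function(n_items, n_reps, B = 1000, seed = NULL,
                            exhaustive = NULL, exhaustive_cap = 10000) {
  n_cells <- n_items * n_reps
  stopifnot(n_items >= 2L, n_reps >= 1L, B >= 1L)
  n_total <- choose(n_cells, n_reps)
  do_exhaustive <- isTRUE(exhaustive) ||
    (is.null(exhaustive) && n_total <= exhaustive_cap)
  if (do_exhaustive) {
    if (n_total > exhaustive_cap)
      stop("exhaustive enumeration of ", n_total,
           " relabelings exceeds the cap (", exhaustive_cap, ")",
           call. = FALSE)
    idx <- t(utils::combn(n_cells, n_reps))
    return(structure(
      list(idx = idx, B = nrow(idx), exhaustive = TRUE, seed = NA_integer_,
           n_items = n_items, n_reps = n_reps),
      class = "cit_relabelings"))
  }
  idx <- with_seed(seed, {
    t(vapply(seq_len(B),
             function(b) sample.int(n_cells, n_reps),
             integer(n_reps)))
  })
  structure(
    list(idx = idx, B = B, exhaustive = FALSE,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         n_items = n_items, n_reps = n_reps),
    class = "cit_relabelings")
}

# mean(relevant cells) - mean(remaining cells) for each relabeling row,
# vectorized over relabelings; v is the flattened response grid
relabeled_differences <- function(v, idx, n_reps) {
  n_cells <- length(v)
  total <- sum(v)
  rel_sums <- rowSums(matrix(v[idx], nrow = nrow(idx)))
  rel_sums / n_reps - (total - rel_sums) / (n_cells - n_reps)
}

#' Convert the rank of a real difference among generated ones to a p-value
#'
#' Implements the rank rule of the randomization test: if the real response
#' difference is the x-th most extreme (largest for direction `+1`, smallest
#' for `-1`) among `B` generated differences, the p-value is `x / B`. The
#' rank is `x = 1 + #` of generated differences at least as extreme as the
#' real one (ties count against significance), clipped to `[1, B]`, so a
#' real difference beating all generated ones gives `p = 1/B` (never 0) and
#' fully tied degenerate data give `p = 1`.
#'
#' @param real The observed response difference.
#' @param generated Numeric vector of generated response differences.
#' @param direction `+1` if larger differences are more extreme (SCR), `-1`
#'   if smaller are (HR, RLL, NPV).
#' @param self_contained `TRUE` when `generated` already contains the real
#'   labeling (exhaustive enumeration), in which case the anti-zero `+1` is
#'   not added.
#' @return List with `p` and the integer rank `x`.
#' @export
#' @examples
#' # a real difference ranking 50th largest among 1000 => p = 0.05
#' rank_to_p(0.9515, (1:1000) / 1000, direction = 1)$p
rank_to_p <- function(real, generated, direction = 1,
                      self_contained = FALSE) {
  B <- length(generated)
  n_extreme <- sum(direction * generated >= direction * real)
  x <- if (self_contained) n_extreme else n_extreme + 1L
  x <- max(1L, min(as.integer(x), B))
  list(p = x / B, x = x)
}

#' Per-measure randomization-test p-value
#'
#' The real response difference (mean relevant minus mean irrelevant) is
#' ranked among the differences generated by random relabelings of the
#' response cells; the p-value is rank/B in the measure's expected
#' direction (see [rank_to_p()]).
#'
#' @param responses Numeric `n_items` x `n_reps` response matrix for one
#'   measure.
#' @param relevant Relevant item row index.
#' @param relabelings A [cit_relabelings] object matching the matrix design.
#' @param direction Expected response direction, `+1` or `-1`.
#' @return List with `p`, rank `x`, `real_difference`, and the vector of
#'   `generated_differences`.
#' @export
randomization_p <- function(responses, relevant, relabelings,
                            direction = 1) {
  stopifnot(inherits(relabelings, "cit_relabelings"))
  m <- as.matrix(responses)
  if (nrow(m) != relabelings$n_items || ncol(m) != relabelings$n_reps)
    stop("response matrix does not match the relabeling design",
         call. = FALSE)
  v <- as.vector(m)
  rel_cells <- relevant + nrow(m) * (seq_len(ncol(m)) - 1L)
  # same arithmetic path as the generated differences, so the observed
  # labeling ties its own subset exactly in exhaustive mode
  real <- relabeled_differences(v, matrix(rel_cells, nrow = 1L),
                                relabelings$n_reps)
  gen <- relabeled_differences(v, relabelings$idx, relabelings$n_reps)
  r <- rank_to_p(real, gen, direction,
                 self_contained = relabelings$exhaustive)
  list(p = r$p, x = r$x, real_difference = real,
       generated_differences = gen)
}

# self-inclusive pseudo-p of each generated difference among all generated
# differences: #{j : generated_j at least as extreme as generated_b} / B
pseudo_p <- function(generated, direction) {
  v <- direction * generated
  (length(v) - rank(v, ties.method = "min") + 1) / length(v)
}

#' Integrated randomization-test p-value of a CIT session
#'
#' Computes per-measure randomization p-values from a single shared set of
#' relabelings, multiplies them across the measures present ("original
#' multiplied p"), and calibrates that product against its own permutation
#' null: each relabeling b gets a pseudo-p per measure (the self-inclusive
#' rank of its generated difference among all B generated differences, in
#' the measure's direction), the pseudo-p's are multiplied across measures,
#' and the integrated p is the rank of the original multiplied p among the B
#' generated multiplied p's, divided by B. Missing measures are simply
#' skipped. The calibration step is what makes the product of dependent
#' per-measure p-values interpretable as a p-value itself.
#'
#' @param session A [cit_session].
#' @param relevant Relevant item (label or index); defaults to the session's.
#' @param B Number of relabelings (default 1000).
#' @param seed Integer seed for the relabeling draw.
#' @param exhaustive Passed to [cit_relabelings()].
#' @param relabelings Optionally a pre-built [cit_relabelings] object
#'   (overrides `B`, `seed`, `exhaustive`); used to share one draw across
#'   the items of a searching CIT.
#' @return Object of class `cit_p`: list with `per_measure_p`,
#'   `per_measure_x` (named vectors), `integrated_p`, `integrated_x`,
#'   `original_multiplied_p`, `B`, `seed`, `exhaustive`, `relevant`,
#'   `session_id`.
#' @export
cit_p <- function(session, relevant = NULL, B = 1000, seed = NULL,
                  exhaustive = NULL, relabelings = NULL) {
  stopifnot(inherits(session, "cit_session"))
  rel <- resolve_relevant(session, relevant)
  if (is.null(relabelings))
    relabelings <- cit_relabelings(session$n_items, session$n_reps, B = B,
                                   seed = seed, exhaustive = exhaustive)
  measures <- names(session$responses)
  per <- lapply(measures, function(ms)
    randomization_p(session$responses[[ms]], rel, relabelings,
                    session$directions[ms]))
  names(per) <- measures
  p_m <- vapply(per, `[[`, numeric(1), "p")
  x_m <- vapply(per, function(z) as.integer(z$x), integer(1))

  original <- prod(p_m)
  gen_mult <- Reduce(`*`, lapply(measures, function(ms)
    pseudo_p(per[[ms]]$generated_differences, session$directions[ms])))
  n_le <- sum(gen_mult <= original)
  x_int <- if (relabelings$exhaustive) n_le else n_le + 1L
  x_int <- max(1L, min(as.integer(x_int), relabelings$B))

  structure(
    list(per_measure_p = p_m, per_measure_x = x_m,
         integrated_p = x_int / relabelings$B, integrated_x = x_int,
         original_multiplied_p = original, B = relabelings$B,
         seed = relabelings$seed, exhaustive = relabelings$exhaustive,
         relevant = rel, session_id = session$session_id),
    class = "cit_p")
}

#' @export
print.cit_p <- function(x, digits = 4, ...) {
  cat("CIT randomization test (session '", x$session_id, "', relevant item ",
      x$relevant, ")\n", sep = "")
  cat("  ", if (x$exhaustive) "exhaustive enumeration of" else
      "Monte-Carlo relabelings:", " B = ", x$B, "\n", sep = "")
  print(round(x$per_measure_p, digits))
  cat("integrated p:", format(x$integrated_p, digits = digits), "\n")
  invisible(x)
}
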