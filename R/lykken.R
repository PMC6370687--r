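#' Lykken block scoring of one measure
#'
#' The traditional CIT score: within each repetition block, the relevant
#' item receives 2 points if it evoked the largest response of the block, 1
#' point if the second largest, 0 otherwise; the score is the sum over
#' blocks, in `[0, 2 * n_reps]`. Responses are direction-adjusted first
#' (multiplied by the measure's expected direction) so "largest" means
#' most-in-the-expected-direction for every measure. Ties, which have
#' probability zero for continuous responses, are broken at random.
#'
#' @param responses Numeric `n_items` x `n_reps` response matrix (at least 3
#'   items, so that the 2/1/0 ranks are distinct).
#' @param relevant Relevant item row index.
#' @param direction Expected response direction, `+1` or `-1`.
#' @param seed Optional integer seed making random tie-breaks reproducible.
#' @return Integer score in `[0, 2 * n_reps]`.
#' @export
#' @examples
#' m <- rbind(c(5, 5), c(1, 3), c(2, 1))  # relevant row largest in both blocks
#' lykken_score(m, relevant = 1)          # 4
lykken_score <- function(responses, relevant, direction = 1, seed = NULL) {
  m <- as.matrix(responses)
  if (nrow(m) < 3L)
    stop("Lykken scoring needs at least 3 items", call. = FALSE)
  stopifnot(relevant >= 1L, relevant <= nrow(m))
  adj <- direction * m
  with_seed(seed, {
    block_pts <- vapply(seq_len(ncol(adj)), function(j) {
      r <- rank(-adj[, j], ties.method = "random")[relevant]
      if (r == 1) 2L else if (r == 2) 1L else 0L
    }, integer(1))
    sum(block_pts)
  })
}

#' Integrate Lykken scores across measures by averaging
#'
#' @param per_measure_scores Named numeric vector (or list) of per-measure
#'   Lykken scores.
#' @return Arithmetic mean (scalar).
#' @export
#' @examples
#' integrate_lykken(c(SCR = 10, HR = 6, RLL = 4, NPV = 0))  # 5
integrate_lykken <- function(per_measure_scores) {
  s <- unlist(per_measure_scores)
  if (length(s) == 0L)
    stop("no per-measure Lykken scores to integrate", call. = FALSE)
  mean(s)
}

#' Lykken scoring of a CIT session
#'
#' Applies [lykken_score()] to every measure present and averages across
#' measures. Lykken scoring is the traditional comparator: it always assigns
#' points, even when no response in a block is salient, and no inconclusive
#' band or decision threshold is defined for it.
#'
#' @param session A [cit_session] with at least 3 items.
#' @param relevant Relevant item (label or index); defaults to the
#'   session's.
#' @param seed Optional integer seed for tie-breaking.
#' @return Object of class `cit_lykken`: list with `per_measure_score`
#'   (named vector), `integrated_score`, `max_score` (`2 * n_reps`),
#'   `relevant`, `session_id`.
#' @export
cit_lykken <- function(session, relevant = NULL, seed = NULL) {
  stopifnot(inherits(session, "cit_session"))
  rel <- resolve_relevant(session, relevant)
  measures <- names(session$responses)
  scores <- vapply(seq_along(measures), function(k)
    lykken_score(session$responses[[measures[k]]], rel,
                 session$directions[measures[k]],
                 seed = child_seed(seed, k)),
    integer(1))
  names(scores) <- measures
  structure(
    list(per_measure_score = scores,
         integrated_score = integrate_lykken(scores),
         max_score = 2L * session$n_reps,
         relevant = rel, session_id = session$session_id),
    class = "cit_lykken")
}

#' @export
print.cit_lykken <- function(x, ...) {
  cat("CIT Lykken score (session '", x$session_id, "', relevant item ",
      x$relevant, ")\n", sep = "")
  print(x$per_measure_score)
  cat("integrated score:", x$integrated_score, "of", x$max_score, "\n")
  invisible(x)
}
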