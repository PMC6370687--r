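#' Pooled standard deviation from unbiased variances
#'
#' The standardizer used by the CIT effect size: with `n1` responses to the
#' relevant item (unbiased variance `s1^2`) and `n2` responses to the
#' irrelevant items (unbiased variance `s2^2`),
#' \deqn{s_p = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}.}
#'
#' @param relevant_responses Numeric vector, responses to the relevant item
#'   (length >= 2).
#' @param irrelevant_responses Numeric vector, responses to the irrelevant
#'   items (length >= 2).
#' @return The pooled standard deviation (scalar, >= 0).
#' @export
#' @examples
#' pooled_sd(c(0, 2), c(0, 2))  # sqrt(2)
pooled_sd <- function(relevant_responses, irrelevant_responses) {
  n1 <- length(relevant_responses)
  n2 <- length(irrelevant_responses)
  if (n1 < 2L || n2 < 2L)
    stop("pooled SD needs at least 2 responses in each group ",
         "(unbiased variances)", call. = FALSE)
  s1 <- stats::var(relevant_responses)
  s2 <- stats::var(irrelevant_responses)
  sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
}

#' Per-measure CIT effect size d
#'
#' The mean response to the relevant item minus the mean response to the
#' irrelevant items, divided by the pooled standard deviation
#' ([pooled_sd()]), then multiplied by the measure's expected direction so
#' that a positive d always means the relevant item evoked the response
#' pattern expected under recognition (larger SCR; smaller HR, RLL, NPV).
#'
#' @param session A [cit_session].
#' @param measure Measure name (must be present in the session).
#' @param relevant Relevant item (label or index); defaults to the session's
#'   designated relevant item.
#' @return The effect size d (scalar).
#' @export
effect_size_d <- function(session, measure, relevant = NULL) {
  stopifnot(inherits(session, "cit_session"))
  if (!measure %in% names(session$responses))
    stop("measure '", measure, "' is not present in this session",
         call. = FALSE)
  rel <- resolve_relevant(session, relevant)
  m <- session$responses[[measure]]
  x1 <- m[rel, ]
  x2 <- as.vector(m[-rel, , drop = FALSE])
  sp <- pooled_sd(x1, x2)
  if (sp == 0)
    stop("degenerate data: pooled SD is 0 for measure '", measure,
         "', d is undefined", call. = FALSE)
  unname(session$directions[measure]) * (mean(x1) - mean(x2)) / sp
}

#' Integrate per-measure effect sizes by averaging
#'
#' Cross-measure integration is a plain arithmetic mean; when some measures
#' are missing (e.g. skin conductance for an electrodermal non-responder) the
#' mean is taken over the remaining measures.
#'
#' @param per_measure_d Named numeric vector (or list) of per-measure d
#'   values.
#' @return The integrated d (scalar mean).
#' @export
#' @examples
#' integrate_d(c(SCR = 0.8, HR = 0.4, RLL = 0.4, NPV = 0.0))  # 0.4
integrate_d <- function(per_measure_d) {
  d <- unlist(per_measure_d)
  if (length(d) == 0L)
    stop("no per-measure d values to integrate", call. = FALSE)
  mean(d)
}

#' Effect-size scoring of a CIT session
#'
#' Computes the per-measure effect size d for every measure present in the
#' session, with the ingredients of each (group sizes, unbiased variances,
#' pooled SD), and the integrated d (mean over present measures).
#'
#' @inheritParams effect_size_d
#' @return Object of class `cit_d`: list with `per_measure_d` (named
#'   vector), `ingredients` (data frame with one row per measure: `n1`, `n2`,
#'   `s1_sq`, `s2_sq`, `s_p`), `integrated_d`, `relevant`, `session_id`.
#' @export
cit_d <- function(session, relevant = NULL) {
  stopifnot(inherits(session, "cit_session"))
  rel <- resolve_relevant(session, relevant)
  measures <- names(session$responses)
  ing <- lapply(measures, function(ms) {
    m <- session$responses[[ms]]
    x1 <- m[rel, ]
    x2 <- as.vector(m[-rel, , drop = FALSE])
    data.frame(measure = ms, n1 = length(x1), n2 = length(x2),
               s1_sq = stats::var(x1), s2_sq = stats::var(x2),
               s_p = pooled_sd(x1, x2))
  })
  ing <- do.call(rbind, ing)
  d <- vapply(measures, function(ms) effect_size_d(session, ms, rel),
              numeric(1))
  structure(
    list(per_measure_d = d, ingredients = ing, integrated_d = integrate_d(d),
         relevant = rel, session_id = session$session_id),
    class = "cit_d")
}

#' @export
print.cit_d <- function(x, digits = 3, ...) {
  cat("CIT effect size d (session '", x$session_id, "', relevant item ",
      x$relevant, ")\n", sep = "")
  print(round(x$per_measure_d, digits))
  cat("integrated d:", format(x$integrated_d, digits = digits), "\n")
  invisible(x)
}
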