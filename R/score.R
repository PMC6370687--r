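#' Score a CIT session with all statistics
#'
#' The central entry point: computes for one session the per-measure and
#' integrated effect size d ([cit_d()]), randomization-test p ([cit_p()])
#' and Lykken score ([cit_lykken()]). Degenerate measures (zero pooled SD)
#' make d undefined; the d slot is then `NULL` and downstream judgment
#' should treat the session as inconclusive.
#'
#' @param session A [cit_session].
#' @param relevant Relevant item (label or index); defaults to the
#'   session's.
#' @param B Number of relabelings for the randomization test.
#' @param seed Integer seed for the relabeling draw and Lykken tie-breaks.
#' @param statistics Subset of `c("d", "p", "lykken")` to compute.
#' @param exhaustive Passed to [cit_relabelings()].
#' @return Object of class `cit_score`: list with elements `d` (a `cit_d`
#'   or `NULL` if degenerate), `p` (a `cit_p`), `lykken` (a `cit_lykken`),
#'   `degenerate` (flag), `relevant`, `session_id`.
#' @export
#' @examples
#' s <- simulate_cit_session(cit_synthetic_config(seed = 1),
#'                           recognizing = TRUE, seed = 7)
#' fit <- cit_score(s, B = 200, seed = 42)
#' fit
#' coef(fit)
cit_score <- function(session, relevant = NULL, B = 1000, seed = NULL,
                      statistics = c("d", "p", "lykken"),
                      exhaustive = NULL) {
  stopifnot(inherits(session, "cit_session"))
  statistics <- match.arg(statistics, several.ok = TRUE)
  rel <- resolve_relevant(session, relevant)
  degenerate <- FALSE
  d <- p <- lyk <- NULL
  if ("d" %in% statistics) {
    d <- tryCatch(cit_d(session, rel), error = function(e) {
      if (grepl("degenerate", conditionMessage(e))) NULL else stop(e)
    })
    degenerate <- is.null(d)
  }
  if ("p" %in% statistics)
    p <- cit_p(session, rel, B = B, seed = seed, exhaustive = exhaustive)
  if ("lykken" %in% statistics && session$n_items >= 3L)
    lyk <- cit_lykken(session, rel, seed = child_seed(seed, 1L))
  structure(
    list(d = d, p = p, lykken = lyk, degenerate = degenerate,
         relevant = rel, session_id = session$session_id),
    class = "cit_score")
}

#' @export
print.cit_score <- function(x, digits = 3, ...) {
  cat("CIT scores for session '", x$session_id, "' (relevant item ",
      x$relevant, ")\n", sep = "")
  if (x$degenerate)
    cat("  effect size d: undefined (zero pooled SD)\n")
  else if (!is.null(x$d))
    cat("  integrated d:     ", format(x$d$integrated_d, digits = digits),
        "\n", sep = "")
  if (!is.null(x$p))
    cat("  integrated p:     ", format(x$p$integrated_p, digits = digits),
        "  (B = ", x$p$B, ")\n", sep = "")
  if (!is.null(x$lykken))
    cat("  Lykken (mean):    ",
        format(x$lykken$integrated_score, digits = digits), " of ",
        x$lykken$max_score, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cit_score <- function(object, ...) {
  measures <- if (!is.null(object$p)) names(object$p$per_measure_p)
              else names(object$d$per_measure_d)
  tab <- data.frame(measure = measures)
  if (!is.null(object$d))
    tab$d <- object$d$per_measure_d[measures]
  if (!is.null(object$p))
    tab$p <- object$p$per_measure_p[measures]
  if (!is.null(object$lykken))
    tab$lykken <- object$lykken$per_measure_score[measures]
  structure(list(table = tab, integrated = coef(object),
                 session_id = object$session_id,
                 degenerate = object$degenerate),
            class = "summary.cit_score")
}

#' @export
print.summary.cit_score <- function(x, digits = 3, ...) {
  cat("Per-measure CIT scores, session '", x$session_id, "':\n", sep = "")
  print(x$table, digits = digits, row.names = FALSE)
  cat("integrated:\n")
  print(round(x$integrated, digits))
  invisible(x)
}

#' @export
coef.cit_score <- function(object, ...) {
  c(d = if (!is.null(object$d)) object$d$integrated_d else NA_real_,
    p = if (!is.null(object$p)) object$p$integrated_p else NA_real_,
    lykken = if (!is.null(object$lykken))
      object$lykken$integrated_score else NA_real_)
}

#' Judge a scored session
#'
#' Applies a threshold configuration to the integrated statistic of a
#' [cit_score()] fit. A session whose d is degenerate (zero pooled SD) is
#' judged inconclusive when the configured statistic is d.
#'
#' @param fit A `cit_score` object.
#' @param config A [cit_judgment_config] with `mode = "known_solution"`, or
#'   the string `"both"` to apply the conjunctive d-and-p rule at the strict
#'   presets.
#' @return A `cit_judgment`.
#' @export
judge_cit <- function(fit, config = cit_preset("known_d")) {
  stopifnot(inherits(fit, "cit_score"))
  if (identical(config, "both"))
    return(judge_both(coef(fit)[["d"]], coef(fit)[["p"]]))
  stopifnot(inherits(config, "cit_judgment_config"))
  value <- coef(fit)[[config$statistic]]
  if (is.na(value))
    return(new_judgment("inconclusive", config$statistic, config, NA_real_))
  judge_known(value, config)
}
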