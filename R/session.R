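#' Default autonomic measure directions
#'
#' The conventional response directions of the four standard CIT measures:
#' a recognized item elicits a *larger* skin conductance response (SCR,
#' direction `+1`) but a *smaller* heart rate (HR), respiration line length
#' (RLL) and normalized pulse volume (NPV) (direction `-1`). Effect sizes and
#' randomization ranks for `-1` measures are orientation-corrected so that a
#' positive d (small p) always means "responded in the expected direction to
#' the relevant item".
#'
#' @return Named numeric vector of `+1`/`-1` directions.
#' @export
#' @examples
#' cit_default_directions()
cit_default_directions <- function() {
  c(SCR = 1, HR = -1, RLL = -1, NPV = -1)
}

#' Construct a CIT session
#'
#' A session holds the scalar responses of one examinee to one CIT question:
#' for each recorded autonomic measure, an item-by-repetition matrix of
#' per-presentation responses (one scalar per presentation, after upstream
#' signal preprocessing). A measure is either entirely present (a complete
#' grid) or entirely absent -- e.g. skin conductance is dropped for
#' electrodermal non-responders; partially missing cells are rejected.
#'
#' @param responses Named list of numeric matrices, one per measure, each
#'   `n_items` x `n_reps` (rows = items in presentation-list order, columns =
#'   repetition blocks). All matrices must share dimensions and contain no
#'   missing values.
#' @param items Character vector of item labels, length `n_items`. Defaults to
#'   the rownames of the first matrix, or `item1..itemK`.
#' @param relevant The designated crime-relevant item, as a label or a 1-based
#'   index, or `NULL` for a searching CIT where the relevant item is unknown.
#' @param directions Named numeric vector of `+1`/`-1` expected response
#'   directions. Entries for measures not covered by
#'   [cit_default_directions()] must be supplied here; defaults are filled in
#'   for the four standard measures.
#' @param session_id Character identifier for reports.
#'
#' @return An object of class `cit_session`: a list with elements `items`,
#'   `responses`, `directions`, `relevant` (integer index or `NA`),
#'   `n_items`, `n_reps`, `session_id`.
#' @export
#' @examples
#' m <- matrix(rnorm(25), 5, 5)
#' s <- cit_session(list(SCR = m), items = paste0("item", 1:5), relevant = 2)
#' s
cit_session <- function(responses, items = NULL, relevant = NULL,
                        directions = NULL, session_id = "session") {
  if (!is.list(responses) || length(responses) < 1L)
    stop("at least one measure must be present", call. = FALSE)
  if (is.null(names(responses)) || anyNA(names(responses)) ||
      any(names(responses) == ""))
    stop("'responses' must be a named list (one element per measure)",
         call. = FALSE)
  if (anyDuplicated(names(responses)))
    stop("duplicate measure names in 'responses'", call. = FALSE)

  responses <- lapply(responses, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(responses, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all measures must share the same item x repetition dimensions",
         call. = FALSE)
  n_items <- unname(dims[1, 1])
  n_reps <- unname(dims[2, 1])
  if (n_items < 2L) stop("a CIT needs at least 2 items", call. = FALSE)
  if (n_reps < 1L) stop("at least one repetition is required", call. = FALSE)
  if (any(vapply(responses, anyNA, logical(1))))
    stop("missing cells are not allowed: a measure is either fully present ",
         "or absent", call. = FALSE)

  if (is.null(items)) items <- rownames(responses[[1]])
  if (is.null(items)) items <- paste0("item", seq_len(n_items))
  items <- as.character(items)
  if (length(items) != n_items)
    stop("'items' must have one label per matrix row", call. = FALSE)
  if (anyDuplicated(items)) stop("item labels must be unique", call. = FALSE)
  responses <- lapply(responses, function(m) {
    dimnames(m) <- list(items, paste0("rep", seq_len(n_reps)))
    m
  })

  dirs <- cit_default_directions()
  if (!is.null(directions)) {
    if (is.null(names(directions)))
      stop("'directions' must be a named vector", call. = FALSE)
    dirs[names(directions)] <- directions
  }
  missing_dir <- setdiff(names(responses), names(dirs))
  if (length(missing_dir))
    stop("no expected response direction declared for measure(s): ",
         paste(missing_dir, collapse = ", "), call. = FALSE)
  dirs <- dirs[names(responses)]
  if (!all(dirs %in% c(-1, 1)))
    stop("directions must be +1 or -1", call. = FALSE)

  rel <- NA_integer_
  if (!is.null(relevant) && !is.na(relevant[1]) &&
      !identical(relevant, "unknown")) {
    rel <- if (is.character(relevant)) match(relevant, items)
           else as.integer(relevant)
    if (is.na(rel) || rel < 1L || rel > n_items)
      stop("'relevant' does not name a valid item", call. = FALSE)
  }

  structure(
    list(items = items, responses = responses, directions = dirs,
         relevant = rel, n_items = n_items, n_reps = n_reps,
         session_id = as.character(session_id)),
    class = "cit_session")
}

#' @export
print.cit_session <- function(x, ...) {
  rel <- if (is.na(x$relevant)) "unknown (searching CIT)"
         else sprintf("%s (item %d)", x$items[x$relevant], x$relevant)
  cat("CIT session '", x$session_id, "'\n", sep = "")
  cat("  items:      ", paste(x$items, collapse = ", "), "\n", sep = "")
  cat("  design:     ", x$n_items, " items x ", x$n_reps, " repetitions\n",
      sep = "")
  cat("  measures:   ",
      paste(sprintf("%s(%+d)", names(x$responses), x$directions),
            collapse = ", "), "\n", sep = "")
  cat("  relevant:   ", rel, "\n", sep = "")
  invisible(x)
}

# resolve a relevant-item argument against a session; errors if neither the
# argument nor the session designates one
resolve_relevant <- function(session, relevant) {
  if (is.null(relevant)) {
    if (is.na(session$relevant))
      stop("no relevant item designated: pass 'relevant' or use the ",
           "searching-CIT functions", call. = FALSE)
    return(session$relevant)
  }
  rel <- if (is.character(relevant)) match(relevant, session$items)
         else as.integer(relevant)
  if (is.na(rel) || rel < 1L || rel > session$n_items)
    stop("'relevant' does not name a valid item", call. = FALSE)
  rel
}
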