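#' Read a CIT session from a long-format CSV file
#'
#' The on-disk format is a plain CSV with columns
#' `measure,item,repetition,value` preceded by a small commented header that
#' carries the session metadata the table itself cannot:
#'
#' ```
#' # cit_session: s001
#' # items: ring,necklace,watch,bracelet,earring
#' # relevant: ring
#' # directions: SCR=1,HR=-1,RLL=-1,NPV=-1
#' measure,item,repetition,value
#' SCR,ring,1,0.5312...
#' ```
#'
#' `relevant: unknown` marks a searching CIT. Every measure present in the
#' table must form a complete item-by-repetition grid; duplicate cells,
#' ragged grids, and measures without a declared direction are format errors.
#' Values are written by [write_cit_session()] with 17 significant digits, so
#' a write/read round trip reproduces a session bit-identically.
#'
#' @param path Path to a session CSV written by [write_cit_session()] (or by
#'   hand in the same layout).
#' @return A [cit_session] object.
#' @seealso [write_cit_session()]
#' @export
read_cit_session <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    pat <- paste0("^#\\s*", key, ":\\s*")
    hit <- grep(pat, hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(pat, "", hit[1]))
  }
  session_id <- get_field("cit_session")
  if (is.null(session_id)) session_id <- "session"
  items_field <- get_field("items")
  if (is.null(items_field))
    stop("session file lacks the '# items:' header line", call. = FALSE)
  items <- trimws(strsplit(items_field, ",")[[1]])
  relevant <- get_field("relevant")
  if (is.null(relevant)) relevant <- "unknown"

  directions <- NULL
  dir_field <- get_field("directions")
  if (!is.null(dir_field)) {
    pairs <- strsplit(trimws(strsplit(dir_field, ",")[[1]]), "=")
    directions <- vapply(pairs, function(p) as.numeric(p[2]), numeric(1))
    names(directions) <- vapply(pairs, function(p) trimws(p[1]), character(1))
  }

  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                         stringsAsFactors = FALSE)
  need <- c("measure", "item", "repetition", "value")
  if (!all(need %in% names(tab)))
    stop("session table must have columns measure,item,repetition,value",
         call. = FALSE)
  if (nrow(tab) == 0L) stop("session table is empty", call. = FALSE)
  bad_item <- setdiff(unique(tab$item), items)
  if (length(bad_item))
    stop("table contains item(s) absent from the '# items:' header: ",
         paste(bad_item, collapse = ", "), call. = FALSE)
  key <- paste(tab$measure, tab$item, tab$repetition, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (measure, item, repetition) cell(s) in session table",
         call. = FALSE)

  n_items <- length(items)
  responses <- lapply(split(tab, tab$measure), function(sub) {
    reps <- sort(unique(sub$repetition))
    n_reps <- length(reps)
    if (!identical(as.integer(reps), seq_len(n_reps)))
      stop("repetition indices for measure '", sub$measure[1],
           "' must be 1..n_reps", call. = FALSE)
    if (nrow(sub) != n_items * n_reps)
      stop("ragged grid: measure '", sub$measure[1], "' has ", nrow(sub),
           " cells, expected ", n_items * n_reps, call. = FALSE)
    m <- matrix(NA_real_, n_items, n_reps)
    m[cbind(match(sub$item, items), sub$repetition)] <- sub$value
    if (anyNA(m))
      stop("ragged grid: measure '", sub$measure[1],
           "' does not cover every (item, repetition) cell", call. = FALSE)
    m
  })
  # split() orders by factor level; restore first-appearance order
  responses <- responses[unique(tab$measure)]

  cit_session(responses, items = items, relevant = relevant,
              directions = directions, session_id = session_id)
}

#' Write a CIT session to a long-format CSV file
#'
#' @param session A [cit_session] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_cit_session()] for the file layout.
#' @export
write_cit_session <- function(session, path) {
  stopifnot(inherits(session, "cit_session"))
  rel <- if (is.na(session$relevant)) "unknown"
         else session$items[session$relevant]
  hdr <- c(
    paste0("# cit_session: ", session$session_id),
    paste0("# items: ", paste(session$items, collapse = ",")),
    paste0("# relevant: ", rel),
    paste0("# directions: ",
           paste(sprintf("%s=%d", names(session$directions),
                         as.integer(session$directions)), collapse = ",")))
  rows <- unlist(lapply(names(session$responses), function(ms) {
    m <- session$responses[[ms]]
    idx <- expand.grid(i = seq_len(nrow(m)), r = seq_len(ncol(m)))
    sprintf("%s,%s,%d,%.17g", ms, session$items[idx$i], idx$r,
            m[cbind(idx$i, idx$r)])
  }))
  writeLines(c(hdr, "measure,item,repetition,value", rows), path)
  invisible(path)
}
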