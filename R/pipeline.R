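#' Run the full simulate-score-judge-evaluate pipeline
#'
#' Drives the whole toolchain from one declarative configuration:
#' simulates a labeled cohort, scores every session with the integrated d,
#' randomization p and Lykken score, judges each session at a threshold
#' preset, and evaluates cohort operating characteristics (three-way rates,
#' AUCs, binned score tables, and -- in searching mode -- the two-type
#' false-positive decomposition). All outputs are plain CSV/JSON and the
#' run is reproducible from the logged configuration and seed.
#'
#' @param config A named list (or path to a JSON file holding one) with any
#'   of the fields: `n_recognizing`, `n_unrecognizing`, `n_items`,
#'   `n_reps`, `delta`, `habituation`, `rho`, `nonresponder_prob`,
#'   `nonresponder_mode`, `noise_sd` (passed to [cit_synthetic_config()]);
#'   `B` (relabelings, default 1000); `seed`; `mode` (`"known_solution"`
#'   or `"searching"`); `preset_d`, `preset_p` (preset names for
#'   [cit_preset()], defaulting to the strict presets of the mode);
#'   `write_sessions` (logical, default `FALSE`).
#' @param out_dir Output directory (created if needed); `NULL` to skip all
#'   file output and just return the results.
#' @return (Invisibly) a list with `scores` (data frame, one row per
#'   session), `judgments_d`, `judgments_p` (label vectors),
#'   `evaluation` (the report list written to `report.json`), `truth`, and
#'   `config`.
#' @export
#' @examples
#' res <- run_cit_pipeline(list(n_recognizing = 5, n_unrecognizing = 5,
#'                              B = 100, seed = 1), out_dir = NULL)
#' res$evaluation$d$rates
run_cit_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) stop("'config' must be a list or a JSON file path",
                             call. = FALSE)
  get <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  mode <- match.arg(get("mode", "known_solution"),
                    c("known_solution", "searching"))
  searching <- mode == "searching"
  B <- get("B", 1000)
  seed <- get("seed", NULL)
  delta <- get("delta", cit_reference_delta())
  if (!is.null(config$delta) && is.list(config$delta))
    delta <- unlist(config$delta)
  sim_cfg <- cit_synthetic_config(
    n_recognizing = get("n_recognizing", 80),
    n_unrecognizing = get("n_unrecognizing", 72),
    n_items = get("n_items", 5), n_reps = get("n_reps", 5),
    delta = delta, habituation = get("habituation", 0),
    rho = get("rho", 0.3),
    nonresponder_prob = get("nonresponder_prob", 0.25),
    nonresponder_mode = get("nonresponder_mode", "drop"),
    noise_sd = get("noise_sd", 1), seed = seed)
  cfg_d <- cit_preset(get("preset_d",
                          if (searching) "searching_d" else "known_d"))
  cfg_p <- cit_preset(get("preset_p",
                          if (searching) "searching_p" else "known_p"))

  cohort <- simulate_cit_cohort(sim_cfg, searching = searching)
  n <- length(cohort$sessions)
  rows <- vector("list", n)
  jd <- jp <- character(n)
  item_d <- item_p <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    s <- cohort$sessions[[k]]
    s_seed <- child_seed(if (is.null(seed)) 0L else seed, 100000L + k)
    if (searching) {
      sc <- searching_scores(s, B = B, seed = s_seed)
      jdg_d <- judge_searching(sc, cfg_d)
      jdg_p <- judge_searching(sc, cfg_p)
      rows[[k]] <- data.frame(
        session_id = s$session_id,
        integrated_d = max(sc$integrated_d, na.rm = TRUE),
        integrated_p = min(sc$integrated_p),
        lykken = NA_real_)
      jd[k] <- jdg_d$label; jp[k] <- jdg_p$label
      item_d[k] <- jdg_d$identified_item
      item_p[k] <- jdg_p$identified_item
    } else {
      fit <- cit_score(s, B = B, seed = s_seed)
      cf <- coef(fit)
      rows[[k]] <- data.frame(session_id = s$session_id,
                              integrated_d = cf[["d"]],
                              integrated_p = cf[["p"]],
                              lykken = cf[["lykken"]])
      jd[k] <- judge_cit(fit, cfg_d)$label
      jp[k] <- judge_cit(fit, cfg_p)$label
    }
  }
  scores <- do.call(rbind, rows)
  truth <- cohort$truth

  evaluation <- list(
    mode = mode, n_sessions = n,
    d = c(list(auc = if (all(is.na(scores$integrated_d))) NA_real_ else
                 roc_auc(scores$integrated_d, truth$recognizing)),
          rates = list(cohort_rates(jd, truth$recognizing)[1:3])),
    p = c(list(auc = roc_auc(scores$integrated_p, truth$recognizing,
                             direction = "less")),
          rates = list(cohort_rates(jp, truth$recognizing)[1:3])),
    bins_d = binned_recognition_ratios(scores$integrated_d,
                                       truth$recognizing, type = "d"),
    bins_p = binned_recognition_ratios(scores$integrated_p,
                                       truth$recognizing, type = "p"))
  if (!searching && !all(is.na(scores$lykken)))
    evaluation$lykken <- list(auc = roc_auc(scores$lykken,
                                            truth$recognizing))
  if (searching) {
    evaluation$searching_d <- searching_error_decomposition(
      data.frame(label = jd, identified_item = item_d),
      truth$recognizing, truth$relevant_item)
    evaluation$searching_p <- searching_error_decomposition(
      data.frame(label = jp, identified_item = item_p),
      truth$recognizing, truth$relevant_item)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(truth,
                           judgment_d = jd, judgment_p = jp,
                           identified_item_d = item_d,
                           identified_item_p = item_p),
                     file.path(out_dir, "judgments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(evaluation, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    logged <- c(config, list(mode = mode, B = B,
                             delta = as.list(sim_cfg$delta)))
    logged <- logged[!duplicated(names(logged))]
    jsonlite::write_json(logged, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    if (isTRUE(get("write_sessions", FALSE))) {
      sess_dir <- file.path(out_dir, "sessions")
      dir.create(sess_dir, showWarnings = FALSE)
      for (s in cohort$sessions)
        write_cit_session(s, file.path(sess_dir,
                                       paste0(s$session_id, ".csv")))
    }
  }
  invisible(list(scores = scores, judgments_d = jd, judgments_p = jp,
                 identified_item_d = item_d, identified_item_p = item_p,
                 evaluation = evaluation, truth = truth, config = config))
}
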