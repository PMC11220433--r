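#' Run a pipeline command and write machine-readable reports
#'
#' Single programmatic entry point wiring the analysis modules into the
#' simulate -> describe -> signal -> lasso -> changepoint workflow. Each
#' command validates its configuration before any computation, reads the
#' input corpus (except `simulate`, which generates one), applies the
#' common filter block, runs the analysis and writes JSON-first reports
#' (with CSV mirrors for tabular payloads) into `out_dir`, together with an
#' echo of the resolved configuration and seed so any report can be
#' regenerated identically.
#'
#' Config structure (YAML file or list): top-level `input` (corpus CSV
#' path; not used by `simulate`), optional `filter` block (`forums`,
#' `date_from`, `date_to`, `atc`, `meddra`), and one block per command —
#' `simulate` (fields of [simulation_config()]), `signal` (`measure`,
#' `drug`, `ade`, `zero_cell`), `lasso` (`ade`, `B`, `max_predictors`, `q`,
#' `mode`), `changepoint` (`unit`, `drug`, `ade`, `n_bootstrap`,
#' `confidence_threshold`, `min_segment_length`).
#'
#' A thin command-line wrapper around this function is installed at
#' `system.file("exec", "phv", package = "pvsignal")`.
#'
#' @param command One of `"simulate"`, `"describe"`, `"signal"`, `"lasso"`,
#'   `"changepoint"`.
#' @param config A list or path to a YAML file.
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed for the stochastic commands.
#' @param vocabulary A [pv_vocabulary()]; defaults to the bundled toy
#'   vocabulary.
#' @return Character vector of written file paths, invisibly.
#' @export
pv_run <- function(command, config = list(), out_dir = ".", seed = 1,
                   vocabulary = load_toy_vocabulary()) {
  commands <- c("simulate", "describe", "signal", "lasso", "changepoint")
  if (length(command) != 1L || !command %in% commands) {
    abort(paste0("unknown command: '", paste(command, collapse = " "),
                 "'. Use one of: ", paste(commands, collapse = ", ")),
          class = "pv_config_error")
  }
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config), class = "pv_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path",
                              class = "pv_config_error")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # all configuration problems are raised here, before any computation
  if (command != "simulate") {
    if (is.null(config$input)) abort("config$input (corpus CSV) is required",
                                     class = "pv_config_error")
    if (!file.exists(config$input)) {
      abort(paste0("input file not found: ", config$input), class = "pv_config_error")
    }
  }
  inform(paste0("[pvsignal] command=", command, " seed=", seed,
                " out_dir=", normalizePath(out_dir)))
  written <- character()
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    written <<- c(written, p)
  }
  emit_csv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p, na = "")
    written <<- c(written, p)
  }
  emit_json(list(command = command, seed = seed, config = config),
            "run_config.json")

  if (command == "simulate") {
    sc <- config$simulate %||% list()
    cfg <- do.call(simulation_config, sc)
    sim <- simulate_corpus(cfg, seed = seed)
    write_annotations(sim$corpus, file.path(out_dir, "corpus.csv"))
    written <- c(written, file.path(out_dir, "corpus.csv"))
    emit_json(list(
      changepoint_month = sim$truth$changepoint_month,
      n_couple_events = sim$truth$n_couple_events,
      association = sim$truth$association,
      pair_cells = sim$truth$pair_cells,
      monthly_couples = dplyr::mutate(sim$truth$monthly_couples,
                                      month = format(.data$month, "%Y-%m"))
    ), "truth.json")
    return(invisible(written))
  }

  corpus <- read_annotations(config$input)
  fb <- config$filter %||% list()
  date_range <- if (!is.null(fb$date_from) || !is.null(fb$date_to)) {
    c(fb$date_from %||% as.character(min(corpus$date)),
      fb$date_to %||% as.character(max(corpus$date)))
  }
  corpus <- filter_corpus(corpus, forums = fb$forums, date_range = date_range,
                          atc = fb$atc, meddra = fb$meddra,
                          vocabulary = vocabulary)

  if (command == "describe") {
    smry <- corpus_summary(corpus)
    rankings <- list(
      forum = rank_by(corpus, "forum_name"),
      pt = rank_by(corpus, "meddra_code", vocabulary = vocabulary),
      soc = rank_by(corpus, "soc", vocabulary = vocabulary)
    )
    series <- monthly_series(corpus, unit = "couples")
    emit_json(list(summary = as.list(smry),
                   rankings = rankings,
                   monthly_couples = dplyr::mutate(series, month = format(.data$month, "%Y-%m"))),
              "describe.json")
    emit_csv(smry, "summary.csv")
    emit_csv(rankings$forum, "ranking_forum.csv")
    emit_csv(rankings$pt, "ranking_pt.csv")
    emit_csv(series, "monthly_couples.csv")
  } else if (command == "signal") {
    sc <- config$signal %||% list()
    if (is.null(sc$drug) || is.null(sc$ade)) {
      abort("signal config needs 'drug' and 'ade' selectors", class = "pv_config_error")
    }
    measure <- sc$measure %||% "prr"
    zero_cell <- sc$zero_cell %||% "strict"
    tab <- build_contingency(corpus, drug = sc$drug, ade = sc$ade,
                             vocabulary = vocabulary)
    est <- if (measure == "prr") prr(tab, zero_cell) else ror(tab, zero_cell)
    series <- cumulative_prr_series(corpus, drug = sc$drug, ade = sc$ade,
                                    vocabulary = vocabulary, measure = measure,
                                    zero_cell = zero_cell)
    emit_json(as.list(est), "signal.json")
    emit_csv(dplyr::mutate(series, month = format(.data$month, "%Y-%m")),
             "signal_series.csv")
  } else if (command == "lasso") {
    lc <- config$lasso %||% list()
    if (is.null(lc$ade)) abort("lasso config needs an 'ade' selector",
                               class = "pv_config_error")
    design <- build_design(corpus, ade = lc$ade, vocabulary = vocabulary)
    fit <- ciss_lasso(design,
                      B = lc$B %||% 250,
                      max_predictors = lc$max_predictors %||% 50,
                      q = lc$q %||% 10,
                      seed = seed,
                      mode = lc$mode %||% "coefficient")
    emit_json(list(glance = as.list(glance(fit)), retained = fit$retained,
                   drugs = tidy(fit)), "lasso.json")
    emit_csv(tidy(fit), "lasso.csv")
  } else if (command == "changepoint") {
    cc <- config$changepoint %||% list()
    series <- monthly_series(corpus, unit = cc$unit %||% "couples",
                             atc = cc$drug, meddra = cc$ade,
                             vocabulary = vocabulary)
    if (nrow(series) == 0L) abort("no events match the changepoint selection",
                                  class = "pv_empty_table")
    bps <- detect_breakpoints(series,
                              n_bootstrap = cc$n_bootstrap %||% 1000,
                              confidence_threshold = cc$confidence_threshold %||% 0.95,
                              min_segment_length = cc$min_segment_length %||% 6,
                              seed = seed)
    out <- if (nrow(bps)) dplyr::mutate(bps, month = format(.data$month, "%Y-%m")) else bps
    emit_json(list(n_breakpoints = nrow(bps), breakpoints = out), "changepoint.json")
    emit_csv(out, "changepoint.csv")
  }
  invisible(written)
}
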