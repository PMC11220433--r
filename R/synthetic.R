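#' Configure a synthetic annotation corpus
#'
#' Builds and validates the generative model for [simulate_corpus()]. Each
#' post independently draws a forum, a calendar month within the period, a
#' set of mentioned drugs (one Bernoulli per catalog drug) and a set of
#' mentioned ADEs. ADE presence follows a logistic model: the log-odds of
#' ADE `j` are its baseline log-odds plus `log(rho_ij)` for every mentioned
#' drug `i`, so an association multiplier `rho > 1` makes the ADE more
#' likely exactly when the drug is present — the world in which both
#' disproportionality and the subsampling lasso have a recoverable target.
#' `rho = 1` everywhere (the default) is exact independence.
#'
#' Emitted annotation lines follow the 12-column corpus schema: every
#' co-mentioned (drug, ADE) pair yields couple lines (both codes present),
#' drugs mentioned in a post without any ADE yield drug-only lines, and
#' ADEs without any drug yield ADE-only lines. Verbatim text fields are
#' lowercase variants of the catalog labels: non-empty, but carrying no
#' linguistic content.
#'
#' @param n_posts Number of posts to generate.
#' @param start_month First month of the period, `"YYYY-MM"` or a Date.
#' @param n_months Number of calendar months in the period.
#' @param forum_weights Named numeric vector of forum sampling
#'   probabilities; must sum to 1.
#' @param drug_catalog Data frame `atc_code`, `label`, `p_mention`
#'   (per-post mention probability). Defaults to 8 drugs from the bundled
#'   toy ATC table with mention probabilities between 0.8% and 6%.
#' @param ade_catalog Data frame `meddra_code`, `label`, `p_base`
#'   (baseline per-post probability). Defaults to 8 PTs from the bundled
#'   toy MedDRA table with baselines between 1% and 8%.
#' @param association Data frame `atc_code`, `meddra_code`, `rho` giving
#'   odds multipliers for designed drug-ADE pairs; omitted pairs have
#'   `rho = 1`.
#' @param couples_per_post Mean line multiplicity of an emitted couple: each
#'   co-mentioned pair produces `1 + Poisson(couples_per_post - 1)` couple
#'   lines, so the default 1 emits each couple once and larger values model
#'   users repeating a drug-ADE pair within a post.
#' @param rate_shift Optional temporal shift: a list with `month` (1-based
#'   month index tau within the period), `multiplier`, and `target` —
#'   `"volume"` (post volume from tau on), `"drug"` with `atc_code` (that
#'   drug's mention odds from tau on), or `"pair"` with `atc_code` and
#'   `meddra_code` (that pair's association odds from tau on).
#' @return Validated config object of class `pv_sim_config`.
#' @examples
#' cfg <- simulation_config(n_posts = 500, association = data.frame(
#'   atc_code = "H03AA01", meddra_code = "10016256", rho = 5))
#' sim <- simulate_corpus(cfg, seed = 7)
#' corpus_summary(sim$corpus)
#' @export
simulation_config <- function(n_posts,
                              start_month = "2017-01",
                              n_months = 24,
                              forum_weights = c(
                                "Vivre sans thyroide" = 0.35,
                                "Doctissimo Sante" = 0.25,
                                "Atoute" = 0.15,
                                "Carenity" = 0.15,
                                "Allo docteurs" = 0.10
                              ),
                              drug_catalog = default_drug_catalog(),
                              ade_catalog = default_ade_catalog(),
                              association = NULL,
                              couples_per_post = 1,
                              rate_shift = NULL) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (!is_scalar_number(n_posts) || n_posts < 0 || n_posts != floor(n_posts)) {
    note("n_posts: must be a nonnegative integer")
  }
  start <- if (inherits(start_month, "Date")) {
    first_of_month(start_month)
  } else {
    suppressWarnings(lubridate::ym(as.character(start_month), quiet = TRUE))
  }
  if (is.na(start)) note("start_month: must be 'YYYY-MM' or a Date")
  if (!is_scalar_number(n_months) || n_months < 1) note("n_months: must be >= 1")

  if (is.null(names(forum_weights)) || any(!nzchar(names(forum_weights)))) {
    note("forum_weights: must be a named vector")
  }
  if (any(forum_weights < 0 | forum_weights > 1)) {
    note("forum_weights: probabilities must be in [0, 1]")
  } else if (abs(sum(forum_weights) - 1) > 1e-9) {
    note("forum_weights: must sum to 1")
  }

  drug_catalog <- as_tibble(drug_catalog)
  if (!all(c("atc_code", "label", "p_mention") %in% names(drug_catalog))) {
    note("drug_catalog: needs columns atc_code, label, p_mention")
  } else {
    if (!all(is_atc_code(drug_catalog$atc_code))) note("drug_catalog: invalid ATC code(s)")
    if (any(drug_catalog$p_mention < 0 | drug_catalog$p_mention > 1)) {
      note("drug_catalog: p_mention must be in [0, 1]")
    }
  }
  ade_catalog <- as_tibble(ade_catalog)
  if (!all(c("meddra_code", "label", "p_base") %in% names(ade_catalog))) {
    note("ade_catalog: needs columns meddra_code, label, p_base")
  } else {
    if (!all(is_pt_code(ade_catalog$meddra_code))) note("ade_catalog: invalid PT code(s)")
    if (any(ade_catalog$p_base < 0 | ade_catalog$p_base > 1)) {
      note("ade_catalog: p_base must be in [0, 1]")
    }
  }
  if (is.null(association)) {
    association <- tibble(atc_code = character(), meddra_code = character(),
                          rho = numeric())
  }
  association <- as_tibble(association)
  if (!all(c("atc_code", "meddra_code", "rho") %in% names(association))) {
    note("association: needs columns atc_code, meddra_code, rho")
  } else if (nrow(association)) {
    if (any(association$rho < 0)) note("association: rho must be >= 0")
    if (!all(association$atc_code %in% drug_catalog$atc_code)) {
      note("association: atc_code(s) not in drug_catalog")
    }
    if (!all(association$meddra_code %in% ade_catalog$meddra_code)) {
      note("association: meddra_code(s) not in ade_catalog")
    }
  }
  if (!is_scalar_number(couples_per_post) || couples_per_post < 1) {
    note("couples_per_post: must be >= 1")
  }
  if (!is.null(rate_shift)) {
    if (!is.list(rate_shift) ||
        !all(c("month", "multiplier", "target") %in% names(rate_shift))) {
      note("rate_shift: needs fields month, multiplier, target")
    } else {
      if (!is_scalar_number(rate_shift$month) ||
          rate_shift$month < 1 ||
          (is_scalar_number(n_months) && rate_shift$month > n_months)) {
        note("rate_shift$month: must be a month index within the period")
      }
      if (!is_scalar_number(rate_shift$multiplier) || rate_shift$multiplier < 0) {
        note("rate_shift$multiplier: must be >= 0")
      }
      if (!rate_shift$target %in% c("volume", "drug", "pair")) {
        note("rate_shift$target: must be 'volume', 'drug' or 'pair'")
      } else if (rate_shift$target == "drug" && is.null(rate_shift$atc_code)) {
        note("rate_shift: target 'drug' needs field atc_code")
      } else if (rate_shift$target == "pair" &&
                 (is.null(rate_shift$atc_code) || is.null(rate_shift$meddra_code))) {
        note("rate_shift: target 'pair' needs fields atc_code and meddra_code")
      }
    }
  }
  if (length(problems)) {
    abort(paste0("invalid simulation config:\n", paste0("- ", problems, collapse = "\n")),
          class = "pv_config_error")
  }
  structure(
    list(n_posts = as.integer(n_posts), start_month = start,
         n_months = as.integer(n_months), forum_weights = forum_weights,
         drug_catalog = drug_catalog, ade_catalog = ade_catalog,
         association = association, couples_per_post = couples_per_post,
         rate_shift = rate_shift),
    class = "pv_sim_config"
  )
}

#' @rdname simulation_config
#' @export
default_drug_catalog <- function() {
  tibble(
    atc_code = c("H03AA01", "N06AX22", "M03BX01", "N06AX21",
                 "A10BX04", "M05BX03", "N02BE01", "M01AE01"),
    label = c("Levothyroxine sodium", "Agomelatine", "Baclofen", "Duloxetine",
              "Exenatide", "Strontium ranelate", "Paracetamol", "Ibuprofen"),
    p_mention = c(0.050, 0.020, 0.015, 0.020, 0.008, 0.010, 0.060, 0.040)
  )
}

#' @rdname simulation_config
#' @export
default_ade_catalog <- function() {
  tibble(
    meddra_code = c("10016256", "10033371", "10019211", "10013573",
                    "10028813", "10022437", "10033557", "10048061"),
    label = c("Fatigue", "Pain", "Headache", "Dizziness",
              "Nausea", "Insomnia", "Palpitations", "Weight decreased"),
    p_base = c(0.080, 0.070, 0.050, 0.030, 0.030, 0.020, 0.010, 0.015)
  )
}

#' Simulate an annotation corpus with known ground truth
#'
#' Draws a corpus under the generative model of [simulation_config()] and
#' returns it with everything needed for recovery checks: the designed
#' association multipliers, the true shift month (if any), the realized
#' monthly couple counts and the realized contingency cells of every
#' designed pair. Identical config and seed reproduce the corpus exactly.
#'
#' @param config A `pv_sim_config` from [simulation_config()].
#' @param seed Integer seed.
#' @return List with `corpus` (annotation tibble in the canonical schema)
#'   and `truth` (list: `association`, `changepoint_month` — index and Date
#'   or `NULL`, `monthly_couples`, `pair_cells`, `n_couple_events`).
#' @export
simulate_corpus <- function(config, seed = 1) {
  if (!inherits(config, "pv_sim_config")) {
    abort("`config` must come from simulation_config()", class = "pv_config_error")
  }
  months_all <- seq(config$start_month, by = "month", length.out = config$n_months)
  empty <- tibble(
    forum_name = character(), post_id = character(), date = as.Date(character()),
    time = character(), ade_verbatim = character(), ade_normalized = character(),
    cui = character(), meddra_code = character(), drug_verbatim = character(),
    drug_normalized = character(), active_ingredient = character(),
    atc_code = character()
  )
  if (config$n_posts == 0L) {
    return(list(corpus = empty, truth = list(
      association = config$association, changepoint_month = NULL,
      monthly_couples = tibble(month = months_all, n = 0L),
      pair_cells = tibble(atc_code = character(), meddra_code = character(),
                          rho = numeric(), a = integer(), b = integer(),
                          c = integer(), d = integer()),
      n_couple_events = 0L
    )))
  }

  withr::with_seed(as.integer(seed) %% 2147483647L, {
    n <- config$n_posts
    shift <- config$rate_shift
    nd <- nrow(config$drug_catalog)
    na_ <- nrow(config$ade_catalog)

    month_w <- rep(1, config$n_months)
    if (!is.null(shift) && shift$target == "volume") {
      month_w[shift$month:config$n_months] <- shift$multiplier
    }
    month_idx <- sample.int(config$n_months, n, replace = TRUE, prob = month_w)
    after <- if (!is.null(shift)) month_idx >= shift$month else rep(FALSE, n)
    forum <- sample(names(config$forum_weights), n, replace = TRUE,
                    prob = config$forum_weights)

    # drug mentions: Bernoulli per catalog drug, optional odds surge after tau
    pmat <- matrix(rep(config$drug_catalog$p_mention, each = n), nrow = n)
    if (!is.null(shift) && shift$target == "drug") {
      j <- match(shift$atc_code, config$drug_catalog$atc_code)
      odds <- pmat[after, j] / (1 - pmat[after, j]) * shift$multiplier
      pmat[after, j] <- odds / (1 + odds)
    }
    drug_present <- matrix(runif(n * nd) < pmat, nrow = n)

    # ADE mentions: baseline log-odds + log(rho) per mentioned drug
    logit <- matrix(rep(qlogis(config$ade_catalog$p_base), each = n), nrow = n)
    assoc <- config$association
    if (nrow(assoc)) {
      for (k in seq_len(nrow(assoc))) {
        i <- match(assoc$atc_code[k], config$drug_catalog$atc_code)
        j <- match(assoc$meddra_code[k], config$ade_catalog$meddra_code)
        rho <- rep(assoc$rho[k], n)
        if (!is.null(shift) && shift$target == "pair" &&
            shift$atc_code == assoc$atc_code[k] &&
            shift$meddra_code == assoc$meddra_code[k]) {
          rho[after] <- rho[after] * shift$multiplier
        }
        logit[, j] <- logit[, j] + drug_present[, i] * log(rho)
      }
    }
    if (!is.null(shift) && shift$target == "pair" &&
        !any(assoc$atc_code == shift$atc_code & assoc$meddra_code == shift$meddra_code)) {
      i <- match(shift$atc_code, config$drug_catalog$atc_code)
      j <- match(shift$meddra_code, config$ade_catalog$meddra_code)
      logit[after, j] <- logit[after, j] + drug_present[after, i] * log(shift$multiplier)
    }
    ade_present <- matrix(runif(n * na_) < plogis(logit), nrow = n)

    post_id <- sprintf("P%06d", seq_len(n))
    day <- sample.int(28, n, replace = TRUE)
    date <- months_all[month_idx] + (day - 1)
    secs <- sample.int(86400, n, replace = TRUE) - 1L
    time <- sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)

    dcat <- config$drug_catalog
    acat <- config$ade_catalog
    acat$cui <- sprintf("C%07d", 15000 + seq_len(na_))
    any_drug <- rowSums(drug_present) > 0
    any_ade <- rowSums(ade_present) > 0

    lines <- list()
    # couple lines: every co-mentioned (drug, ADE) pair
    for (i in seq_len(nd)) {
      for (j in seq_len(na_)) {
        p <- which(drug_present[, i] & ade_present[, j])
        if (!length(p)) next
        reps <- if (config$couples_per_post > 1) {
          1L + rpois(length(p), config$couples_per_post - 1)
        } else rep(1L, length(p))
        p <- rep(p, reps)
        lines[[length(lines) + 1L]] <- tibble(
          forum_name = forum[p], post_id = post_id[p], date = date[p],
          time = time[p],
          ade_verbatim = tolower(acat$label[j]), ade_normalized = acat$label[j],
          cui = acat$cui[j], meddra_code = acat$meddra_code[j],
          drug_verbatim = tolower(dcat$label[i]),
          drug_normalized = toupper(dcat$label[i]),
          active_ingredient = dcat$label[i], atc_code = dcat$atc_code[i]
        )
      }
    }
    # drug-only lines: mentioned drugs in posts without any ADE
    for (i in seq_len(nd)) {
      p <- which(drug_present[, i] & !any_ade)
      if (!length(p)) next
      lines[[length(lines) + 1L]] <- tibble(
        forum_name = forum[p], post_id = post_id[p], date = date[p],
        time = time[p],
        ade_verbatim = NA_character_, ade_normalized = NA_character_,
        cui = NA_character_, meddra_code = NA_character_,
        drug_verbatim = tolower(dcat$label[i]),
        drug_normalized = toupper(dcat$label[i]),
        active_ingredient = dcat$label[i], atc_code = dcat$atc_code[i]
      )
    }
    # ADE-only lines: mentioned ADEs in posts without any drug
    for (j in seq_len(na_)) {
      p <- which(ade_present[, j] & !any_drug)
      if (!length(p)) next
      lines[[length(lines) + 1L]] <- tibble(
        forum_name = forum[p], post_id = post_id[p], date = date[p],
        time = time[p],
        ade_verbatim = tolower(acat$label[j]), ade_normalized = acat$label[j],
        cui = acat$cui[j], meddra_code = acat$meddra_code[j],
        drug_verbatim = NA_character_, drug_normalized = NA_character_,
        active_ingredient = NA_character_, atc_code = NA_character_
      )
    }
    # posts with no catalog mention still carry an unnormalized complaint
    # (verbatim only, no codes), as real annotator output does; this keeps
    # the corpus post universe complete, so per-post models see the true
    # baseline rather than a sample conditioned on having a normalized
    # mention
    p <- which(!any_drug & !any_ade)
    if (length(p)) {
      chatter <- c("stress", "mal de dos", "rhume", "moral bas", "insomnie legere")
      lines[[length(lines) + 1L]] <- tibble(
        forum_name = forum[p], post_id = post_id[p], date = date[p],
        time = time[p],
        ade_verbatim = sample(chatter, length(p), replace = TRUE),
        ade_normalized = NA_character_, cui = NA_character_,
        meddra_code = NA_character_,
        drug_verbatim = NA_character_, drug_normalized = NA_character_,
        active_ingredient = NA_character_, atc_code = NA_character_
      )
    }
    corpus <- if (length(lines)) {
      dplyr::arrange(dplyr::bind_rows(lines), .data$post_id, .data$atc_code,
                     .data$meddra_code)
    } else empty

    truth <- ground_truth(corpus, config, months_all)
    list(corpus = corpus, truth = truth)
  })
}

ground_truth <- function(corpus, config, months_all) {
  cp <- is_couple(corpus)
  couples <- corpus[cp, ]
  monthly <- tibble(month = months_all)
  cm <- first_of_month(couples$date)
  monthly$n <- vapply(months_all, function(m) sum(cm == m), integer(1))
  cells <- if (nrow(config$association) == 0L) {
    tibble(atc_code = character(), meddra_code = character(), rho = numeric(),
           a = integer(), b = integer(), c = integer(), d = integer())
  } else purrr::pmap_dfr(config$association, function(atc_code, meddra_code, rho) {
    dm <- couples$atc_code == atc_code
    em <- couples$meddra_code == meddra_code
    tibble(atc_code = atc_code, meddra_code = meddra_code, rho = rho,
           a = sum(dm & em), b = sum(dm & !em), c = sum(!dm & em),
           d = sum(!dm & !em))
  })
  shift <- config$rate_shift
  list(
    association = config$association,
    changepoint_month = if (!is.null(shift)) {
      list(index = shift$month, month = months_all[shift$month],
           target = shift$target, multiplier = shift$multiplier)
    } else NULL,
    monthly_couples = monthly,
    pair_cells = cells,
    n_couple_events = sum(cp)
  )
}

#' Packaged thyroid-drug surge scenario
#'
#' A 50-month corpus built for documentation and integration checks: one
#' dominant thyroid-community forum carrying about 82% of posts, a
#' levothyroxine product (ATC H03AA01) whose mention rate surges fivefold at
#' month 25, and an elevated association (odds multiplier 4) between that
#' drug and the tiredness preferred term (Fatigue, PT 10016256). The surge
#' makes the monthly couple counts of the pair step up mid-period — a
#' recoverable change point — while the association keeps the pair's
#' disproportionality signal positive once events accumulate.
#'
#' @param seed Integer seed.
#' @param n_posts Number of posts (default 6000, about 120 per month).
#' @return As [simulate_corpus()], plus the `config` used.
#' @export
scenario_levothyrox <- function(seed = 1, n_posts = 6000) {
  config <- simulation_config(
    n_posts = n_posts,
    start_month = "2017-01",
    n_months = 50,
    forum_weights = c(
      "Vivre sans thyroide" = 0.82,
      "Doctissimo Sante" = 0.08,
      "Atoute" = 0.04,
      "Carenity" = 0.03,
      "Allo docteurs" = 0.03
    ),
    association = tibble(atc_code = "H03AA01", meddra_code = "10016256", rho = 4),
    rate_shift = list(month = 25, multiplier = 5, target = "drug",
                      atc_code = "H03AA01")
  )
  sim <- simulate_corpus(config, seed = seed)
  sim$config <- config
  sim
}
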