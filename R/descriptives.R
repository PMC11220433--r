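#' Corpus-level descriptive summary
#'
#' Post-level quantities (`n_posts`, `n_posts_with_couple`) count distinct
#' post ids; annotation-level quantities count lines. A drug (ADE) annotation
#' is any line with a drug (ADE) verbatim; a normalized couple is a line
#' carrying both a MedDRA PT code and an ATC code.
#'
#' @inheritParams write_annotations
#' @return One-row tibble with `n_posts`, `n_annotation_lines`,
#'   `n_drug_annotations`, `n_ade_annotations`, `n_normalized_couples`,
#'   `n_posts_with_couple`, `pct_posts_with_couple` (percent, 2 decimals,
#'   half-up; 0 for an empty corpus).
#' @examples
#' corpus <- simulate_corpus(simulation_config(n_posts = 100), seed = 1)$corpus
#' corpus_summary(corpus)
#' @export
corpus_summary <- function(corpus) {
  corpus <- check_corpus(corpus)
  cp <- is_couple(corpus)
  n_posts <- dplyr::n_distinct(corpus$post_id)
  n_pwc <- dplyr::n_distinct(corpus$post_id[cp])
  tibble(
    n_posts = n_posts,
    n_annotation_lines = nrow(corpus),
    n_drug_annotations = sum(!is.na(corpus$drug_verbatim)),
    n_ade_annotations = sum(!is.na(corpus$ade_verbatim)),
    n_normalized_couples = sum(cp),
    n_posts_with_couple = n_pwc,
    pct_posts_with_couple = if (n_posts > 0) round_half_up(100 * n_pwc / n_posts, 2) else 0
  )
}

#' Ranked count distribution with cumulative frequencies
#'
#' `rank_by()` counts annotation lines of a corpus grouped by a key and
#' returns them sorted by decreasing count (ties broken lexicographically by
#' label), with the cumulative percentage of the full total — computed before
#' any top-n truncation, so a truncated table keeps the same cumulative
#' column as the full one. `ranked_distribution()` builds the same structure
#' from an already-counted label/count table.
#'
#' @inheritParams filter_corpus
#' @param key One of `"forum_name"`, `"meddra_code"`, `"atc_code"`, `"soc"`
#'   (system organ class; requires `vocabulary`). For the code keys, lines
#'   without the code are excluded and labels are taken from `vocabulary`
#'   when available.
#' @param top_n Optional: keep only the first `top_n` rows after ranking.
#' @return Tibble with columns `label`, `n`, `cumulative_pct` (2 decimals,
#'   half-up) and attribute `total` (full total before truncation).
#' @examples
#' ranked_distribution(data.frame(label = c("A", "B", "C"), n = c(2, 1, 1)))
#' @export
rank_by <- function(corpus, key = c("forum_name", "meddra_code", "atc_code", "soc"),
                    vocabulary = NULL, top_n = NULL) {
  corpus <- check_corpus(corpus)
  key <- match.arg(key)
  if (key == "soc" && is.null(vocabulary)) {
    abort("ranking by SOC requires a vocabulary", class = "pv_selector_error")
  }
  lab <- switch(key,
    forum_name = corpus$forum_name,
    meddra_code = {
      x <- corpus$meddra_code
      if (!is.null(vocabulary)) {
        i <- match(x, vocabulary$meddra$pt_code)
        ifelse(is.na(i), x, vocabulary$meddra$pt_label[i])
      } else x
    },
    atc_code = {
      x <- corpus$atc_code
      if (!is.null(vocabulary)) {
        i <- match(x, vocabulary$atc$atc_code)
        ifelse(is.na(i), x, vocabulary$atc$label[i])
      } else x
    },
    soc = {
      i <- match(corpus$meddra_code, vocabulary$meddra$pt_code)
      vocabulary$meddra$soc[i]
    }
  )
  lab <- lab[!is.na(lab)]
  counts <- dplyr::count(tibble(label = lab), .data$label, name = "n")
  ranked_distribution(counts, top_n = top_n)
}

#' @param counts Data frame with columns `label` and `n` (nonnegative
#'   counts), e.g. a published per-forum table.
#' @rdname rank_by
#' @export
ranked_distribution <- function(counts, top_n = NULL) {
  counts <- as_tibble(counts)
  if (!all(c("label", "n") %in% names(counts))) {
    abort("`counts` must have columns label, n", class = "pv_corpus_error")
  }
  if (nrow(counts) == 0L) {
    out <- tibble(label = character(), n = integer(), cumulative_pct = numeric())
    attr(out, "total") <- 0L
    return(out)
  }
  total <- sum(counts$n)
  out <- dplyr::arrange(counts, dplyr::desc(.data$n), .data$label)
  out$cumulative_pct <- round_half_up(100 * cumsum(out$n) / total, 2)
  if (!is.null(top_n)) out <- dplyr::slice_head(out, n = top_n)
  attr(out, "total") <- total
  out
}

#' Monthly event series for a corpus selection
#'
#' Buckets a (possibly filtered) corpus into calendar months from the first
#' to the last matching date inclusive; months with no events are explicit
#' zeros. Units: `"couples"` counts normalized drug-ADE couple lines,
#' `"annotation_lines"` counts all lines, `"posts"` counts each distinct post
#' once in the month of its date.
#'
#' @inheritParams filter_corpus
#' @param unit What to count per month.
#' @param ... Passed to [filter_corpus()] (`forums`, `date_range`, `atc`,
#'   `meddra`, `vocabulary`).
#' @return Tibble with `month` (Date, first of month) and `n`; zero rows if
#'   nothing matches.
#' @export
monthly_series <- function(corpus, unit = c("couples", "annotation_lines", "posts"), ...) {
  unit <- match.arg(unit)
  corpus <- filter_corpus(corpus, ...)
  if (unit == "couples") corpus <- corpus[is_couple(corpus), ]
  if (nrow(corpus) == 0L) {
    return(tibble(month = as.Date(character()), n = integer()))
  }
  months <- month_seq(min(corpus$date), max(corpus$date))
  m <- first_of_month(corpus$date)
  n <- if (unit == "posts") {
    vapply(months, function(mm) dplyr::n_distinct(corpus$post_id[m == mm]), integer(1))
  } else {
    vapply(months, function(mm) sum(m == mm), integer(1))
  }
  tibble(month = months, n = n)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)` used to summarise annotation-module
#' performance. Vectorized; full precision is returned (round at report
#' time).
#'
#' @param precision,recall Proportions in `[0, 1]`, not both zero.
#' @return Numeric vector of F1 scores.
#' @examples
#' f1_from_pr(0.683, 0.956)
#' @export
f1_from_pr <- function(precision, recall) {
  if (!is.numeric(precision) || !is.numeric(recall) ||
      any(precision < 0 | precision > 1, na.rm = TRUE) ||
      any(recall < 0 | recall > 1, na.rm = TRUE)) {
    abort("precision and recall must be proportions in [0, 1]", class = "pv_input_error")
  }
  if (any(precision == 0 & recall == 0, na.rm = TRUE)) {
    abort("F1 is undefined when precision and recall are both zero",
          class = "pv_input_error")
  }
  2 * precision * recall / (precision + recall)
}
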