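#' Build a 2x2 contingency table of drug-ADE couple events
#'
#' Counts *events over posts*: every normalized couple line contributes
#' exactly 1 to exactly one cell, so a pair annotated several times in one
#' post is counted as many times as it occurs. Non-couple lines contribute
#' nothing. Multi-code selectors are pooled — several drugs (or ADEs)
#' selected together are treated as one new entity.
#'
#' Cells: `a` = (drug of interest, ADE of interest), `b` = (drug of
#' interest, other ADE), `c` = (other drug, ADE of interest), `d` = (other
#' drug, other ADE); `a + b + c + d` equals the number of couple events in
#' the corpus.
#'
#' @inheritParams filter_corpus
#' @param drug ATC code(s) or class prefix(es) defining the drug of interest.
#' @param ade MedDRA PT code(s) or a higher-level label (resolved through
#'   `vocabulary`) defining the ADE of interest.
#' @param count_unit `"events"` (default, the only counting rule used for
#'   routine disproportionality) counts couple lines with multiplicity;
#'   `"posts"` is a sensitivity-analysis mode counting distinct posts per
#'   cell (a post repeating a pair contributes once, but a post with
#'   couples in several cells contributes to each).
#' @return One-row tibble with integer columns `a`, `b`, `c`, `d`.
#' @examples
#' corpus <- scenario_levothyrox(seed = 1)$corpus
#' build_contingency(corpus, drug = "H03AA01", ade = "10016256")
#' @export
build_contingency <- function(corpus, drug, ade, vocabulary = NULL,
                              count_unit = c("events", "posts")) {
  count_unit <- match.arg(count_unit)
  corpus <- check_corpus(corpus)
  couples <- corpus[is_couple(corpus), ]
  if (nrow(couples) == 0L) {
    abort("corpus contains no normalized drug-ADE couple lines",
          class = "pv_empty_table")
  }
  dm <- atc_matches(couples$atc_code, drug)
  em <- couples$meddra_code %in% resolve_pt_codes(ade, vocabulary)
  n_in <- function(keep) {
    if (count_unit == "events") sum(keep)
    else dplyr::n_distinct(couples$post_id[keep])
  }
  tibble(
    a = n_in(dm & em), b = n_in(dm & !em),
    c = n_in(!dm & em), d = n_in(!dm & !em)
  )
}

#' Disproportionality signal estimates: PRR and ROR
#'
#' The proportional reporting ratio compares the share of the ADE of
#' interest among couple events of the drug of interest with the same share
#' among all other drugs: `PRR = (a/(a+b)) / (c/(c+d))`; 1 under
#' independence. The reporting odds ratio is `ROR = ad/bc`. Both get Wald
#' 95% confidence intervals on the log scale,
#' `ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))` and
#' `ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)`, and the signal rule: a
#' signal is flagged when the lower bound of the 95% CI of the log estimate
#' is greater than 0.
#'
#' Zero cells: under the default `"strict"` policy an estimate whose
#' defining cells contain a zero (`a` or `c` for PRR; any cell for ROR) is
#' returned as an explicit not-computable row (`computable = FALSE`, `NA`
#' estimate, `NA` signal flag) — never a silent infinity.
#' `"haldane"` applies the Haldane-Anscombe continuity correction (+0.5 to
#' every cell) before computing.
#'
#' @param table One-row data frame with columns `a`, `b`, `c`, `d` (from
#'   [build_contingency()]) or a numeric vector of the four cells in that
#'   order.
#' @param zero_cell Zero-cell policy, `"strict"` (default) or `"haldane"`.
#' @return One-row tibble: `measure`, `a`, `b`, `c`, `d`, `point`,
#'   `log_point`, `log_ci_low`, `log_ci_high`, `is_signal`, `computable`.
#' @examples
#' prr(data.frame(a = 10, b = 90, c = 100, d = 9900))
#' ror(c(2, 1, 1, 2))
#' @export
prr <- function(table, zero_cell = c("strict", "haldane")) {
  signal_estimate(table, measure = "prr", zero_cell = match.arg(zero_cell))
}

#' @rdname prr
#' @export
ror <- function(table, zero_cell = c("strict", "haldane")) {
  signal_estimate(table, measure = "ror", zero_cell = match.arg(zero_cell))
}

as_cells <- function(table) {
  if (is.data.frame(table)) {
    if (!all(c("a", "b", "c", "d") %in% names(table)) || nrow(table) != 1L) {
      abort("`table` must be a one-row data frame with columns a, b, c, d",
            class = "pv_input_error")
    }
    cells <- c(a = table$a[1], b = table$b[1], c = table$c[1], d = table$d[1])
  } else if (is.numeric(table) && length(table) == 4L) {
    cells <- c(a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]])
  } else {
    abort("`table` must be a contingency row or a length-4 numeric vector",
          class = "pv_input_error")
  }
  if (any(cells < 0) || any(is.na(cells))) {
    abort("contingency cells must be nonnegative numbers", class = "pv_input_error")
  }
  cells
}

signal_estimate <- function(table, measure, zero_cell = "strict") {
  cells <- as_cells(table)
  orig <- as.list(cells)
  if (zero_cell == "haldane") cells <- cells + 0.5
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  computable <- if (measure == "prr") {
    a > 0 && c > 0 && (a + b) > 0 && (c + d) > 0
  } else {
    a > 0 && b > 0 && c > 0 && d > 0
  }
  if (!computable) {
    return(tibble(measure = toupper(measure),
                  a = orig$a, b = orig$b, c = orig$c, d = orig$d,
                  point = NA_real_, log_point = NA_real_,
                  log_ci_low = NA_real_, log_ci_high = NA_real_,
                  is_signal = NA, computable = FALSE))
  }
  if (measure == "prr") {
    point <- (a / (a + b)) / (c / (c + d))
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  } else {
    point <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  }
  lp <- log(point)
  tibble(measure = toupper(measure),
         a = orig$a, b = orig$b, c = orig$c, d = orig$d,
         point = point, log_point = lp,
         log_ci_low = lp - 1.96 * se, log_ci_high = lp + 1.96 * se,
         is_signal = lp - 1.96 * se > 0, computable = TRUE)
}

#' Cumulative monthly disproportionality series
#'
#' For each calendar month from the first couple event of the selected pair
#' to the last month present in the corpus, restricts the corpus to dates up
#' to the end of that month, rebuilds the contingency table and recomputes
#' the estimate — the evolution of the cumulated PRR (or ROR) over time.
#' Months where the estimate is not computable under the zero-cell policy
#' carry the explicit not-computable marker (`computable = FALSE`).
#'
#' @inheritParams build_contingency
#' @param measure `"prr"` or `"ror"`.
#' @param zero_cell Zero-cell policy, see [prr()].
#' @return Tibble with `month` (Date, first of month) plus the [prr()]
#'   estimate columns, one row per month.
#' @export
cumulative_prr_series <- function(corpus, drug, ade, vocabulary = NULL,
                                  measure = c("prr", "ror"),
                                  zero_cell = c("strict", "haldane")) {
  measure <- match.arg(measure)
  zero_cell <- match.arg(zero_cell)
  corpus <- check_corpus(corpus)
  couples <- corpus[is_couple(corpus), ]
  if (nrow(couples) == 0L) {
    abort("corpus contains no normalized drug-ADE couple lines",
          class = "pv_empty_table")
  }
  pair <- atc_matches(couples$atc_code, drug) &
    couples$meddra_code %in% resolve_pt_codes(ade, vocabulary)
  if (!any(pair)) {
    abort("no couple events match the selected drug-ADE pair",
          class = "pv_empty_table")
  }
  months <- month_seq(min(couples$date[pair]), max(corpus$date))
  fn <- if (measure == "prr") prr else ror
  purrr::map_dfr(months, function(m) {
    upto <- couples[couples$date < lubridate::ceiling_date(m, "month", change_on_boundary = TRUE), ]
    tab <- build_contingency(upto, drug = drug, ade = ade, vocabulary = vocabulary)
    dplyr::mutate(fn(tab, zero_cell = zero_cell), month = m, .before = 1)
  })
}
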