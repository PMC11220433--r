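#' @rdname read_annotations
#' @format NULL
#' @export
pv_columns <- c("forum_name", "post_id", "date", "time",
                "ade_verbatim", "ade_normalized", "cui", "meddra_code",
                "drug_verbatim", "drug_normalized", "active_ingredient",
                "atc_code")

#' Read and write normalized annotation corpora
#'
#' An annotation corpus is a tibble with one row per annotation line: a drug
#' annotation, an ADE annotation, or a drug-ADE couple when both are present
#' on the same line. Rows carry post metadata (forum, post id, date, time)
#' plus verbatim and normalized fields; the normalized ADE is a MedDRA
#' preferred-term code and the normalized drug an ATC level-5 code. A line is
#' a *normalized couple* exactly when it carries both codes; couples are
#' never inferred by joining separate lines of one post.
#'
#' `read_annotations()` parses a CSV with the 12 canonical columns
#' (`pv_columns`, order-insensitive; extra columns are ignored). Empty cells
#' and the em-dash placeholder are read as missing. Rows violating the line
#' invariants (no verbatim at all, unparseable date, malformed CUI/MedDRA/ATC
#' code) are rejected and reported with their row numbers in the `rejected`
#' attribute; a warning summarises them.
#'
#' @param path File path of a UTF-8 CSV with header.
#' @param date_format `"auto"` accepts ISO 8601 dates and English
#'   "October 8, 2018"-style dates; `"iso"` accepts ISO 8601 only.
#' @return `read_annotations()`: a tibble (the corpus) with `pv_columns`
#'   columns, `date` as `Date`, and attribute `rejected` (tibble of `row`,
#'   `reason` for rejected data rows). `write_annotations()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' corpus <- simulate_corpus(simulation_config(n_posts = 20), seed = 1)$corpus
#' write_annotations(corpus, f)
#' identical(as.data.frame(read_annotations(f)), as.data.frame(corpus))
#' @export
read_annotations <- function(path, date_format = c("auto", "iso")) {
  date_format <- match.arg(date_format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pv_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(pv_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "pv_missing_columns")
  }
  raw <- raw[pv_columns]
  # placeholder dashes (em dash, en dash, hyphen) and blanks are absent values
  raw <- dplyr::mutate(raw, across(
    dplyr::everything(),
    ~ ifelse(is.na(.x) | trimws(.x) %in% c("", "—", "–", "-"), NA_character_, trimws(.x))
  ))
  if (nrow(raw) == 0L) {
    out <- dplyr::mutate(raw, date = as.Date(character()))
    attr(out, "rejected") <- tibble(row = integer(), reason = character())
    return(out)
  }

  parsed_date <- if (date_format == "iso") {
    suppressWarnings(lubridate::ymd(raw$date, quiet = TRUE))
  } else {
    parse_pv_date(raw$date)
  }

  reasons <- character(nrow(raw))
  bad_date <- is.na(parsed_date)
  reasons[bad_date] <- paste0("unparseable date: '", raw$date[bad_date], "'")
  no_verbatim <- is.na(raw$ade_verbatim) & is.na(raw$drug_verbatim)
  reasons[no_verbatim & !nzchar(reasons)] <- "neither ade_verbatim nor drug_verbatim present"
  bad_cui <- !is.na(raw$cui) & !is_cui(raw$cui)
  reasons[bad_cui & !nzchar(reasons)] <- paste0("malformed CUI: '", raw$cui[bad_cui & !nzchar(reasons)], "'")
  bad_pt <- !is.na(raw$meddra_code) & !is_pt_code(raw$meddra_code)
  reasons[bad_pt & !nzchar(reasons)] <- paste0("malformed MedDRA code: '", raw$meddra_code[bad_pt & !nzchar(reasons)], "'")
  bad_atc <- !is.na(raw$atc_code) & !is_atc_code(raw$atc_code)
  reasons[bad_atc & !nzchar(reasons)] <- paste0("malformed ATC code: '", raw$atc_code[bad_atc & !nzchar(reasons)], "'")

  keep <- !nzchar(reasons)
  rejected <- tibble(row = which(!keep), reason = reasons[!keep])
  out <- dplyr::mutate(raw[keep, ], date = parsed_date[keep])
  if (nrow(rejected)) {
    warn(paste0(nrow(rejected), " row(s) rejected; see attr(corpus, 'rejected'). First: row ",
                rejected$row[1], " (", rejected$reason[1], ")"))
  }
  attr(out, "rejected") <- rejected
  out
}

#' @param corpus An annotation corpus tibble as returned by
#'   [read_annotations()] or [simulate_corpus()].
#' @rdname read_annotations
#' @export
write_annotations <- function(corpus, path) {
  corpus <- check_corpus(corpus)
  out <- dplyr::mutate(corpus[pv_columns], date = format(.data$date, "%Y-%m-%d"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# light structural check used by every corpus-consuming function
check_corpus <- function(corpus, arg = "corpus") {
  if (!is.data.frame(corpus)) {
    abort(paste0("`", arg, "` must be a data frame"), class = "pv_corpus_error")
  }
  missing_cols <- setdiff(pv_columns, names(corpus))
  if (length(missing_cols)) {
    abort(paste0("`", arg, "` is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "pv_corpus_error")
  }
  corpus <- as_tibble(corpus)
  if (!inherits(corpus$date, "Date")) corpus$date <- parse_pv_date(corpus$date)
  corpus
}

# a line is a normalized drug-ADE couple iff it carries BOTH codes
is_couple <- function(corpus) !is.na(corpus$meddra_code) & !is.na(corpus$atc_code)

#' Filter an annotation corpus by forum, period, drug and ADE selectors
#'
#' Mirrors the query sidebar of a pharmacovigilance dashboard: a line is kept
#' iff it satisfies every provided criterion; absent criteria are no-ops.
#' Drug and ADE selectors match on normalized codes only (verbatims are never
#' consulted), so lines without the relevant code are dropped by that
#' criterion.
#'
#' @inheritParams write_annotations
#' @param forums Character vector of forum names to keep.
#' @param date_range Length-2 vector (coercible to `Date`): closed interval.
#' @param atc ATC level-5 codes and/or class prefixes (1, 3, 4, 5 or 7
#'   characters).
#' @param meddra MedDRA PT codes and/or higher-level labels resolved through
#'   `vocabulary` (unknown labels are an error).
#' @param vocabulary A [pv_vocabulary()]; required for label selectors.
#' @return The filtered corpus tibble.
#' @export
filter_corpus <- function(corpus, forums = NULL, date_range = NULL,
                          atc = NULL, meddra = NULL, vocabulary = NULL) {
  corpus <- check_corpus(corpus)
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(forums)) keep <- keep & corpus$forum_name %in% forums
  if (!is.null(date_range)) {
    dr <- as.Date(date_range)
    if (length(dr) != 2L || any(is.na(dr))) {
      abort("`date_range` must be two valid dates", class = "pv_selector_error")
    }
    keep <- keep & corpus$date >= min(dr) & corpus$date <= max(dr)
  }
  if (!is.null(atc)) keep <- keep & atc_matches(corpus$atc_code, atc)
  if (!is.null(meddra)) {
    pts <- resolve_pt_codes(meddra, vocabulary)
    keep <- keep & !is.na(corpus$meddra_code) & corpus$meddra_code %in% pts
  }
  out <- corpus[keep, ]
  attr(out, "rejected") <- NULL
  out
}
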