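#' Terminology vocabulary for MedDRA and ATC code resolution
#'
#' A vocabulary bundles two lookup tables: the MedDRA preferred-term (PT)
#' hierarchy (PT -> high-level term -> high-level group term -> system organ
#' class) and an ATC level-5 code -> active-ingredient label map. It is used
#' to resolve higher-level MedDRA selectors (e.g. a SOC label) down to the PT
#' codes at which signal detection operates, and to label ranked outputs.
#'
#' @param meddra A data frame with columns `pt_code`, `pt_label`, `hlt`,
#'   `hlgt`, `soc`. PT codes are 8-digit strings.
#' @param atc A data frame with columns `atc_code` (7-character level-5 ATC
#'   code, pattern letter-digit-digit-letter-letter-digit-digit) and `label`.
#' @return An object of class `pv_vocabulary`: a list with tibbles `meddra`
#'   and `atc`.
#' @examples
#' vocab <- load_toy_vocabulary()
#' resolve_pt_codes(c("Psychiatric disorders"), vocab)
#' @export
pv_vocabulary <- function(meddra, atc) {
  meddra <- as_tibble(meddra)
  atc <- as_tibble(atc)
  need_m <- c("pt_code", "pt_label", "hlt", "hlgt", "soc")
  if (!all(need_m %in% names(meddra))) {
    abort(paste0("meddra table must have columns: ", paste(need_m, collapse = ", ")),
          class = "pv_vocab_error")
  }
  if (!all(c("atc_code", "label") %in% names(atc))) {
    abort("atc table must have columns: atc_code, label", class = "pv_vocab_error")
  }
  bad_pt <- meddra$pt_code[!grepl("^[0-9]{8}$", meddra$pt_code)]
  if (length(bad_pt)) {
    abort(paste0("invalid PT codes: ", paste(bad_pt, collapse = ", ")),
          class = "pv_vocab_error")
  }
  bad_atc <- atc$atc_code[!is_atc_code(atc$atc_code)]
  if (length(bad_atc)) {
    abort(paste0("invalid ATC codes: ", paste(bad_atc, collapse = ", ")),
          class = "pv_vocab_error")
  }
  if (anyDuplicated(meddra$pt_code)) {
    abort("duplicated PT codes: each PT maps to exactly one SOC",
          class = "pv_vocab_error")
  }
  structure(list(meddra = meddra, atc = atc), class = "pv_vocabulary")
}

#' @describeIn pv_vocabulary Load the small toy vocabulary shipped with the
#'   package (~50 PTs with SOC assignments, 40 ATC codes). Real MedDRA is
#'   licensed and is not distributed; this synthetic table is sufficient for
#'   examples, simulations and tests.
#' @export
load_toy_vocabulary <- function() {
  ext <- system.file("extdata", package = "pvsignal")
  pv_vocabulary(
    readr::read_csv(file.path(ext, "meddra_toy.csv"), col_types = readr::cols(.default = "c")),
    readr::read_csv(file.path(ext, "atc_toy.csv"), col_types = readr::cols(.default = "c"))
  )
}

#' @export
print.pv_vocabulary <- function(x, ...) {
  cat("<pv_vocabulary> ", nrow(x$meddra), " MedDRA PTs (",
      length(unique(x$meddra$soc)), " SOCs), ",
      nrow(x$atc), " ATC codes\n", sep = "")
  invisible(x)
}

is_atc_code <- function(x) grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", x)

is_pt_code <- function(x) grepl("^[0-9]{8}$", x)

is_cui <- function(x) grepl("^C[0-9]{7}$", x)

# ATC prefixes are valid at the 5 classification levels: 1, 3, 4, 5 or 7 chars
is_atc_selector <- function(x) {
  grepl("^[A-Z]$|^[A-Z][0-9]{2}$|^[A-Z][0-9]{2}[A-Z]$|^[A-Z][0-9]{2}[A-Z]{2}$|^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", x)
}

#' Resolve a MedDRA selector to preferred-term codes
#'
#' Selectors that look like 8-digit PT codes are passed through unchanged.
#' Any other selector is treated as a label at some level of the hierarchy
#' (PT label, HLT, HLGT or SOC) and resolved to the PT codes beneath it via
#' the vocabulary. An unknown label is an error, not an empty result.
#'
#' @param selector Character vector of PT codes and/or hierarchy labels.
#' @param vocabulary A [pv_vocabulary()], required when any selector is a
#'   label rather than a PT code.
#' @return Character vector of distinct PT codes.
#' @export
resolve_pt_codes <- function(selector, vocabulary = NULL) {
  selector <- as.character(selector)
  codes <- selector[is_pt_code(selector)]
  labels <- selector[!is_pt_code(selector)]
  if (length(labels)) {
    if (is.null(vocabulary)) {
      abort(paste0("MedDRA label selector(s) require a vocabulary: ",
                   paste(labels, collapse = ", ")),
            class = "pv_selector_error")
    }
    m <- vocabulary$meddra
    for (lab in labels) {
      hit <- m$pt_code[m$pt_label == lab | m$hlt == lab | m$hlgt == lab | m$soc == lab]
      if (!length(hit)) {
        abort(paste0("unknown MedDRA term: '", lab, "' not found at any hierarchy level"),
              class = "pv_selector_error")
      }
      codes <- c(codes, hit)
    }
  }
  unique(codes)
}

# TRUE for each code (NA -> FALSE) matching any ATC code-or-prefix selector
atc_matches <- function(codes, selector) {
  selector <- as.character(selector)
  bad <- selector[!is_atc_selector(selector)]
  if (length(bad)) {
    abort(paste0("invalid ATC selector(s): ", paste(bad, collapse = ", ")),
          class = "pv_selector_error")
  }
  out <- rep(FALSE, length(codes))
  ok <- !is.na(codes)
  for (s in selector) out[ok] <- out[ok] | startsWith(codes[ok], s)
  out
}
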