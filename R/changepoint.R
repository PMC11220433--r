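#' CUSUM path of a count series
#'
#' Cumulative sums of deviations from the series mean:
#' `S_0 = 0`, `S_i = S_{i-1} + (x_i - mean(x))`. By construction `S_n = 0`;
#' a sustained shift in the mean bends the path, so the extremal range
#' `s_diff = max(S) - min(S)` measures shift evidence and the position of
#' the largest `|S_i|` estimates the last point before the shift.
#'
#' @param series Numeric vector of length >= 2, or a monthly-series tibble
#'   with columns `month` and `n` (from [monthly_series()]).
#' @return Object of class `cusum_path`: list with `values`, `mean`, `S`
#'   (length n+1 path including `S_0`), `s_diff`, and `argmax` (earliest
#'   index i in 1..n-1 maximizing `|S_i|`).
#' @examples
#' cusum_path(c(10, 10, 10, 40, 40, 40))
#' @export
cusum_path <- function(series) {
  x <- series_values(series)
  n <- length(x)
  if (n < 2L) abort("series must have length >= 2", class = "pv_input_error")
  S <- c(0, cumsum(x - mean(x)))
  inner <- abs(S[2:n])  # S_1 .. S_{n-1}; S_0 = S_n = 0
  structure(
    list(values = x, mean = mean(x), S = S,
         s_diff = max(S) - min(S),
         argmax = which.max(inner)),
    class = "cusum_path"
  )
}

#' @export
print.cusum_path <- function(x, ...) {
  cat("<cusum_path> n = ", length(x$values), ", mean = ",
      format(x$mean, digits = 4), ", s_diff = ", format(x$s_diff, digits = 4),
      ", argmax |S| at i = ", x$argmax, "\n", sep = "")
  invisible(x)
}

#' Recursive CUSUM change-point detection with permutation bootstrap
#'
#' On a segment, the observed extremal CUSUM range `s_diff` is compared
#' against its distribution under random reorderings of the segment values
#' (`n_bootstrap` permutations, i.e. resampling without replacement). The
#' confidence of a change is the fraction of permutations with a strictly
#' smaller range; when it reaches `confidence_threshold`, a breakpoint is
#' placed at the earliest maximum of `|S_i|` — restricted to positions at
#' least `min_segment_length` points from either segment edge, which keeps
#' every pair of emitted breakpoints at least `min_segment_length` apart —
#' and the procedure recurses on the sub-segments before and after it until
#' no further significant change is found.
#'
#' @inheritParams cusum_path
#' @param n_bootstrap Number of permutations per tested segment.
#' @param confidence_threshold Minimum bootstrap confidence to accept a
#'   breakpoint (default 0.95).
#' @param min_segment_length Shortest segment side, in months, a breakpoint
#'   may leave on either flank; segments shorter than twice this are not
#'   tested.
#' @param seed Integer seed; identical input and seed reproduce the result.
#' @return Tibble of breakpoints ordered by position: `index` (the last
#'   point of the pre-change segment), `month` (if the input carried
#'   months), `confidence`, `mean_before`, `mean_after`, `direction`
#'   (sign of the mean change).
#' @examples
#' x <- c(rpois(24, 10), rpois(24, 40))
#' detect_breakpoints(x, seed = 1)
#' @export
detect_breakpoints <- function(series, n_bootstrap = 1000,
                               confidence_threshold = 0.95,
                               min_segment_length = 6, seed = 1) {
  x <- series_values(series)
  months <- if (is.data.frame(series)) series$month else NULL
  if (!is_scalar_number(confidence_threshold) ||
      confidence_threshold <= 0 || confidence_threshold >= 1) {
    abort("confidence_threshold must be in (0, 1)", class = "pv_input_error")
  }
  if (!is_scalar_number(min_segment_length) || min_segment_length < 2) {
    abort("min_segment_length must be >= 2", class = "pv_input_error")
  }
  if (length(x) < 2 * min_segment_length) {
    abort(paste0("series must have length >= 2 * min_segment_length = ",
                 2 * min_segment_length), class = "pv_input_error")
  }

  found <- list()
  segment <- function(lo, hi, seg_seed) {
    len <- hi - lo + 1L
    if (len < 2L * min_segment_length) return(invisible(NULL))
    xs <- x[lo:hi]
    S <- c(0, cumsum(xs - mean(xs)))
    s_diff <- max(S) - min(S)
    if (s_diff <= 0) return(invisible(NULL))
    perm <- withr::with_seed(seg_seed, {
      vapply(seq_len(n_bootstrap), function(i) {
        Sp <- cumsum(sample(xs) - mean(xs))
        max(Sp, 0) - min(Sp, 0)
      }, numeric(1))
    })
    confidence <- mean(perm < s_diff)
    if (confidence < confidence_threshold) return(invisible(NULL))
    # candidate breakpoints leave >= min_segment_length points on each side
    cand <- seq.int(min_segment_length, len - min_segment_length)
    i_local <- cand[which.max(abs(S[cand + 1L]))]
    bp <- lo + i_local - 1L
    found[[length(found) + 1L]] <<- tibble(
      index = bp,
      confidence = confidence,
      mean_before = mean(x[lo:bp]),
      mean_after = mean(x[(bp + 1L):hi]),
      direction = sign(mean(x[(bp + 1L):hi]) - mean(x[lo:bp]))
    )
    segment(lo, bp, derive_seed(seg_seed, 1L))
    segment(bp + 1L, hi, derive_seed(seg_seed, 2L))
  }
  segment(1L, length(x), as.integer(seed) %% 2147483647L)

  if (!length(found)) {
    out <- tibble(index = integer(), confidence = numeric(),
                  mean_before = numeric(), mean_after = numeric(),
                  direction = numeric())
  } else {
    out <- dplyr::arrange(dplyr::bind_rows(found), .data$index)
  }
  if (!is.null(months)) {
    out <- dplyr::mutate(out, month = months[.data$index], .after = "index")
  }
  out
}

series_values <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("month", "n") %in% names(series))) {
      abort("a series data frame needs columns month, n", class = "pv_input_error")
    }
    x <- as.numeric(series$n)
  } else if (is.numeric(series)) {
    x <- as.numeric(series)
  } else {
    abort("series must be numeric or a monthly-series data frame",
          class = "pv_input_error")
  }
  if (anyNA(x)) abort("series contains missing values", class = "pv_input_error")
  x
}
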