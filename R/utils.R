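# round half away from zero at `digits` decimals; base round() is half-even,
# which would print 82.215 as 82.22 or 82.21 depending on parity
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# parse dates: ISO 8601 first, then English "October 8, 2018" style
parse_pv_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  x <- as.character(x)
  iso <- suppressWarnings(lubridate::ymd(x, quiet = TRUE))
  out[!is.na(iso)] <- iso[!is.na(iso)]
  rest <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(rest)) {
    eng <- suppressWarnings(lubridate::mdy(x[rest], quiet = TRUE))
    out[rest] <- eng
  }
  out
}

first_of_month <- function(d) lubridate::floor_date(d, "month")

month_seq <- function(from, to) {
  seq(first_of_month(from), first_of_month(to), by = "month")
}
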