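# Fixtures are built in code; nothing binary is stored.

# The published 8-line single-post sample: headaches/cancerous-nodules rows
# lack a MedDRA code, calcium rows lack an ATC code, so exactly 2 lines are
# fully normalized couples (both codes present on the line).
table1_csv <- function(path = tempfile(fileext = ".csv")) {
  lines <- c(
    "forum_name,post_id,date,time,ade_verbatim,ade_normalized,cui,meddra_code,drug_verbatim,drug_normalized,active_ingredient,atc_code",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Maux de tête,Céphalée,C0018681,—,Lévothyrox,LEVOTHYROX,Levothyroxine sodique,H03AA01",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Maux de tête,Céphalée,C0018681,—,Calcium,—,—,—",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Nodules cancereux,—,—,—,Lévothyrox,LEVOTHYROX,Levothyroxine sodique,H03AA01",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Nodules cancereux,—,—,—,Calcium,—,—,—",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Fatigue,Fatigue,C0015672,10016256,Lévothyrox,LEVOTHYROX,Levothyroxine sodique,H03AA01",
    "Atoute,7354,\"October 8, 2018\",21:37:00,fatigue,Fatigue,C0015672,10016256,Calcium,—,—,—",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Perte de poids,Poids diminué,C0043096,10048061,Lévothyrox,LEVOTHYROX,Levothyroxine sodique,H03AA01",
    "Atoute,7354,\"October 8, 2018\",21:37:00,Perte de poids,Poids diminué,C0043096,10048061,Calcium,—,—,—"
  )
  writeLines(lines, path, useBytes = TRUE)
  path
}

table1_corpus <- function() {
  suppressWarnings(read_annotations(table1_csv()))
}

# minimal corpus builder: one annotation line per row of `rows`,
# rows = list of c(post, drug_atc or NA, ade_pt or NA), all dated in one month
# unless dates given
mini_corpus <- function(rows, dates = NULL, forum = "F1") {
  n <- length(rows)
  if (is.null(dates)) dates <- rep(as.Date("2020-01-15"), n)
  purrr::map2_dfr(rows, as.Date(dates), function(r, d) {
    atc <- r[[2]]
    pt <- r[[3]]
    tibble::tibble(
      forum_name = forum, post_id = r[[1]], date = d, time = "12:00:00",
      ade_verbatim = if (!is.na(pt)) "ade text" else NA_character_,
      ade_normalized = if (!is.na(pt)) "ADE" else NA_character_,
      cui = NA_character_,
      meddra_code = ifelse(is.na(pt), NA_character_, pt),
      drug_verbatim = if (!is.na(atc)) "drug text" else NA_character_,
      drug_normalized = if (!is.na(atc)) "DRUG" else NA_character_,
      active_ingredient = NA_character_,
      atc_code = ifelse(is.na(atc), NA_character_, atc)
    )
  })
}

# the 6-couple two-drug/two-ADE fixture used for contingency checks:
# (D1,E1) x2, (D1,E2) x1, (D2,E1) x1, (D2,E2) x2
six_couple_corpus <- function() {
  mini_corpus(list(
    c("p1", "N02BE01", "10016256"),
    c("p1", "N02BE01", "10016256"),
    c("p2", "N02BE01", "10033371"),
    c("p3", "M01AE01", "10016256"),
    c("p4", "M01AE01", "10033371"),
    c("p5", "M01AE01", "10033371")
  ))
}

# brute-force oracle for contingency construction: classify couple lines
# one at a time with plain string comparisons
oracle_contingency <- function(corpus, drug_codes, ade_codes) {
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(corpus))) {
    atc <- corpus$atc_code[i]
    pt <- corpus$meddra_code[i]
    if (is.na(atc) || is.na(pt)) next
    dm <- any(vapply(drug_codes, function(s) startsWith(atc, s), logical(1)))
    em <- pt %in% ade_codes
    if (dm && em) a <- a + 1L
    else if (dm) b <- b + 1L
    else if (em) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

# random small corpus over a few drugs/ADEs, with partial lines mixed in
random_corpus <- function(n_lines, seed) {
  withr::with_seed(seed, {
    drugs <- c("N02BE01", "M01AE01", "H03AA01", "N06AX22", NA)
    ades <- c("10016256", "10033371", "10019211", NA)
    rows <- lapply(seq_len(n_lines), function(i) {
      repeat {
        dd <- sample(drugs, 1)
        ee <- sample(ades, 1)
        if (!is.na(dd) || !is.na(ee)) break
      }
      c(sprintf("p%02d", sample(20, 1)), dd, ee)
    })
    dates <- as.Date("2019-01-01") + sample(0:365, n_lines, replace = TRUE)
    mini_corpus(rows, dates = dates)
  })
}
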