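test_that("invalid config fields are named individually", {
  err <- expect_error(
    simulation_config(n_posts = -5,
                      forum_weights = c(A = 0.5, B = 0.4),
                      couples_per_post = 0.2),
    class = "pv_config_error"
  )
  msg <- conditionMessage(err)
  expect_match(msg, "n_posts")
  expect_match(msg, "forum_weights")
  expect_match(msg, "couples_per_post")

  expect_error(
    simulation_config(n_posts = 10,
                      association = data.frame(atc_code = "X99XX99",
                                               meddra_code = "10016256",
                                               rho = 2)),
    class = "pv_config_error"
  )
  expect_error(
    simulation_config(n_posts = 10, n_months = 12,
                      rate_shift = list(month = 20, multiplier = 2, target = "volume")),
    class = "pv_config_error"
  )
})

test_that("zero posts give an empty corpus and empty ground truth", {
  sim <- simulate_corpus(simulation_config(n_posts = 0), seed = 1)
  expect_equal(nrow(sim$corpus), 0L)
  expect_equal(sim$truth$n_couple_events, 0L)
  expect_true(all(sim$truth$monthly_couples$n == 0))
})

test_that("identical config and seed reproduce the corpus exactly", {
  cfg <- simulation_config(n_posts = 300,
                           association = data.frame(atc_code = "H03AA01",
                                                    meddra_code = "10016256",
                                                    rho = 3))
  s1 <- simulate_corpus(cfg, seed = 17)
  s2 <- simulate_corpus(cfg, seed = 17)
  expect_identical(s1$corpus, s2$corpus)
  expect_identical(s1$truth$pair_cells, s2$truth$pair_cells)
  s3 <- simulate_corpus(cfg, seed = 18)
  expect_false(identical(s1$corpus, s3$corpus))
})

test_that("generated corpora satisfy the schema and round-trip through CSV", {
  sim <- simulate_corpus(
    simulation_config(n_posts = 250,
                      rate_shift = list(month = 12, multiplier = 3, target = "volume")),
    seed = 5
  )
  corpus <- sim$corpus
  expect_equal(names(corpus), pv_columns)
  # every line has at least one verbatim; codes match their patterns
  expect_true(all(!is.na(corpus$ade_verbatim) | !is.na(corpus$drug_verbatim)))
  expect_true(all(is.na(corpus$atc_code) | grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", corpus$atc_code)))
  expect_true(all(is.na(corpus$meddra_code) | grepl("^[0-9]{8}$", corpus$meddra_code)))
  expect_true(all(is.na(corpus$cui) | grepl("^C[0-9]{7}$", corpus$cui)))

  f <- tempfile(fileext = ".csv")
  write_annotations(corpus, f)
  back <- read_annotations(f)
  expect_equal(nrow(attr(back, "rejected")), 0L)
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(corpus))
})

test_that("ground truth accounts for every couple event", {
  sim <- simulate_corpus(
    simulation_config(n_posts = 400,
                      association = data.frame(atc_code = c("H03AA01", "N02BE01"),
                                               meddra_code = c("10016256", "10019211"),
                                               rho = c(4, 2))),
    seed = 9
  )
  cells <- sim$truth$pair_cells
  expect_equal(nrow(cells), 2L)
  # each designed pair's cells partition all couple events
  expect_true(all(cells$a + cells$b + cells$c + cells$d == sim$truth$n_couple_events))
  expect_equal(sum(sim$truth$monthly_couples$n), sim$truth$n_couple_events)
  # realized cells agree with build_contingency on the corpus
  tab <- build_contingency(sim$corpus, drug = "H03AA01", ade = "10016256")
  expect_equal(unlist(tab), c(a = cells$a[1], b = cells$b[1], c = cells$c[1], d = cells$d[1]))
})

test_that("mention frequencies converge to the configured probabilities", {
  cfg <- simulation_config(n_posts = 20000)
  sim <- simulate_corpus(cfg, seed = 31)
  corpus <- sim$corpus
  n_posts <- dplyr::n_distinct(corpus$post_id)
  expect_equal(n_posts, 20000L)
  for (k in seq_len(nrow(cfg$drug_catalog))) {
    p <- cfg$drug_catalog$p_mention[k]
    got <- dplyr::n_distinct(corpus$post_id[!is.na(corpus$atc_code) &
                                              corpus$atc_code == cfg$drug_catalog$atc_code[k]]) / n_posts
    se <- sqrt(p * (1 - p) / n_posts)
    expect_lt(abs(got - p), 3 * se + 1e-9)
  }
})

test_that("a designed association yields a detectable disproportionality signal", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_corpus(
      simulation_config(n_posts = 2000,
                        association = data.frame(atc_code = "H03AA01",
                                                 meddra_code = "10016256", rho = 5)),
      seed = s
    )
    tab <- build_contingency(sim$corpus, "H03AA01", "10016256")
    isTRUE(prr(tab)$is_signal)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the packaged thyroid scenario has its designed structure", {
  sc <- scenario_levothyrox(seed = 1)
  corpus <- sc$corpus

  # one dominant forum concentrates the target drug's annotations
  lev <- filter_corpus(corpus, atc = "H03AA01")
  top <- rank_by(lev, "forum_name")
  expect_equal(top$label[1], "Vivre sans thyroide")
  expect_gte(top$n[1] / sum(top$n), 0.75)
  expect_lte(top$n[1] / sum(top$n), 0.90)

  # the mention surge is a recoverable change point at the shift month +/- 1
  ser <- monthly_series(corpus, unit = "couples", atc = "H03AA01", meddra = "10016256")
  bp <- detect_breakpoints(ser, seed = 1)
  expect_gte(nrow(bp), 1L)
  expect_true(min(abs(bp$index - sc$truth$changepoint_month$index)) <= 1)

  # the designed association keeps the signal on from the surge onward
  prr_ser <- cumulative_prr_series(corpus, drug = "H03AA01", ade = "10016256")
  after <- prr_ser[prr_ser$month >= sc$truth$changepoint_month$month, ]
  expect_true(all(after$computable))
  expect_true(all(after$log_ci_low > 0))
})
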