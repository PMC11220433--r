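test_that("contingency cells classify each couple event exactly once", {
  tab <- build_contingency(six_couple_corpus(), drug = "N02BE01", ade = "10016256")
  expect_equal(unlist(tab), c(a = 2L, b = 1L, c = 1L, d = 2L))

  # selector matching every drug leaves no comparator events
  tab_all <- build_contingency(six_couple_corpus(), drug = c("N02BE01", "M01AE01"),
                               ade = "10016256")
  expect_equal(tab_all$b + tab_all$d, 3L)
  expect_equal(tab_all$c, 0L)

  # the published 8-line sample: only the two fully coded lines are events
  tab1 <- build_contingency(table1_corpus(), drug = "H03AA01", ade = "10016256")
  expect_equal(unlist(tab1), c(a = 1L, b = 1L, c = 0L, d = 0L))

  expect_error(build_contingency(mini_corpus(list(c("p1", "N02BE01", NA))),
                                 drug = "N02BE01", ade = "10016256"),
               class = "pv_empty_table")

  # sensitivity mode: a post repeating a pair counts once per cell
  rep_corpus <- mini_corpus(list(
    c("p1", "N02BE01", "10016256"), c("p1", "N02BE01", "10016256"),
    c("p1", "M01AE01", "10033371"), c("p2", "M01AE01", "10033371")
  ))
  ev <- build_contingency(rep_corpus, drug = "N02BE01", ade = "10016256")
  po <- build_contingency(rep_corpus, drug = "N02BE01", ade = "10016256",
                          count_unit = "posts")
  expect_equal(unlist(ev), c(a = 2L, b = 0L, c = 0L, d = 2L))
  expect_equal(unlist(po), c(a = 1L, b = 0L, c = 0L, d = 2L))
})

test_that("PRR point estimates, Wald CI on the log scale and the signal rule", {
  est <- prr(c(2, 1, 1, 2))
  expect_equal(est$point, 2)
  expect_equal(est$log_ci_low, log(2) - 1.96 * sqrt(1/2 - 1/3 + 1 - 1/3))
  expect_equal(round(est$log_ci_low, 3), -1.096)
  expect_false(est$is_signal)

  expect_equal(prr(c(5, 5, 5, 5))$point, 1)
  expect_equal(prr(c(10, 90, 100, 9900))$point, 10)
  big <- prr(c(100, 900, 1000, 99000))
  expect_true(big$is_signal)
  expect_true(big$log_ci_low > 0)
  expect_equal(big$log_point, log(big$point))
})

test_that("ROR point estimates and CI", {
  expect_equal(ror(c(2, 1, 1, 2))$point, 4)
  expect_equal(ror(c(5, 5, 5, 5))$point, 1)
  expect_equal(ror(c(10, 90, 100, 9900))$point, 11)
  est <- ror(c(10, 90, 100, 9900))
  expect_equal(est$log_ci_high - est$log_point,
               1.96 * sqrt(1/10 + 1/90 + 1/100 + 1/9900))
})

test_that("zero cells give an explicit not-computable result; Haldane correction computes", {
  s <- prr(c(0, 5, 3, 7))
  expect_false(s$computable)
  expect_true(is.na(s$point) && is.na(s$is_signal))
  r <- ror(c(2, 0, 1, 2))
  expect_false(r$computable)

  h <- ror(c(2, 0, 1, 2), zero_cell = "haldane")
  expect_true(h$computable)
  expect_equal(h$point, (2.5 * 2.5) / (0.5 * 1.5))
  # original cells are reported untouched
  expect_equal(h$b, 0)
})

test_that("PRR/ROR are scale invariant and ROR is reciprocal under row swap", {
  withr::with_seed(7, {
    for (i in 1:50) {
      cells <- sample(1:50, 4, replace = TRUE)
      k <- sample(2:5, 1)
      expect_equal(prr(k * cells)$point, prr(cells)$point)
      expect_equal(ror(k * cells)$point, ror(cells)$point)
      swapped <- cells[c(3, 4, 1, 2)]
      expect_equal(ror(swapped)$point, 1 / ror(cells)$point)
    }
  })
})

test_that("contingency construction matches the brute-force oracle on random corpora", {
  for (seed in 1:20) {
    corpus <- random_corpus(n_lines = 150, seed = seed)
    got <- build_contingency(corpus, drug = c("N02BE01", "H03AA"), ade = c("10016256", "10019211"))
    want <- oracle_contingency(corpus, c("N02BE01", "H03AA"), c("10016256", "10019211"))
    expect_equal(unlist(got), want)
    expect_equal(sum(unlist(got)), sum(!is.na(corpus$atc_code) & !is.na(corpus$meddra_code)))
  }
})

test_that("cumulative series recomputes the estimate per month-end and stabilises", {
  corpus <- mini_corpus(
    list(c("p1", "N02BE01", "10016256"), c("p1", "N02BE01", "10016256"),
         c("p2", "N02BE01", "10033371"), c("p3", "M01AE01", "10016256"),
         c("p4", "M01AE01", "10033371"), c("p5", "M01AE01", "10033371"),
         c("p6", "N02BE01", "10016256"), c("p7", "M01AE01", "10033371")),
    dates = c(rep("2020-01-10", 6), "2020-02-05", "2020-02-20")
  )
  ser <- cumulative_prr_series(corpus, drug = "N02BE01", ade = "10016256")
  expect_equal(nrow(ser), 2L)
  expect_equal(ser$point[1], prr(c(2, 1, 1, 2))$point)
  # month 2 cumulates to (3,1,1,3): PRR = (3/4)/(1/4)
  expect_equal(ser$point[2], 3)

  # couple counts stop changing -> estimate constant from then on
  # (the trailing months contain only a non-couple drug mention)
  corpus2 <- rbind(corpus,
                   mini_corpus(list(c("p9", "J01CA04", NA)), dates = "2020-04-03"))
  ser2 <- cumulative_prr_series(corpus2, drug = "N02BE01", ade = "10016256")
  expect_equal(nrow(ser2), 4L)
  expect_equal(ser2$point[2:3], rep(ser2$point[4], 2))
  expect_equal(ser2$a[4], 3)

  # single-month corpus: length-1 series equal to the whole-corpus estimate
  one <- cumulative_prr_series(six_couple_corpus(), drug = "N02BE01", ade = "10016256")
  expect_equal(nrow(one), 1L)
  expect_equal(one$point, prr(build_contingency(six_couple_corpus(), "N02BE01", "10016256"))$point)
})
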