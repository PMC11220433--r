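test_that("design matrix encodes per-post binary presence", {
  corpus <- mini_corpus(list(
    c("p1", "N02BE01", "10016256"),
    c("p2", "N02BE01", NA),
    c("p3", "M01AE01", NA)
  ))
  d <- build_design(corpus, ade = "10016256")
  expect_equal(d$outcome, c(1L, 0L, 0L))
  expect_equal(unname(d$drugs[, "N02BE01"]), c(1L, 1L, 0L))
  expect_equal(unname(d$drugs[, "M01AE01"]), c(0L, 0L, 1L))
  expect_equal(d$n1, 1L)
  expect_equal(d$n0, 2L)

  # the same drug annotated five times in one post is still a 0/1 indicator
  rep5 <- mini_corpus(c(replicate(5, c("p1", "N02BE01", "10016256"), simplify = FALSE),
                        list(c("p2", "M01AE01", NA))))
  d5 <- build_design(rep5, ade = "10016256")
  expect_equal(max(d5$drugs), 1L)

  # every post carrying the ADE is a degenerate design
  allcase <- mini_corpus(list(c("p1", "N02BE01", "10016256"),
                              c("p2", "M01AE01", "10016256")))
  expect_error(build_design(allcase, ade = "10016256"),
               class = "pv_degenerate_design")
})

test_that("perfect separation gives a positive penalized coefficient in every draw", {
  # drug present in all outcome-1 posts, absent from all outcome-0 posts
  rows <- c(
    lapply(1:12, function(i) c(sprintf("c%02d", i), "H03AA01", "10016256")),
    lapply(1:30, function(i) c(sprintf("n%02d", i), "N02BE01", NA))
  )
  d <- build_design(mini_corpus(rows), ade = "10016256")
  fit <- ciss_lasso(d, B = 40, q = 15, seed = 3)
  expect_true(all(fit$coefficients[, "H03AA01"] > 0))
  expect_true("H03AA01" %in% retained_at(fit, 5))
  expect_true("H03AA01" %in% retained_at(fit, 10))
  expect_true("H03AA01" %in% retained_at(fit, 15))

  # cross-check one draw against an unpenalized refit on the same posts:
  # separation keeps even the MLE direction positive (glm warns, sign holds)
  i1 <- withr::with_seed(pvsignal:::derive_seed(3, 1L), {
    s1 <- which(d$outcome == 1); s0 <- which(d$outcome == 0)
    c(sample(s1, d$n1, replace = TRUE),
      sample(s0, max(4 * d$n1, 4 * d$Nm), replace = TRUE))
  })
  refit <- suppressWarnings(
    glm(d$outcome[i1] ~ d$drugs[i1, "H03AA01"], family = binomial)
  )
  expect_gt(coef(refit)[2], 0)
})

test_that("results are exactly reproducible for identical design, config and seed", {
  corpus <- simulate_corpus(
    simulation_config(n_posts = 400,
                      association = data.frame(atc_code = "H03AA01",
                                               meddra_code = "10016256", rho = 5)),
    seed = 2
  )$corpus
  d <- build_design(corpus, ade = "10016256")
  f1 <- ciss_lasso(d, B = 30, seed = 99)
  f2 <- ciss_lasso(d, B = 30, seed = 99)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$retained, f2$retained)
  f3 <- ciss_lasso(d, B = 30, seed = 100)
  expect_false(identical(f1$coefficients, f3$coefficients))
})

test_that("subsample sizes follow R = max(4 n1, 4 Nm) and the model-size cap holds", {
  corpus <- simulate_corpus(simulation_config(n_posts = 400), seed = 5)$corpus
  d <- build_design(corpus, ade = "10016256")
  fit <- ciss_lasso(d, B = 20, max_predictors = 3, seed = 1)
  expect_equal(fit$config$R, max(4 * d$n1, 4 * d$Nm))
  expect_true(all(fit$model_sizes <= 3))
  expect_true(all(fit$selection_counts <= fit$config$B))
})

test_that("retained sets are nested across the retention percentiles", {
  for (seed in 1:5) {
    corpus <- simulate_corpus(
      simulation_config(n_posts = 500,
                        association = data.frame(atc_code = c("H03AA01", "N06AX22"),
                                                 meddra_code = c("10016256", "10016256"),
                                                 rho = c(4, 2))),
      seed = seed
    )$corpus
    d <- build_design(corpus, ade = "10016256")
    fit <- ciss_lasso(d, B = 40, seed = seed)
    r5 <- retained_at(fit, 5); r10 <- retained_at(fit, 10); r15 <- retained_at(fit, 15)
    expect_true(all(r5 %in% r10))
    expect_true(all(r10 %in% r15))
  }
})

test_that("B = 1 retains exactly the drugs with a positive coefficient in that draw", {
  corpus <- simulate_corpus(
    simulation_config(n_posts = 400,
                      association = data.frame(atc_code = "H03AA01",
                                               meddra_code = "10016256", rho = 6)),
    seed = 8
  )$corpus
  d <- build_design(corpus, ade = "10016256")
  fit <- ciss_lasso(d, B = 1, q = 5, seed = 21)
  expect_setequal(fit$retained, colnames(fit$coefficients)[fit$coefficients[1, ] > 0])
})

test_that("selection-count mode retains drugs selected in enough draws", {
  corpus <- simulate_corpus(
    simulation_config(n_posts = 500,
                      association = data.frame(atc_code = "H03AA01",
                                               meddra_code = "10016256", rho = 6)),
    seed = 12
  )$corpus
  d <- build_design(corpus, ade = "10016256")
  fit <- ciss_lasso(d, B = 40, q = 10, seed = 4, mode = "selection")
  # q = 10 on the 0/1 selection indicators: retention requires selection in
  # (essentially) at least 90% of draws
  freq <- colSums(fit$coefficients > 0) / 40
  expect_true(all(freq[fit$retained] >= 0.9))
  expect_true(all(!names(freq)[freq < 0.9] %in% fit$retained))
  expect_true("H03AA01" %in% fit$retained)
})

test_that("tidy and glance summarise the fit", {
  corpus <- simulate_corpus(simulation_config(n_posts = 300), seed = 3)$corpus
  d <- build_design(corpus, ade = "10016256")
  fit <- ciss_lasso(d, B = 10, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), d$Nm)
  expect_true(all(c("atc_code", "selection_count", "q_percentile", "retained") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$B, 10L)
  expect_equal(gl$n_retained, length(fit$retained))
})
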