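#' Build a per-post design matrix for multivariate signal detection
#'
#' One row per distinct post. The outcome is 1 when the post carries at
#' least one ADE annotation matching the selector (normalized PT-code
#' match); the predictors are binary presence indicators, one per ATC
#' level-5 drug code observed in the corpus — a drug annotated in a post is
#' assumed taken by the patient, and presence is binary regardless of how
#' often the drug is annotated. Posts with the ADE form the case set S1
#' (size `n1`), the rest S0 (size `n0`).
#'
#' @inheritParams filter_corpus
#' @param ade MedDRA PT code(s) or higher-level label defining the ADE of
#'   interest.
#' @return An object of class `pv_design`: list with `outcome` (0/1 integer
#'   vector), `drugs` (posts x Nm 0/1 matrix, ATC codes as column names),
#'   `post_ids`, `n1`, `n0`, `Nm`, and `dropped` (drug columns removed
#'   because no post mentioned them).
#' @examples
#' corpus <- scenario_levothyrox(seed = 1)$corpus
#' design <- build_design(corpus, ade = "10016256")
#' design
#' @export
build_design <- function(corpus, ade, vocabulary = NULL) {
  corpus <- check_corpus(corpus)
  pts <- resolve_pt_codes(ade, vocabulary)
  posts <- sort(unique(corpus$post_id))
  if (length(posts) < 2L) {
    abort("need at least 2 posts to build a design", class = "pv_degenerate_design")
  }
  pi <- match(corpus$post_id, posts)
  outcome <- integer(length(posts))
  hit <- !is.na(corpus$meddra_code) & corpus$meddra_code %in% pts
  outcome[unique(pi[hit])] <- 1L

  drug_codes <- sort(unique(corpus$atc_code[!is.na(corpus$atc_code)]))
  if (length(drug_codes) == 0L) {
    abort("corpus contains no normalized drug annotations", class = "pv_degenerate_design")
  }
  drugs <- matrix(0L, nrow = length(posts), ncol = length(drug_codes),
                  dimnames = list(posts, drug_codes))
  has_drug <- !is.na(corpus$atc_code)
  drugs[cbind(pi[has_drug], match(corpus$atc_code[has_drug], drug_codes))] <- 1L

  empty <- colSums(drugs) == 0L
  dropped <- drug_codes[empty]
  if (any(empty)) {
    warn(paste0("dropping all-zero drug column(s): ", paste(dropped, collapse = ", ")))
    drugs <- drugs[, !empty, drop = FALSE]
  }
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort(paste0("degenerate design: n1 = ", n1, ", n0 = ", n0,
                 " (need posts both with and without the ADE)"),
          class = "pv_degenerate_design")
  }
  structure(
    list(outcome = outcome, drugs = drugs, post_ids = posts,
         n1 = n1, n0 = n0, Nm = ncol(drugs), dropped = dropped),
    class = "pv_design"
  )
}

#' @export
print.pv_design <- function(x, ...) {
  cat("<pv_design> ", length(x$post_ids), " posts, ", x$Nm, " drugs; n1 = ",
      x$n1, " (ADE present), n0 = ", x$n0, "\n", sep = "")
  invisible(x)
}

#' Class-imbalanced subsampling lasso signal detection
#'
#' Fits, over `B` resamples, an L1-penalized logistic regression of ADE
#' presence on all drug-presence indicators. Each resample draws, with
#' replacement, `n1` posts from the case set S1 and `R = max(4*n1, 4*Nm)`
#' posts from the non-case set S0 — a balanced-enough subsample in corpora
#' where non-cases dominate. Within each draw the penalty is relaxed along
#' the regularization path from the largest lambda downward and stopped at
#' the smallest lambda whose active set has at most `max_predictors`
#' nonzero drug coefficients (the model-size cap); the coefficient of every
#' drug at that lambda is recorded (0 when not in the model). A drug is
#' *retained* when the `q`-th percentile of its recorded collection across
#' the `B` draws is greater than 0 — so at `q = 10` roughly 90% of draws
#' must give it a strictly positive coefficient, and a smaller `q` is the
#' stricter criterion.
#'
#' @param design A `pv_design` from [build_design()].
#' @param B Number of resampling draws (default 250).
#' @param max_predictors Maximum model size along the path (default 50).
#' @param q Retention percentile, one of 5, 10, 15.
#' @param seed Integer master seed; per-draw seeds are derived
#'   deterministically from it, so identical input and config reproduce the
#'   result exactly.
#' @param mode `"coefficient"` (default) applies the percentile rule to the
#'   coefficient values; `"selection"` applies it to the 0/1
#'   selected-in-draw indicators (retention then means selected in more than
#'   `100 - q` percent of draws). The two can differ; see the package
#'   vignette.
#' @param lambda_rule `"cap"` (default, the path rule above) or `"cv"`
#'   (per-draw 10-fold cross-validated lambda.min; the size cap is then not
#'   enforced).
#' @return An object of class `ciss_lasso`; use [tidy()] for the per-drug
#'   table and [glance()] for the one-row fit summary. Fields include
#'   `coefficients` (B x Nm matrix), `percentiles`, `selection_counts`,
#'   `retained` (character vector of ATC codes), `model_sizes`,
#'   `n_redrawn`, `config`.
#' @examples
#' corpus <- scenario_levothyrox(seed = 1)$corpus
#' design <- build_design(corpus, ade = "10016256")
#' fit <- ciss_lasso(design, B = 25, seed = 42)
#' tidy(fit)
#' @export
ciss_lasso <- function(design, B = 250, max_predictors = 50,
                       q = 10, seed = 1,
                       mode = c("coefficient", "selection"),
                       lambda_rule = c("cap", "cv")) {
  if (!inherits(design, "pv_design")) {
    abort("`design` must be a pv_design from build_design()", class = "pv_input_error")
  }
  mode <- match.arg(mode)
  lambda_rule <- match.arg(lambda_rule)
  if (!is_scalar_number(B) || B < 1) abort("B must be >= 1", class = "pv_input_error")
  if (!q %in% c(5, 10, 15)) abort("q must be one of 5, 10, 15", class = "pv_input_error")
  if (!is_scalar_number(max_predictors) || max_predictors < 1) {
    abort("max_predictors must be >= 1", class = "pv_input_error")
  }
  B <- as.integer(B)
  s1 <- which(design$outcome == 1L)
  s0 <- which(design$outcome == 0L)
  n1 <- design$n1
  R <- max(4L * n1, 4L * design$Nm)
  Nm <- design$Nm

  coefs <- matrix(0, nrow = B, ncol = Nm, dimnames = list(NULL, colnames(design$drugs)))
  sizes <- integer(B)
  n_redrawn <- 0L

  one_draw <- function(draw_seed) {
    withr::with_seed(draw_seed, {
      i1 <- sample(s1, n1, replace = TRUE)
      i0 <- sample(s0, R, replace = TRUE)
      idx <- c(i1, i0)
      x <- design$drugs[idx, , drop = FALSE]
      y <- design$outcome[idx]
      fit_penalized(x, y, max_predictors, lambda_rule)
    })
  }

  for (b in seq_len(B)) {
    draw_seed <- derive_seed(seed, b)
    res <- tryCatch(one_draw(draw_seed), error = function(e) NULL)
    if (is.null(res)) {
      # one retry with a derived seed, then record the draw as all-zero
      n_redrawn <- n_redrawn + 1L
      res <- tryCatch(one_draw(derive_seed(seed, b + 500009L)),
                      error = function(e) NULL)
    }
    if (is.null(res)) {
      warn(paste0("draw ", b, " failed to converge twice; recorded as all-zero"))
      res <- numeric(Nm)
    }
    coefs[b, ] <- res
    sizes[b] <- sum(res != 0)
  }

  collection <- if (mode == "coefficient") coefs else (coefs > 0) + 0
  percentiles <- apply(collection, 2, quantile, probs = q / 100, type = 7, names = FALSE)
  selection_counts <- colSums(coefs > 0)
  retained <- colnames(coefs)[percentiles > 0]

  structure(
    list(coefficients = coefs,
         percentiles = percentiles,
         selection_counts = selection_counts,
         retained = retained,
         model_sizes = sizes,
         n_redrawn = n_redrawn,
         config = list(B = B, max_predictors = max_predictors, q = q,
                       seed = seed, mode = mode, lambda_rule = lambda_rule,
                       R = R, n1 = n1, n0 = design$n0, Nm = Nm)),
    class = "ciss_lasso"
  )
}

# per-draw seeds: derived deterministically from the master seed, kept
# inside 32-bit integer range
derive_seed <- function(seed, b) {
  as.integer((abs(as.numeric(seed)) * 48271 + b * 16807) %% 2147483647)
}

# L1 logistic fit returning the drug coefficient vector at the chosen lambda
fit_penalized <- function(x, y, max_predictors, lambda_rule) {
  p <- ncol(x)
  if (p == 1L) {
    # glmnet needs >= 2 columns; an all-zero dummy is never selected and
    # leaves the real predictor's path unchanged
    x <- cbind(x, `.dummy` = 0)
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        standardize = FALSE, intercept = TRUE)
  if (lambda_rule == "cv") {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            standardize = FALSE, intercept = TRUE)
    s <- cv$lambda.min
  } else {
    # walk the path from the largest lambda down, keeping the active set
    # within the cap; among the admissible lambdas choose by BIC, so that
    # when the cap cannot bind (few drugs) the fit is still genuinely
    # penalized rather than collapsing to the unpenalized path end
    over <- which(fit$df > max_predictors)
    k_max <- if (length(over)) max(over[1] - 1L, 1L) else length(fit$lambda)
    n_obs <- length(y)
    dev <- (1 - fit$dev.ratio[1:k_max]) * fit$nulldev
    bic <- dev + fit$df[1:k_max] * log(n_obs)
    s <- fit$lambda[which.min(bic)]
  }
  as.numeric(coef(fit, s = s, exact = FALSE))[-1][seq_len(p)]
}

#' Recompute the retained set at another percentile
#'
#' Reuses the stored coefficient draws, so no refitting is needed; useful to
#' compare the strict (q = 5) and lax (q = 15) retention rules, whose
#' retained sets are nested: retained(5) is a subset of retained(10), which
#' is a subset of retained(15).
#'
#' @param fit A `ciss_lasso` object.
#' @param q Retention percentile, one of 5, 10, 15.
#' @return Character vector of retained ATC codes.
#' @export
retained_at <- function(fit, q) {
  if (!inherits(fit, "ciss_lasso")) abort("`fit` must be a ciss_lasso object",
                                          class = "pv_input_error")
  if (!q %in% c(5, 10, 15)) abort("q must be one of 5, 10, 15", class = "pv_input_error")
  collection <- if (fit$config$mode == "coefficient") {
    fit$coefficients
  } else (fit$coefficients > 0) + 0
  p <- apply(collection, 2, quantile, probs = q / 100, type = 7, names = FALSE)
  colnames(fit$coefficients)[p > 0]
}

#' @export
print.ciss_lasso <- function(x, ...) {
  cat("<ciss_lasso> B = ", x$config$B, " draws, ", x$config$Nm, " drugs, ",
      "subsample n1 = ", x$config$n1, " + R = ", x$config$R, "\n",
      "retained at q = ", x$config$q, ": ",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' @rdname ciss_lasso
#' @param x A `ciss_lasso` object.
#' @param ... Unused.
#' @export
tidy.ciss_lasso <- function(x, ...) {
  tibble(
    atc_code = colnames(x$coefficients),
    selection_count = as.integer(x$selection_counts),
    selection_freq = as.numeric(x$selection_counts) / x$config$B,
    q_percentile = as.numeric(x$percentiles),
    retained = colnames(x$coefficients) %in% x$retained
  ) |>
    dplyr::arrange(dplyr::desc(.data$selection_count), .data$atc_code)
}

#' @rdname ciss_lasso
#' @export
glance.ciss_lasso <- function(x, ...) {
  tibble(
    B = x$config$B, q = x$config$q, n1 = x$config$n1, n0 = x$config$n0,
    R = x$config$R, Nm = x$config$Nm,
    n_retained = length(x$retained),
    max_model_size = max(x$model_sizes),
    n_redrawn = x$n_redrawn
  )
}
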