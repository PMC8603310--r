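# Direct construction of an already-z-scored trial table for regression
# tests (bypasses the Likert generator; values are on the z scale).
make_z_trials <- function(n_participants = 40, n_trials = 60,
                          cond_effect = 0, noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_participants), function(i) {
      cond <- if (i %% 2 == 0) "d_exposure" else "control"
      tibble::tibble(
        participant_id = sprintf("p%02d", i),
        token_id = sprintf("tok_%03d", seq_len(n_trials)),
        block = "d_goodness",
        condition = cond,
        language = "english",
        raw_rating = 4L,
        category = rep(c("d", "t"), length.out = n_trials),
        z_rating = rnorm(n_trials, 0, noise_sd) +
          ifelse(cond == "d_exposure", cond_effect, 0)
      )
    })
    dplyr::bind_rows(rows)
  })
}

test_that("within-participant z-scoring standardizes exactly", {
  r <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 3),
    token_id = rep(sprintf("t%d", 1:3), 2),
    block = "d_goodness", condition = "control", language = "english",
    raw_rating = c(2L, 4L, 6L, 5L, 5L, 5L)
  )
  expect_warning(z <- zscore_within_participant(r), "constant")
  expect_equal(z$z_rating[z$participant_id == "a"], c(-1, 0, 1))
  expect_equal(z$z_rating[z$participant_id == "b"], c(0, 0, 0))

  big <- make_ratings(n_participants = 8, n_trials = 20, seed = 3)
  zb <- zscore_within_participant(big)
  for (pid in unique(zb$participant_id)) {
    zi <- zb$z_rating[zb$participant_id == pid]
    expect_equal(mean(zi), 0, tolerance = 1e-9)
    expect_equal(sd(zi), 1, tolerance = 1e-9)
  }
  # idempotence: re-standardizing the standardized values changes nothing
  zb2 <- zb
  zb2$raw_rating <- zb$z_rating
  rez <- zscore_within_participant(zb2)
  expect_equal(rez$z_rating, zb$z_rating, tolerance = 1e-9)

  single <- r[c(1, 4:6), ]
  expect_error(zscore_within_participant(single), "single rating")
})

test_that("by-item means aggregate correctly and conserve counts", {
  r <- tibble::tibble(
    participant_id = c("a", "b", "a"),
    token_id = c("t1", "t1", "t2"),
    block = "d_goodness",
    condition = "control",
    language = "english",
    raw_rating = 4L,
    z_rating = c(-0.5, 0.5, 1.2)
  )
  preds <- tibble::tibble(
    token_id = c("t1", "t2"), condition = "control", block = "d_goodness",
    p_d = c(0.8, 0.3), p_t = c(0.2, 0.7), posterior_rating = c(0.6, -0.4)
  )
  item <- by_item_means(r, preds)
  expect_equal(item$mean_z_rating[item$token_id == "t1"], 0)
  expect_equal(item$mean_z_rating[item$token_id == "t2"], 1.2)
  expect_equal(sum(item$n_participants), 3)
  expect_equal(item$posterior_rating[item$token_id == "t1"], 0.6)

  r_orphan <- r
  r_orphan$token_id[3] <- "t9"
  expect_error(by_item_means(r_orphan, preds), "t9")
})

test_that("exposure regression recovers an injected condition shift", {
  dat <- make_z_trials(cond_effect = 0.4, noise_sd = 1, seed = 8)
  fit <- exposure_effect_regression(dat, align = "none", mode = "fixed")
  i <- match("condition", fit$term)
  expect_lt(abs(fit$estimate[i] - 0.4), 0.1)
  expect_equal(fit$t[i], fit$estimate[i] / fit$se[i], tolerance = 1e-9)
})

test_that("exposure regression is calibrated under the null", {
  hits <- sapply(1:100, function(s) {
    dat <- make_z_trials(cond_effect = 0, seed = 100 + s)
    fit <- exposure_effect_regression(dat, align = "none", mode = "fixed")
    i <- match("condition", fit$term)
    abs(fit$estimate[i]) < 2 * fit$se[i]
  })
  expect_gte(sum(hits), 90)
})

test_that("exposure regression rejects degenerate inputs", {
  dat <- make_z_trials(seed = 9)
  dat$condition <- "control"
  expect_error(exposure_effect_regression(dat, align = "none"),
               "both exposure conditions")
  dat2 <- make_z_trials(seed = 9)
  dat2$category <- NULL
  expect_error(exposure_effect_regression(dat2, align = "category_match"),
               "category")
})

test_that("the hierarchical backend fits random intercepts when supported", {
  # data with genuine participant and item variance, where the mixed model
  # converges and is preferred by mode = "auto"
  dat <- withr::with_seed(15, {
    base <- make_z_trials(cond_effect = 0.4, noise_sd = 0.6)
    p_off <- rnorm(40, 0, 0.4)
    i_off <- rnorm(60, 0, 0.4)
    base$z_rating <- base$z_rating +
      p_off[as.integer(factor(base$participant_id))] +
      i_off[as.integer(factor(base$token_id))]
    base
  })
  fit <- exposure_effect_regression(dat, align = "none", mode = "lmer")
  expect_equal(attr(fit, "mode"), "lmer")
  expect_match(attr(fit, "grouping"), "random intercepts")
  i <- match("condition", fit$term)
  expect_lt(abs(fit$estimate[i] - 0.4), 0.3)
  fit_auto <- exposure_effect_regression(dat, align = "none", mode = "auto")
  expect_equal(attr(fit_auto, "mode"), "lmer")
  expect_equal(fit_auto$estimate, fit$estimate, tolerance = 1e-8)
})

test_that("estimates are invariant to row order", {
  dat <- make_z_trials(cond_effect = 0.3, seed = 10)
  fit1 <- exposure_effect_regression(dat, align = "none", mode = "fixed")
  perm <- withr::with_seed(1, sample(nrow(dat)))
  fit2 <- exposure_effect_regression(dat[perm, ], align = "none",
                                     mode = "fixed")
  expect_equal(fit1$estimate, fit2$estimate, tolerance = 1e-10)
  expect_equal(fit1$se, fit2$se, tolerance = 1e-10)
})

test_that("interaction term appears when two experiments are present", {
  en <- make_z_trials(cond_effect = 0.5, seed = 11)
  sv <- make_z_trials(cond_effect = 0, seed = 12)
  sv$language <- "swedish"
  sv$participant_id <- paste0("sv_", sv$participant_id)
  fit <- exposure_effect_regression(dplyr::bind_rows(en, sv),
                                    align = "none", mode = "fixed")
  expect_setequal(
    fit$term,
    c("(Intercept)", "condition", "experiment", "condition:experiment")
  )
  i <- match("condition:experiment", fit$term)
  expect_lt(abs(fit$estimate[i] - 0.5), 0.15)
})

test_that("model-fit regression recovers the generating identity-link slope", {
  n_tokens <- 40
  withr::with_seed(13, {
    p <- runif(n_tokens)
    preds <- tibble::tibble(
      token_id = sprintf("tok_%03d", seq_len(n_tokens)),
      condition = "control", block = "d_goodness",
      p_d = p, p_t = 1 - p, posterior_rating = -1 + 2 * p
    )
    rows <- lapply(1:50, function(i) {
      tibble::tibble(
        participant_id = sprintf("p%02d", i),
        token_id = preds$token_id,
        block = "d_goodness", condition = "control", language = "english",
        raw_rating = 4L,
        z_rating = 0.2 + 1.2 * preds$p_d + rnorm(n_tokens, 0, 0.5)
      )
    })
    dat <- dplyr::bind_rows(rows)
  })
  fit <- model_fit_regression(dat, preds, mode = "fixed")
  i <- match("posterior", fit$term)
  expect_lt(abs(fit$estimate[i] - 1.2), 0.15)

  # permutation null: shuffled predictions carry no signal
  hits <- sapply(1:100, function(s) {
    preds_s <- preds
    perm <- withr::with_seed(200 + s, sample(n_tokens))
    preds_s$p_d <- preds$p_d[perm]
    preds_s$p_t <- 1 - preds_s$p_d
    fit_s <- model_fit_regression(dat, preds_s, mode = "fixed")
    j <- match("posterior", fit_s$term)
    abs(fit_s$estimate[j]) < 2 * fit_s$se[j]
  })
  expect_gte(sum(hits), 90)

  preds0 <- preds
  preds0$p_d <- 0.5
  preds0$p_t <- 0.5
  expect_error(model_fit_regression(dat, preds0), "zero variance")
})

test_that("item-level agreement is 1 under any affine relation", {
  item <- tibble::tibble(
    token_id = sprintf("t%d", 1:10), condition = "control",
    block = "d_goodness",
    mean_z_rating = seq(-1, 1, length.out = 10) + c(0.01, -0.02, 0, 0.03,
                                                    0, -0.01, 0.02, 0, 0, 0),
    n_participants = 5L,
    posterior_rating = NA_real_, p_d = NA_real_, p_t = NA_real_
  )
  item$posterior_rating <- item$mean_z_rating
  expect_equal(item_level_agreement(item)$pearson_r, 1, tolerance = 1e-12)
  item$posterior_rating <- 3 + 0.5 * item$mean_z_rating
  expect_equal(item_level_agreement(item)$pearson_r, 1, tolerance = 1e-12)

  withr::with_seed(14, {
    item_null <- item[rep(1, 200), ]
    item_null$mean_z_rating <- rnorm(200)
    item_null$posterior_rating <- rnorm(200)
  })
  expect_lt(abs(item_level_agreement(item_null)$pearson_r), 0.15)

  item_const <- item
  item_const$posterior_rating <- 1
  expect_error(item_level_agreement(item_const), "constant")
  expect_error(item_level_agreement(item[1:2, ]), ">= 3 items")
})
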