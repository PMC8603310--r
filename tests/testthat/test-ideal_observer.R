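test_that("category fitting recovers mean and covariance estimators", {
  cues <- matrix(c(1, 2, 3, 3, 2, 1, 2, 2, 2, 2, 2, 2), 4, byrow = TRUE)
  # the closure dimension is constant here, so the sample covariance is
  # singular and the documented ridge floor kicks in and is recorded
  g <- suppressMessages(fit_gaussian_category(make_tokens(n = 4, cues = cues)))
  expect_equal(unname(g$mean), c(2, 2, 2))
  expect_gt(g$regularization_applied, 0)
  expect_equal(g$cov, stats::cov(cues) + diag(g$regularization_applied, 3),
               ignore_attr = TRUE)
  expect_equal(g$n_tokens, 4L)

  # well-conditioned data: exact unbiased sample covariance, no ridge
  cues_pd <- withr::with_seed(3, matrix(rnorm(30, c(200, 80, 30), 10), 10,
                                        byrow = TRUE))
  g_pd <- fit_gaussian_category(make_tokens(n = 10, cues = cues_pd))
  expect_equal(g_pd$cov, stats::cov(cues_pd), ignore_attr = TRUE)
  expect_equal(g_pd$regularization_applied, 0)

  expect_error(fit_gaussian_category(make_tokens(n = 3)), "at least 4")
  mixed <- make_tokens(n = 4)
  mixed$category <- c("d", "d", "t", "t")
  expect_error(fit_gaussian_category(mixed), "single category")
})

test_that("degenerate identical tokens need an explicit ridge", {
  cues <- matrix(rep(c(100, 50, 20), each = 6), 6)
  tok <- make_tokens(n = 6, cues = cues)
  expect_error(fit_gaussian_category(tok, ridge = 0), "singular")
  g <- suppressMessages(fit_gaussian_category(tok, ridge = 2))
  expect_equal(g$cov, diag(2, 3), ignore_attr = TRUE)
})

test_that("parameter recovery: 10,000 simulated tokens", {
  mu <- c(200, 80, 30)
  # all covariance entries well away from zero so 10% relative recovery is
  # a meaningful bound for every entry
  S <- diag(c(30, 20, 12)) %*%
    matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3) %*% diag(c(30, 20, 12))
  X <- withr::with_seed(99, MASS::mvrnorm(10000, mu, S))
  g <- fit_gaussian_category(make_tokens(n = 10000, cues = X))
  expect_true(all(abs(g$mean - mu) / mu < 0.02))
  expect_true(all(abs(g$cov - S) / abs(S) < 0.10))
})

test_that("fit errors shrink with sample size (consistency)", {
  mu <- c(200, 80, 30)
  S <- matrix(c(900, 180, 60, 180, 400, 40, 60, 40, 144), 3)
  err <- sapply(c(50, 500, 5000), function(n) {
    X <- withr::with_seed(7, MASS::mvrnorm(n, mu, S))
    g <- fit_gaussian_category(make_tokens(n = n, cues = X))
    max(abs(g$mean - mu) / mu)
  })
  expect_lt(err[3], err[1])
})

test_that("log density matches closed form and brute-force oracle", {
  g <- make_category("d", c(0, 0, 0), diag(1, 3))
  expect_equal(log_density(g, c(0, 0, 0)), -1.5 * log(2 * pi),
               tolerance = 1e-12)
  withr::with_seed(11, {
    for (i in 1:25) {
      mu <- rnorm(3, 0, 5)
      S <- random_pd_cov()
      x <- rnorm(3, 0, 5)
      g <- make_category("d", mu, S)
      expect_equal(log_density(g, x), oracle_log_density(mu, S, x),
                   tolerance = 1e-10)
    }
  })
  expect_error(log_density(g, c(1, NA, 2)), "non-finite")
})

test_that("the density normalizes to 1 (Monte-Carlo integral)", {
  mu <- c(1, -2, 0.5)
  S <- diag(c(1, 2, 0.5))
  g <- make_category("d", mu, S)
  withr::with_seed(5, {
    lo <- mu - 5 * sqrt(diag(S)); hi <- mu + 5 * sqrt(diag(S))
    n <- 4e6
    X <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
    vol <- prod(hi - lo)
    integral <- mean(exp(log_density(g, X))) * vol
    expect_equal(integral, 1, tolerance = 0.01)
  })
})

test_that("posterior follows Bayes' rule: symmetry and likelihood ratios", {
  S <- diag(c(4, 4, 4))
  obs <- make_observer(c(-1, 0, 0), S, c(1, 0, 0), S)
  # equidistant point with equal covariances and uniform priors
  p <- posterior(obs, c(0, 0.7, -0.3))
  expect_equal(unname(p["d"]), 0.5, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # a likelihood ratio of 3 with uniform priors forces p_d = 0.75: place
  # the point so the Mahalanobis difference gives exactly log(3)
  # For 1D-like setup along x: ll_d - ll_t = (2*x*(mu_t-mu_d)... solve directly:
  # with unit-variance x-axis distance d1, d2: ratio = exp(-(d1^2-d2^2)/2)
  S1 <- diag(1, 3)
  obs1 <- make_observer(c(0, 0, 0), S1, c(2, 0, 0), S1)
  # at point x: ll_d - ll_t = -(x^2 - (x-2)^2)/2 = -(4x-4)/2 = 2-2x = log(3)
  x_star <- (2 - log(3)) / 2
  p1 <- posterior(obs1, c(x_star, 5, -5))
  expect_equal(unname(p1["d"]), 0.75, tolerance = 1e-12)
})

test_that("posterior is monotone in the /d/ likelihood and in the prior", {
  S <- diag(1, 3)
  x <- c(0.4, 0, 0)
  # moving the /d/ mean toward x strictly increases log_lik_d, hence p_d
  p_vals <- sapply(c(3, 2, 1, 0.5), function(dist) {
    obs <- make_observer(c(0.4 + dist, 0, 0), S, c(-2, 0, 0), S)
    unname(posterior(obs, x)["d"])
  })
  expect_true(all(diff(p_vals) > 0))

  # prior sensitivity at fixed likelihoods
  p_prior <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(pd) {
    obs <- make_observer(c(1, 0, 0), S, c(-1, 0, 0), S, prior_d = pd)
    unname(posterior(obs, x)["d"])
  })
  expect_true(all(diff(p_prior) > 0))
})

test_that("equal covariances give exactly linear log-odds (LDA limit)", {
  withr::with_seed(21, {
    S <- random_pd_cov(2)
    mu_d <- rnorm(3); mu_t <- rnorm(3)
    prior_d <- 0.3
    obs <- make_observer(mu_d, S, mu_t, S, prior_d = prior_d)
    w <- solve(S, mu_d - mu_t)
    b <- -0.5 * (sum(mu_d * solve(S, mu_d)) - sum(mu_t * solve(S, mu_t))) +
      log(prior_d / (1 - prior_d))
    for (i in 1:20) {
      x <- rnorm(3, 0, 3)
      p <- posterior(obs, x)
      expect_equal(log(p[["d"]] / p[["t"]]), sum(w * x) + b, tolerance = 1e-8)
    }
  })
})

test_that("condition observers use the stipulated token sources", {
  exp_data <- run_synthetic_experiment("english_like", seed = 31)
  nat <- exp_data$corrected[exp_data$corrected$accent == "native", ]
  non <- exp_data$corrected[exp_data$corrected$accent == "nonnative", ]
  ctrl <- build_condition_observer("control", nat, non)
  expo <- build_condition_observer("d_exposure", nat, non)

  expect_true(all(grepl("^nat_d", ctrl$provenance$d)))
  expect_true(all(grepl("^exp_d", expo$provenance$d)))
  expect_identical(ctrl$provenance$t, expo$provenance$t)
  expect_equal(unname(ctrl$priors), c(0.5, 0.5))

  expect_error(
    build_condition_observer("d_exposure", nat, non[non$phase == "test", ]),
    "exposure-phase"
  )
  expect_error(
    build_condition_observer("control", nat[nat$category == "t", ], non),
    "native /d/"
  )
})

test_that("posterior ratings are the affine image of the block posterior", {
  exp_data <- run_synthetic_experiment("english_like", seed = 32)
  obs <- exp_data$observers$control
  test_tok <- exp_data$test_tokens
  pr <- posterior_ratings(obs, test_tok, "d_goodness", c(-1, 1))
  expect_equal(pr$posterior_rating, -1 + 2 * pr$p_d, tolerance = 1e-12)
  expect_equal(pr$p_d + pr$p_t, rep(1, nrow(pr)), tolerance = 1e-12)
  pr_t <- posterior_ratings(obs, test_tok, "t_goodness", c(-1, 1))
  expect_equal(pr_t$posterior_rating, -1 + 2 * pr_t$p_t, tolerance = 1e-12)
  # midpoint and endpoint images
  expect_equal(-1 + 2 * 0.5, 0)
  # empty test set
  empty <- posterior_ratings(obs, test_tok[0, ], "d_goodness")
  expect_equal(nrow(empty), 0)
})

test_that("identical observers predict zero exposure delta", {
  exp_data <- run_synthetic_experiment("english_like", seed = 33)
  ctrl <- exp_data$observers$control
  eff <- exposure_effect_prediction(ctrl, ctrl, exp_data$test_tokens)
  expect_true(all(eff$per_token$delta == 0))
})

test_that("observers serialize to JSON and back exactly", {
  exp_data <- run_synthetic_experiment("english_like", seed = 34)
  obs <- exp_data$observers$d_exposure
  path <- withr::local_tempfile(fileext = ".json")
  observer_to_json(obs, path)
  back <- observer_from_json(path)
  expect_equal(back$categories$d$mean, obs$categories$d$mean,
               ignore_attr = TRUE)
  expect_equal(back$categories$t$cov, obs$categories$t$cov,
               ignore_attr = TRUE)
  expect_equal(back$priors, obs$priors)
  x <- c(180, 90, 20)
  expect_equal(posterior(back, x), posterior(obs, x), tolerance = 1e-12)
})

test_that("fold robustness is deterministic and direction-stable", {
  ov <- list(n_exposure_tokens = 60L, n_native_tokens_per_category = 60L,
             n_test_pairs = 30L)
  exp_data <- run_synthetic_experiment("english_like", seed = 35,
                                       overrides = ov)
  nat <- exp_data$corrected[exp_data$corrected$accent == "native", ]
  non <- exp_data$corrected[exp_data$corrected$accent == "nonnative", ]
  expect_error(fold_robustness(nat, non, k = 1, seed = 1), "k must be")
  f1 <- fold_robustness(nat, non, k = 4, seed = 17)
  f2 <- fold_robustness(nat, non, k = 4, seed = 17)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 4)
  # english-like geometry: positive held-out /d/ delta in >= 3 of 4 folds
  expect_gte(sum(f1$mean_delta_d > 0), 3)
})
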