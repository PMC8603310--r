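# Fixture builders and independent brute-force oracles shared across tests.

# -- oracles ----------------------------------------------------------------

# Direct evaluation of the trivariate Gaussian log density with explicit
# matrix inverse and determinant (independent of the package's
# Cholesky-based path).
oracle_log_density <- function(mu, S, x) {
  d <- length(mu)
  diff <- x - mu
  -0.5 * (d * log(2 * pi) + log(det(S)) +
            as.numeric(t(diff) %*% solve(S) %*% diff))
}

# Explicit Bayes' rule on raw densities (no log-space tricks); valid when
# densities do not underflow, i.e. for modest-scale test instances.
oracle_posterior_d <- function(mu_d, S_d, mu_t, S_t, prior_d, x) {
  dd <- exp(oracle_log_density(mu_d, S_d, x))
  dt <- exp(oracle_log_density(mu_t, S_t, x))
  dd * prior_d / (dd * prior_d + dt * (1 - prior_d))
}

# -- construction helpers ---------------------------------------------------

make_category <- function(label, mean, cov, n = 30) {
  structure(
    list(label = label, mean = mean, cov = cov, n_tokens = n,
         regularization_applied = 0),
    class = "gaussian_category"
  )
}

make_observer <- function(mu_d, S_d, mu_t, S_t, prior_d = 0.5) {
  structure(
    list(
      categories = list(
        d = make_category("d", mu_d, S_d),
        t = make_category("t", mu_t, S_t)
      ),
      priors = c(d = prior_d, t = 1 - prior_d),
      condition = NULL,
      provenance = list(d = character(0), t = character(0))
    ),
    class = "ideal_observer"
  )
}

random_pd_cov <- function(scale = 1) {
  A <- matrix(rnorm(9), 3)
  scale * (crossprod(A) + diag(0.5, 3))
}

# Minimal well-formed token table.
make_tokens <- function(n = 8, category = "d", accent = "native",
                        phase = "exposure", language = "english",
                        cues = NULL, prefix = "tok") {
  if (is.null(cues)) {
    cues <- matrix(rep(c(200, 80, 30), each = n), n) +
      matrix(rnorm(3 * n, 0, 5), n)
  }
  tibble::tibble(
    token_id = sprintf("%s_%03d", prefix, seq_len(n)),
    word = sprintf("w%03d", seq_len(n)),
    minimal_pair_id = "",
    talker_id = "tk1",
    language = language,
    accent = accent,
    phase = phase,
    category = category,
    vowel_ms = cues[, 1], closure_ms = cues[, 2], burst_ms = cues[, 3]
  )
}

make_ratings <- function(n_participants = 6, n_trials = 10,
                         condition = c("control", "d_exposure"),
                         language = "english", seed = NULL) {
  build <- function() {
    rows <- lapply(seq_len(n_participants), function(i) {
      cond <- condition[(i %% length(condition)) + 1]
      tibble::tibble(
        participant_id = sprintf("p%02d", i),
        token_id = sprintf("tok_%03d", seq_len(n_trials)),
        block = rep(c("d_goodness", "t_goodness"), length.out = n_trials),
        condition = cond,
        language = language,
        raw_rating = sample(1:7, n_trials, replace = TRUE)
      )
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Full desk-scale synthetic experiment: tokens -> correction -> observers ->
# ratings (z-scored). Returns all stage objects.
run_synthetic_experiment <- function(preset, seed, language = NULL,
                                     overrides = list()) {
  ov <- utils::modifyList(list(seed = seed), overrides)
  if (!is.null(language)) ov$language <- language
  spec <- expand_preset(preset, ov)
  tokens <- suppressMessages(generate_production_tokens(spec))
  cmodel <- fit_context_model(tokens[tokens$accent == "native", ], "context_frame")
  corrected <- correct_cues(tokens, cmodel, unseen = "zero")
  nat <- corrected[corrected$accent == "native", ]
  non <- corrected[corrected$accent == "nonnative", ]
  observers <- list(
    control = build_condition_observer("control", nat, non),
    d_exposure = build_condition_observer("d_exposure", nat, non)
  )
  test_tokens <- corrected[corrected$phase == "test", ]
  ratings <- generate_rating_experiment(spec, observers, test_tokens)
  ratings <- suppressWarnings(zscore_within_participant(ratings))
  list(spec = spec, tokens = tokens, corrected = corrected,
       observers = observers, test_tokens = test_tokens, ratings = ratings)
}
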