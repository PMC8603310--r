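#' Scenario presets: calibration constants
#'
#' All preset distribution parameters live here, calibrated once against
#' the qualitative geometry the analysis targets (separations expressed in
#' pooled-SD units), not against any measured corpus; they are invented,
#' realistic duration values. Native categories separate on all three
#' cues, most strongly on vowel and closure (long vowel + short closure
#' signals /d/). The `english_like` non-native talker devoices: /d/ and /t/
#' means are identical on vowel and closure and separate only along burst
#' duration (by 6 pooled SDs, well above the 3-SD construction floor). The
#' `swedish_like` non-native talker stays within 0.5 pooled SD of native on
#' every dimension. `null_effect` makes the non-native parameters
#' bit-identical to the native ones.
#'
#' @keywords internal
#' @name preset_calibration
NULL

# (vowel, closure, burst) in ms; covariance = diag(sd^2) with a mild
# positive vowel-closure correlation (0.3), diagonal-dominant.
make_cov <- function(sd_vec, rho_vc = 0.3) {
  S <- diag(sd_vec^2)
  S[1, 2] <- S[2, 1] <- rho_vc * sd_vec[1] * sd_vec[2]
  dimnames(S) <- list(CUE_COLS, CUE_COLS)
  S
}

PRESET_PARAMS <- local({
  native_sd <- c(30, 20, 12)
  nonnat_sd <- c(30, 20, 10)
  native <- list(
    d = list(mean = c(220, 60, 30), cov = make_cov(native_sd)),
    t = list(mean = c(160, 110, 45), cov = make_cov(native_sd))
  )
  list(
    english_like = list(
      native = native,
      # final-stop devoicing: vowel/closure collapse to /t/-like values for
      # both categories, voicing carried by burst alone
      nonnative = list(
        d = list(mean = c(172, 95, 15), cov = make_cov(nonnat_sd)),
        t = list(mean = c(172, 95, 75), cov = make_cov(nonnat_sd))
      )
    ),
    swedish_like = list(
      native = native,
      # near-native realization: every mean within ~0.2 pooled SD of native
      # (comfortably inside the 0.5-SD construction ceiling), so the
      # exposure statistics carry almost no information the native
      # categories lack
      nonnative = list(
        d = list(mean = c(214, 64, 32), cov = make_cov(native_sd)),
        t = list(mean = c(157, 112, 47), cov = make_cov(native_sd))
      )
    ),
    null_effect = list(
      native = native,
      nonnative = native
    )
  )
})

#' Expand a named scenario preset into a full scenario spec
#'
#' @param name One of `"english_like"`, `"swedish_like"`, `"null_effect"`.
#' @param overrides Named list of fields to override (recursively merged),
#'   e.g. `list(seed = 7)` or `list(link = list(noise_sd = 0))`.
#' @return A `scenario_spec`: category distribution parameters per
#'   (accent, category), token counts (30 exposure /d/ tokens, 30 native
#'   tokens per category, 15 test minimal pairs), context effects, the
#'   rating link (slope, noise SD), participant count per condition, and
#'   seed.
#' @export
expand_preset <- function(name, overrides = list()) {
  if (!name %in% names(PRESET_PARAMS)) {
    stop("unknown preset: ", name, " (available: ",
         paste(names(PRESET_PARAMS), collapse = ", "), ")", call. = FALSE)
  }
  language <- if (name == "swedish_like") "swedish" else "english"
  spec <- list(
    name = name,
    language = language,
    categories = PRESET_PARAMS[[name]],
    n_exposure_tokens = 30L,
    n_native_tokens_per_category = 30L,
    n_test_pairs = 15L,
    # one categorical context predictor (carrier-frame prosody) with a
    # known additive effect on vowel and closure, exercised by the C-CuRE
    # correction
    context_effects = list(
      frame = list(a_frame = c(0, 0, 0), b_frame = c(20, 8, 0))
    ),
    link = list(slope = 1, noise_sd = 0.3),
    n_participants_per_condition = 24L,
    seed = 1L
  )
  spec <- utils::modifyList(spec, overrides)
  validate_scenario_spec(spec)
  structure(spec, class = "scenario_spec")
}

validate_scenario_spec <- function(spec) {
  if (spec$n_exposure_tokens < 4) {
    stop("n_exposure_tokens must be >= 4", call. = FALSE)
  }
  if (spec$link$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (acc in names(spec$categories)) {
    for (cat in names(spec$categories[[acc]])) {
      S <- spec$categories[[acc]][[cat]]$cov
      if (max(abs(S - t(S))) > 1e-9 * max(abs(S))) {
        stop("covariance for ", acc, " /", cat, "/ not symmetric", call. = FALSE)
      }
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        stop("covariance for ", acc, " /", cat, "/ not positive definite",
             call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario spec '", x$name, "' (language: ", x$language, ", seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  %d exposure /d/ tokens, %d native tokens/category, %d test pairs, %d participants/condition\n",
              x$n_exposure_tokens, x$n_native_tokens_per_category,
              x$n_test_pairs, x$n_participants_per_condition))
  cat(sprintf("  link: slope %.2f, noise sd %.2f\n",
              x$link$slope, x$link$noise_sd))
  invisible(x)
}

draw_block <- function(n, mu, Sigma) {
  X <- MASS::mvrnorm(n, mu, Sigma)
  if (n == 1) X <- matrix(X, nrow = 1)
  colnames(X) <- CUE_COLS
  X
}

assign_context <- function(n, spec) {
  preds <- names(spec$context_effects)
  if (length(preds) == 0) {
    return(list(cols = NULL, shift = matrix(0, n, 3)))
  }
  cols <- list()
  shift <- matrix(0, n, 3)
  for (p in preds) {
    levels <- names(spec$context_effects[[p]])
    lv <- rep_len(levels, n)  # balanced round-robin assignment
    cols[[paste0("context_", p)]] <- lv
    for (l in levels) {
      shift[lv == l, ] <- shift[lv == l, , drop = FALSE] +
        matrix(spec$context_effects[[p]][[l]], sum(lv == l), 3, byrow = TRUE)
    }
  }
  list(cols = cols, shift = shift)
}

#' Generate a production-token table from a scenario spec
#'
#' Emulates the production side of an exposure-test accent experiment:
#' native /d/ and /t/ recordings (the control listener's category
#' statistics), 30 non-native exposure-phase /d/ recordings (what the
#' /d/-exposure group learns from), and non-native /d/-/t/ minimal-pair
#' test tokens. Cue vectors are drawn from the spec's multivariate
#' Gaussians, context shifts are added per assigned context level, and
#' draws below 1 ms are truncated to 1 ms with a logged count.
#'
#' @param spec A [expand_preset()] result (or hand-built `scenario_spec`).
#' @return A validated token table.
#' @export
generate_production_tokens <- function(spec) {
  validate_scenario_spec(spec)
  lang <- spec$language
  with_seed(derive_seed(spec$seed, "tokens"), {
    blocks <- list()

    emit <- function(prefix, n, accent, category, phase, talker,
                     words, pair_ids = "") {
      par <- spec$categories[[accent]][[category]]
      X <- draw_block(n, par$mean, par$cov)
      ctx <- assign_context(n, spec)
      X <- X + ctx$shift
      df <- tibble::tibble(
        token_id = sprintf("%s_%03d", prefix, seq_len(n)),
        word = words,
        minimal_pair_id = pair_ids,
        talker_id = talker,
        language = lang,
        accent = accent,
        phase = phase,
        category = category,
        vowel_ms = X[, 1], closure_ms = X[, 2], burst_ms = X[, 3]
      )
      if (!is.null(ctx$cols)) for (nm in names(ctx$cols)) df[[nm]] <- ctx$cols[[nm]]
      df
    }

    n_nat <- spec$n_native_tokens_per_category
    blocks$nat_d <- emit("nat_d", n_nat, "native", "d", "exposure",
                         "native_1", sprintf("dword_%02d", seq_len(n_nat)))
    blocks$nat_t <- emit("nat_t", n_nat, "native", "t", "exposure",
                         "native_1", sprintf("tword_%02d", seq_len(n_nat)))
    n_exp <- spec$n_exposure_tokens
    blocks$non_exp <- emit("exp_d", n_exp, "nonnative", "d", "exposure",
                           "nonnative_1", sprintf("dword_%02d", seq_len(n_exp)))
    n_pair <- spec$n_test_pairs
    blocks$test_d <- emit("test_d", n_pair, "nonnative", "d", "test",
                          "nonnative_1", sprintf("pair%02d_d", seq_len(n_pair)),
                          sprintf("mp_%02d", seq_len(n_pair)))
    blocks$test_t <- emit("test_t", n_pair, "nonnative", "t", "test",
                          "nonnative_1", sprintf("pair%02d_t", seq_len(n_pair)),
                          sprintf("mp_%02d", seq_len(n_pair)))

    tokens <- dplyr::bind_rows(blocks)
    n_trunc <- sum(as.matrix(tokens[, CUE_COLS]) < 1)
    if (n_trunc > 0) {
      log_msg("simulate", n_trunc,
              " negative/sub-ms duration draw(s) truncated at 1 ms")
      for (cue in CUE_COLS) tokens[[cue]] <- pmax(tokens[[cue]], 1)
    }
    validate_tokens(tokens)
    tokens
  })
}

#' Generate a synthetic rating experiment
#'
#' Simulates Likert goodness ratings under the identity-link assumption the
#' analysis tests: each participant is assigned an exposure condition; for
#' each test token and rating block, the latent goodness is
#' `slope * posterior_rating` (the scaled posterior under that condition's
#' observer) plus Gaussian response noise, mapped affinely from the rating
#' range onto \[1, 7\] and rounded to the nearest point of the 7-point
#' scale. Block membership of minimal-pair members is counterbalanced
#' across participants (each participant rates each token once, pair
#' members in different blocks).
#'
#' With `noise_sd = 0` and `slope = 1` the ratings are the deterministic
#' discretization of the posterior ratings.
#'
#' @param spec A `scenario_spec` (supplies link, participant count, seed).
#' @param observers Named list with `control` and `d_exposure`
#'   [build_condition_observer()] results.
#' @param test_tokens Test-phase token table the ratings refer to
#'   (typically context-corrected, matching how the observers were fit).
#' @param rating_range Range the posterior is scaled to; default
#'   `c(-1, 1)`.
#' @return A validated rating table (with `category` carried along as an
#'   extra column for block alignment); `z_rating` unset.
#' @export
generate_rating_experiment <- function(spec, observers, test_tokens,
                                       rating_range = c(-1, 1)) {
  stopifnot(all(c("control", "d_exposure") %in% names(observers)))
  if (spec$link$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  test_tokens <- tibble::as_tibble(test_tokens)

  # per-condition, per-block predictions computed once
  preds <- list()
  for (cond in c("control", "d_exposure")) {
    for (blk in c("d_goodness", "t_goodness")) {
      pr <- posterior_ratings(observers[[cond]], test_tokens, blk, rating_range)
      preds[[paste(cond, blk)]] <- setNames(pr$posterior_rating, pr$token_id)
    }
  }
  tok_cat <- setNames(as.character(test_tokens$category), test_tokens$token_id)
  pair_of <- setNames(as.character(test_tokens$minimal_pair_id), test_tokens$token_id)

  with_seed(derive_seed(spec$seed, "ratings"), {
    rows <- list()
    for (cond in c("control", "d_exposure")) {
      for (i in seq_len(spec$n_participants_per_condition)) {
        pid <- sprintf("P_%s_%02d", cond, i)
        # counterbalance: alternate which pair member lands in the /d/ block
        # across pairs (so each block mixes /d/ and /t/ words) and across
        # participants (so each token is rated in both blocks overall)
        flip <- i %% 2 == 0
        pair_rank <- stats::ave(seq_along(pair_of), pair_of, FUN = seq_along)
        pair_index <- as.integer(factor(pair_of, levels = unique(pair_of)))
        in_d_block <- xor((pair_index + pair_rank) %% 2 == 0, flip)
        block <- ifelse(in_d_block, "d_goodness", "t_goodness")
        key <- paste(cond, block)
        scaled <- vapply(seq_along(block), function(j) {
          preds[[key[j]]][[names(pair_of)[j]]]
        }, numeric(1))
        latent <- spec$link$slope * scaled +
          stats::rnorm(length(scaled), 0, spec$link$noise_sd)
        raw <- round(1 + 6 * (latent - rating_range[1]) / diff(rating_range))
        raw <- pmin(pmax(raw, 1), 7)
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = pid,
          token_id = names(pair_of),
          block = block,
          condition = cond,
          language = spec$language,
          raw_rating = as.integer(raw),
          category = unname(tok_cat[names(pair_of)])
        )
      }
    }
    ratings <- dplyr::bind_rows(rows)
    validate_ratings(ratings)
    ratings$z_rating <- NA_real_
    ratings
  })
}
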