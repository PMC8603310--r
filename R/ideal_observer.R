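#' Fit a multivariate Gaussian phonetic category
#'
#' Estimates a category's cue distribution — mean vector and covariance in
#' the 3D space of vowel, closure, and burst duration — from production
#' tokens of that category. The covariance is the unbiased (n-1) sample
#' estimate plus `ridge` times the identity. If the result is still not
#' positive definite (e.g. degenerate tokens), the ridge is escalated to
#' `1e-6 * trace(cov)/3` (floor `1e-8`) and the amount actually applied is
#' recorded in `regularization_applied`.
#'
#' Tokens with a missing burst (unreleased stop) are excluded, with the
#' count logged.
#'
#' @param tokens Token table; all rows must share one category label and at
#'   least 4 complete tokens are required (more tokens than cue dimensions).
#' @param ridge Non-negative ridge added to the covariance diagonal
#'   (ms^2). Default 0: with ~30 tokens in 3 dimensions the sample
#'   covariance is usually well-conditioned, and silent regularization
#'   would bias the exposure-effect deltas.
#' @return A `gaussian_category` with fields `label`, `mean` (ms), `cov`
#'   (ms^2), `n_tokens`, `regularization_applied`.
#' @export
fit_gaussian_category <- function(tokens, ridge = 0) {
  stopifnot(ridge >= 0)
  tokens <- tibble::as_tibble(tokens)
  labs <- unique(as.character(tokens$category))
  if (length(labs) != 1) {
    stop("tokens must share a single category label; got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(tokens[, CUE_COLS])
  if (any(!complete)) {
    log_msg("fit", sum(!complete), " token(s) with missing burst excluded from ",
            labs, " category fit")
  }
  X <- as.matrix(tokens[complete, CUE_COLS])
  if (nrow(X) < 4) {
    stop("need at least 4 complete tokens to fit a 3D Gaussian category; got ",
         nrow(X), call. = FALSE)
  }
  mu <- colMeans(X)
  S <- stats::cov(X) + diag(ridge, 3)
  applied <- ridge
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    if (ridge > 0) {
      # caller-supplied ridge insufficient for a PD covariance: escalate
      extra <- max(1e-6 * sum(diag(S)) / 3, 1e-8)
    } else {
      extra <- max(1e-6 * sum(diag(S)) / 3, 1e-8)
      if (extra <= 0) extra <- 1e-8
    }
    if (ridge == 0 && all(abs(S) < .Machine$double.eps)) {
      stop("singular sample covariance (all tokens identical) and ridge = 0",
           call. = FALSE)
    }
    S <- S + diag(extra, 3)
    applied <- ridge + extra
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("covariance not positive definite even after regularization",
           call. = FALSE)
    }
    log_msg("fit", "ridge escalated to ", format(applied),
            " for category ", labs)
  }
  structure(
    list(
      label = labs,
      mean = mu,
      cov = S,
      n_tokens = nrow(X),
      regularization_applied = applied
    ),
    class = "gaussian_category"
  )
}

#' @export
print.gaussian_category <- function(x, ...) {
  cat(sprintf("Gaussian category /%s/ (n = %d tokens)\n", x$label, x$n_tokens))
  cat("  mean (ms):", paste(sprintf("%s=%.1f", CUE_COLS, x$mean), collapse = ", "), "\n")
  cat(sprintf("  cov diag (ms^2): %s\n",
              paste(sprintf("%.1f", diag(x$cov)), collapse = ", ")))
  if (x$regularization_applied > 0) {
    cat("  ridge applied:", format(x$regularization_applied), "\n")
  }
  invisible(x)
}

#' Build a condition-specific ideal observer
#'
#' An ideal observer holds one Gaussian category per contrast member (/d/
#' and /t/) plus category priors, and categorizes a cue vector by Bayes'
#' rule. The /t/ category is always fit from native /t/ tokens — neither
#' exposure condition presents lexically labeled /t/, so both idealized
#' listeners are assumed to keep native /t/ expectations. The /d/ category
#' is fit from native /d/ tokens for the control observer, and from the
#' non-native exposure-phase /d/ tokens for the /d/-exposure observer
#' (a listener who has completely learned the exposure talker's /d/
#' statistics).
#'
#' @param condition `"control"` or `"d_exposure"`.
#' @param native_tokens Native-accent tokens containing both /d/ and /t/.
#' @param nonnative_tokens Non-native tokens; exposure-phase /d/ rows are
#'   used when `condition = "d_exposure"`.
#' @param priors Named category priors; default uniform `c(d = .5, t = .5)`
#'   (test items are minimal pairs, so both categories are equally expected).
#' @param ridge Passed to [fit_gaussian_category()].
#' @return An `ideal_observer` with `categories`, `priors`, and
#'   `provenance` recording the token ids behind each category.
#' @export
build_condition_observer <- function(condition = c("control", "d_exposure"),
                                     native_tokens,
                                     nonnative_tokens = NULL,
                                     priors = c(d = 0.5, t = 0.5),
                                     ridge = 0) {
  condition <- match.arg(condition)
  if (!all(c("d", "t") %in% names(priors)) || abs(sum(priors) - 1) > 1e-12) {
    stop("priors must be named over {d, t} and sum to 1", call. = FALSE)
  }
  native_tokens <- tibble::as_tibble(native_tokens)
  nat_t <- native_tokens[native_tokens$category == "t", ]
  if (nrow(nat_t) == 0) {
    stop("condition ", condition, ": no native /t/ tokens", call. = FALSE)
  }
  d_source <- if (condition == "control") {
    src <- native_tokens[native_tokens$category == "d", ]
    if (nrow(src) == 0) stop("condition control: no native /d/ tokens", call. = FALSE)
    src
  } else {
    if (is.null(nonnative_tokens)) {
      stop("condition d_exposure: nonnative_tokens required", call. = FALSE)
    }
    nonnative_tokens <- tibble::as_tibble(nonnative_tokens)
    src <- nonnative_tokens[nonnative_tokens$category == "d" &
                              nonnative_tokens$phase == "exposure", ]
    if (nrow(src) == 0) {
      stop("condition d_exposure: no non-native exposure-phase /d/ tokens",
           call. = FALSE)
    }
    src
  }
  obs <- list(
    categories = list(
      d = fit_gaussian_category(d_source, ridge = ridge),
      t = fit_gaussian_category(nat_t, ridge = ridge)
    ),
    priors = priors[c("d", "t")],
    condition = condition,
    provenance = list(
      d = as.character(d_source$token_id),
      t = as.character(nat_t$token_id)
    )
  )
  class(obs) <- "ideal_observer"
  obs
}

#' @export
print.ideal_observer <- function(x, ...) {
  cat(sprintf("Ideal observer (%s condition)\n", x$condition %||% "unspecified"))
  cat(sprintf("  priors: d = %.2f, t = %.2f\n", x$priors[["d"]], x$priors[["t"]]))
  for (lab in names(x$categories)) {
    g <- x$categories[[lab]]
    cat(sprintf("  /%s/: n = %d, mean = (%s) ms\n", lab, g$n_tokens,
                paste(sprintf("%.1f", g$mean), collapse = ", ")))
  }
  invisible(x)
}

#' Log-density of a category at a cue point
#'
#' Exact log of the trivariate Gaussian density, evaluated via the Cholesky
#' factor of the covariance (numerically stable: duration covariances in
#' ms^2 make raw densities extremely small).
#'
#' @param category A `gaussian_category`.
#' @param cues Numeric cue vector (vowel, closure, burst; ms) or a matrix
#'   with one cue vector per row.
#' @return Log density (one value per cue point).
#' @export
log_density <- function(category, cues) {
  stopifnot(inherits(category, "gaussian_category"))
  X <- if (is.matrix(cues)) cues else matrix(cues, nrow = 1)
  if (ncol(X) != 3) stop("cue points must have 3 dimensions", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite cue value", call. = FALSE)
  R <- chol(category$cov)
  log_det <- 2 * sum(log(diag(R)))
  centered <- sweep(X, 2, category$mean)
  # Mahalanobis via triangular solve: z = R^-T (x - mu)
  z <- backsolve(R, t(centered), transpose = TRUE)
  maha <- colSums(z^2)
  -0.5 * (3 * log(2 * pi) + log_det + maha)
}

#' Posterior category probabilities for a cue point
#'
#' Bayes' rule over the observer's categories:
#' p(c | cues) = p(cues | c) p(c) / sum_i p(cues | c_i) p(c_i),
#' computed in log space with max-subtraction so extreme likelihoods cannot
#' underflow.
#'
#' @param observer An `ideal_observer`.
#' @param cues Numeric cue vector (length 3) or matrix of cue rows.
#' @return For a single point, a named probability vector over `{d, t}`
#'   summing to 1; for a matrix, a matrix with columns `d`, `t`.
#' @export
posterior <- function(observer, cues) {
  stopifnot(inherits(observer, "ideal_observer"))
  X <- if (is.matrix(cues)) cues else matrix(cues, nrow = 1)
  log_post <- sapply(names(observer$categories), function(lab) {
    log_density(observer$categories[[lab]], X) + log(observer$priors[[lab]])
  })
  if (nrow(X) == 1) log_post <- matrix(log_post, nrow = 1,
                                       dimnames = list(NULL, names(observer$categories)))
  m <- apply(log_post, 1, max)
  w <- exp(log_post - m)
  p <- w / rowSums(w)
  if (!is.matrix(cues)) {
    return(setNames(as.numeric(p[1, ]), colnames(p)))
  }
  p
}

#' Posterior ratings for test tokens
#'
#' Computes each test token's posterior probability of the block's category
#' and rescales it affinely from \[0, 1\] onto `rating_range`, the range of
#' (z-scored) human ratings, so model predictions and human ratings can be
#' plotted on a common scale. The identity link — posterior probability
#' taken directly as predicted category goodness — is motivated by the
#' linear relation observed between categorization proportions and goodness
#' ratings for stimuli of this kind. The affine rescaling leaves all
#' correlations with human ratings unchanged.
#'
#' @param observer An `ideal_observer`.
#' @param test_tokens Token table of test items.
#' @param block `"d_goodness"` or `"t_goodness"`: which category is being
#'   rated; the posterior of that category drives the rating.
#' @param rating_range Length-2 numeric `c(lo, hi)`, `lo < hi`. Default
#'   `c(-1, 1)`, the span of z-scored by-item mean ratings the scaling
#'   targets.
#' @return Tibble with one row per test token: `token_id`, `p_d`, `p_t`,
#'   `log_lik_d`, `log_lik_t`, `block`, `posterior_rating`.
#' @export
posterior_ratings <- function(observer, test_tokens,
                              block = c("d_goodness", "t_goodness"),
                              rating_range = c(-1, 1)) {
  block <- match.arg(block)
  stopifnot(length(rating_range) == 2, rating_range[1] < rating_range[2])
  test_tokens <- tibble::as_tibble(test_tokens)
  if (nrow(test_tokens) == 0) {
    return(tibble::tibble(
      token_id = character(0), p_d = numeric(0), p_t = numeric(0),
      log_lik_d = numeric(0), log_lik_t = numeric(0),
      block = character(0), posterior_rating = numeric(0)
    ))
  }
  X <- as.matrix(test_tokens[, CUE_COLS])
  p <- posterior(observer, X)
  ll_d <- log_density(observer$categories$d, X)
  ll_t <- log_density(observer$categories$t, X)
  p_block <- if (block == "d_goodness") p[, "d"] else p[, "t"]
  tibble::tibble(
    token_id = as.character(test_tokens$token_id),
    p_d = as.numeric(p[, "d"]),
    p_t = as.numeric(p[, "t"]),
    log_lik_d = as.numeric(ll_d),
    log_lik_t = as.numeric(ll_t),
    block = block,
    posterior_rating = rating_range[1] +
      diff(rating_range) * as.numeric(p_block)
  )
}

#' Predicted effect of /d/-exposure on test-token ratings
#'
#' Applies the control and /d/-exposure observers to the same test tokens
#' and takes the per-token difference of posterior ratings
#' (exposure - control). A positive mean delta on /d/ items means the
#' exposure statistics are predicted to improve /d/-goodness — the
#' model-side analog of a behavioral exposure benefit.
#'
#' @param control_obs,exposure_obs `ideal_observer`s; they are expected to
#'   share the /t/ category (warned if not).
#' @param test_tokens Test-token table (must carry `category`).
#' @param block Rating block whose posterior is compared; default
#'   `"d_goodness"`.
#' @param rating_range As in [posterior_ratings()].
#' @return A list with `per_token` (token_id, category, rating_control,
#'   rating_exposure, delta) and `summary` (mean delta per intended
#'   category).
#' @export
exposure_effect_prediction <- function(control_obs, exposure_obs, test_tokens,
                                       block = "d_goodness",
                                       rating_range = c(-1, 1)) {
  t_ctrl <- control_obs$categories$t
  t_exp <- exposure_obs$categories$t
  if (max(abs(t_ctrl$mean - t_exp$mean)) > 1e-9 ||
      max(abs(t_ctrl$cov - t_exp$cov)) > 1e-9) {
    warning("observers do not share the /t/ category", call. = FALSE)
  }
  pr_c <- posterior_ratings(control_obs, test_tokens, block, rating_range)
  pr_e <- posterior_ratings(exposure_obs, test_tokens, block, rating_range)
  per_token <- tibble::tibble(
    token_id = pr_c$token_id,
    category = as.character(test_tokens$category),
    rating_control = pr_c$posterior_rating,
    rating_exposure = pr_e$posterior_rating,
    delta = pr_e$posterior_rating - pr_c$posterior_rating
  )
  summary <- dplyr::summarise(
    dplyr::group_by(per_token, .data$category),
    mean_delta = mean(.data$delta), n = dplyr::n(), .groups = "drop"
  )
  list(per_token = per_token, summary = summary)
}

#' Fold robustness of the exposure-effect prediction
#'
#' Checks that the predicted exposure effect is not carried by particular
#' tokens: tokens are split into k stratified folds (within accent x
#' category x phase), observers are refit on each training set, and the
#' exposure delta is evaluated on that fold's held-out test tokens.
#'
#' @param native_tokens,nonnative_tokens Token tables as in
#'   [build_condition_observer()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the partition.
#' @param block,rating_range As in [exposure_effect_prediction()].
#' @return Tibble with one row per fold: `fold`, `n_test`,
#'   `mean_delta_d` (held-out /d/ items), `mean_delta` (all held-out
#'   items), `sign_d` (sign of `mean_delta_d`).
#' @export
fold_robustness <- function(native_tokens, nonnative_tokens, k, seed,
                            block = "d_goodness", rating_range = c(-1, 1)) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  native_tokens <- tibble::as_tibble(native_tokens)
  nonnative_tokens <- tibble::as_tibble(nonnative_tokens)

  assign_folds <- function(df, strata) {
    fold <- integer(nrow(df))
    for (s in split(seq_len(nrow(df)), strata, drop = TRUE)) {
      fold[s] <- sample(rep_len(seq_len(k), length(s)))
    }
    fold
  }
  with_seed(seed, {
    nat_fold <- assign_folds(native_tokens, native_tokens$category)
    non_fold <- assign_folds(
      nonnative_tokens,
      paste(nonnative_tokens$category, nonnative_tokens$phase)
    )
  })

  rows <- lapply(seq_len(k), function(i) {
    nat_tr <- native_tokens[nat_fold != i, ]
    non_tr <- nonnative_tokens[non_fold != i, ]
    for (cat in c("d", "t")) {
      if (sum(nat_tr$category == cat &
              stats::complete.cases(nat_tr[, CUE_COLS])) < 4) {
        stop("fold ", i, ": fewer than 4 native /", cat,
             "/ training tokens; use fewer folds", call. = FALSE)
      }
    }
    held <- nonnative_tokens[non_fold == i & nonnative_tokens$phase == "test", ]
    if (nrow(held) == 0) {
      return(tibble::tibble(fold = i, n_test = 0L, mean_delta_d = NA_real_,
                            mean_delta = NA_real_, sign_d = NA_real_))
    }
    ctrl <- build_condition_observer("control", nat_tr, non_tr)
    expo <- build_condition_observer("d_exposure", nat_tr, non_tr)
    eff <- exposure_effect_prediction(ctrl, expo, held, block, rating_range)
    d_rows <- eff$per_token[eff$per_token$category == "d", ]
    md <- if (nrow(d_rows) > 0) mean(d_rows$delta) else NA_real_
    tibble::tibble(
      fold = i, n_test = nrow(held),
      mean_delta_d = md,
      mean_delta = mean(eff$per_token$delta),
      sign_d = sign(md)
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize an ideal observer to JSON
#'
#' Means, covariances (row-major), priors and provenance; round-trips with
#' [observer_from_json()].
#'
#' @param observer An `ideal_observer`.
#' @param path Optional output file.
#' @return JSON string (invisibly if written).
#' @export
observer_to_json <- function(observer, path = NULL) {
  stopifnot(inherits(observer, "ideal_observer"))
  payload <- list(
    condition = observer$condition %||% NA,
    priors = as.list(observer$priors),
    categories = lapply(observer$categories, function(g) {
      list(
        label = g$label,
        mean = as.numeric(g$mean),
        cov_row_major = as.numeric(t(g$cov)),
        n_tokens = g$n_tokens,
        regularization_applied = g$regularization_applied
      )
    }),
    provenance = observer$provenance
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize an ideal observer from JSON
#'
#' @param path_or_json File path or JSON string from [observer_to_json()].
#' @return An `ideal_observer`.
#' @export
observer_from_json <- function(path_or_json) {
  payload <- jsonlite::fromJSON(path_or_json, simplifyVector = TRUE)
  cats <- lapply(payload$categories, function(g) {
    structure(
      list(
        label = g$label,
        mean = setNames(as.numeric(g$mean), CUE_COLS),
        cov = matrix(g$cov_row_major, 3, 3, byrow = TRUE,
                     dimnames = list(CUE_COLS, CUE_COLS)),
        n_tokens = as.integer(g$n_tokens),
        regularization_applied = as.numeric(g$regularization_applied)
      ),
      class = "gaussian_category"
    )
  })
  obs <- list(
    categories = cats,
    priors = unlist(payload$priors)[c("d", "t")],
    condition = if (is.null(payload$condition) || is.na(payload$condition)) NULL else payload$condition,
    provenance = payload$provenance
  )
  class(obs) <- "ideal_observer"
  obs
}
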