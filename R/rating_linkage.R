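#' Standardize ratings within participant
#'
#' Likert use differs across participants (scale compression, offset), so
#' ratings are z-scored within each participant before any comparison:
#' z = (raw - participant mean) / participant SD (sample SD). A participant
#' whose ratings are all identical carries no usable variance and gets
#' z = 0 with a warning.
#'
#' @param ratings Validated rating table; every participant needs >= 2
#'   ratings.
#' @return The same table with `z_rating` set.
#' @export
zscore_within_participant <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  counts <- table(ratings$participant_id)
  if (any(counts < 2)) {
    stop("participant(s) with a single rating cannot be standardized: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::group_by(ratings, .data$participant_id)
  out <- dplyr::mutate(
    out,
    .p_sd = stats::sd(.data$raw_rating),
    z_rating = ifelse(
      .data$.p_sd > 0,
      (.data$raw_rating - mean(.data$raw_rating)) / .data$.p_sd,
      0
    )
  )
  out <- dplyr::ungroup(out)
  n_const <- length(unique(out$participant_id[out$.p_sd == 0]))
  if (n_const > 0) {
    warning(n_const, " participant(s) with constant ratings assigned z = 0",
            call. = FALSE)
  }
  out$.p_sd <- NULL
  out
}

#' By-item means of ratings and predictions
#'
#' Aggregates z-scored ratings to item level — one row per
#' (token, condition, block) cell — and attaches the matching posterior
#' rating, the unit at which model and human data are compared.
#'
#' @param ratings z-scored rating table.
#' @param predictions Prediction table carrying `token_id`, `condition`,
#'   `block`, `p_d`, `p_t`, `posterior_rating` (e.g. per-condition
#'   [posterior_ratings()] results bound together with a `condition`
#'   column).
#' @return Tibble: `token_id`, `condition`, `block`, `mean_z_rating`,
#'   `n_participants`, `posterior_rating`, `p_d`, `p_t`.
#' @export
by_item_means <- function(ratings, predictions) {
  ratings <- tibble::as_tibble(ratings)
  predictions <- tibble::as_tibble(predictions)
  if (any(is.na(ratings$z_rating))) {
    stop("ratings must be z-scored first (see zscore_within_participant)",
         call. = FALSE)
  }
  key_r <- unique(paste(ratings$token_id, ratings$condition, ratings$block))
  key_p <- paste(predictions$token_id, predictions$condition, predictions$block)
  missing_keys <- setdiff(key_r, key_p)
  if (length(missing_keys) > 0) {
    stop("rated token(s) without a matching prediction: ",
         paste(head(vapply(strsplit(missing_keys, " "), `[`, "", 1), 10),
               collapse = ", "), call. = FALSE)
  }
  item <- dplyr::summarise(
    dplyr::group_by(ratings, .data$token_id, .data$condition, .data$block),
    mean_z_rating = mean(.data$z_rating),
    n_participants = dplyr::n_distinct(.data$participant_id),
    .groups = "drop"
  )
  dplyr::left_join(
    item,
    dplyr::distinct(
      predictions,
      .data$token_id, .data$condition, .data$block,
      .keep_all = TRUE
    )[, c("token_id", "condition", "block", "posterior_rating", "p_d", "p_t")],
    by = c("token_id", "condition", "block")
  )
}

# Centered +/- 0.5 deviation codes: the coefficient of a coded factor is
# the difference between its two levels, and main effects are evaluated at
# the average of the other factor (the "effects differ between experiments"
# interaction framing).
code_condition <- function(x) ifelse(x == "d_exposure", 0.5, -0.5)
code_experiment <- function(x) ifelse(x == "english", 0.5, -0.5)

new_regression_result <- function(table, n_obs, grouping, mode) {
  structure(
    table,
    n_obs = n_obs, grouping = grouping, mode = mode,
    class = c("regression_result", class(table))
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Regression result (", attr(x, "mode"), " fit; n = ",
      attr(x, "n_obs"), ")\n", sep = "")
  cat("  grouping:", attr(x, "grouping"), "\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# Shared regression backend. `mode`:
#  - "lmer":  by-participant and by-item random intercepts
#             (lmerTest, Satterthwaite df)
#  - "fixed": OLS with cluster-robust (by participant) standard errors
#  - "auto":  lmer, falling back to fixed on error/non-convergence
fit_rating_regression <- function(data, fixed_terms, mode = c("auto", "lmer", "fixed"),
                                  term_labels = NULL) {
  mode <- match.arg(mode)
  rhs <- paste(fixed_terms, collapse = " + ")

  relabel <- function(tab) {
    if (!is.null(term_labels)) {
      idx <- match(tab$term, names(term_labels))
      tab$term[!is.na(idx)] <- unname(term_labels[idx[!is.na(idx)]])
    }
    tab
  }

  fit_lmer <- function() {
    f <- stats::as.formula(paste(
      "z_rating ~", rhs, "+ (1 | participant_id) + (1 | token_id)"
    ))
    fit <- lmerTest::lmer(f, data = data,
                          control = lme4::lmerControl(calc.derivs = FALSE))
    if (length(fit@optinfo$conv$lme4$messages) > 0) {
      stop("lmer convergence warning")
    }
    cf <- summary(fit)$coefficients
    tab <- tibble::tibble(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      se = cf[, "Std. Error"],
      t = cf[, "t value"],
      p = cf[, "Pr(>|t|)"]
    )
    new_regression_result(
      relabel(tab), nrow(data),
      "random intercepts by participant and item (Satterthwaite df)", "lmer"
    )
  }

  fit_fixed <- function() {
    f <- stats::as.formula(paste("z_rating ~", rhs))
    fit <- stats::lm(f, data = data)
    # two-way clustering by participant and by item: the robust analog of
    # the by-participant and by-item random-effects structure
    # (Cameron-Gelbach-Miller). On small balanced designs the two-way
    # estimator can produce non-positive variances; those terms fall back
    # to the larger of the two one-way clustered variances, a conservative
    # always-valid bound.
    v_two <- diag(sandwich::vcovCL(
      fit, cluster = data.frame(p = data$participant_id, i = data$token_id)
    ))
    v_part <- diag(sandwich::vcovCL(fit, cluster = data$participant_id))
    v_item <- diag(sandwich::vcovCL(fit, cluster = data$token_id))
    bad <- !is.finite(v_two) | v_two <= 0
    v_two[bad] <- pmax(v_part, v_item)[bad]
    est <- stats::coef(fit)
    se <- sqrt(v_two)
    tval <- est / se
    df <- min(length(unique(data$participant_id)),
              length(unique(data$token_id))) - 1
    tab <- tibble::tibble(
      term = names(est),
      estimate = unname(est),
      se = unname(se),
      t = unname(tval),
      p = 2 * stats::pt(-abs(unname(tval)), df = df)
    )
    new_regression_result(
      relabel(tab), nrow(data),
      sprintf("OLS with two-way cluster-robust SEs (participant + item clusters, df = %d)", df),
      "fixed"
    )
  }

  switch(mode,
    lmer = fit_lmer(),
    fixed = fit_fixed(),
    auto = tryCatch(suppressWarnings(fit_lmer()), error = function(e) fit_fixed())
  )
}

#' Exposure-effect regression on z-scored ratings
#'
#' Quantifies the behavioral /d/-exposure effect: z-scored ratings are
#' regressed on exposure condition and, when two experiments (languages)
#' are present, on experiment and the condition x experiment interaction —
#' the interaction being the test of whether the exposure effect differs
#' between experiments. Both factors use centered +/- 0.5 deviation codes
#' (d_exposure and english coded +0.5), so the condition coefficient equals
#' the condition difference in z units.
#'
#' @param ratings z-scored rating table. With `align = "category_match"`
#'   (default) the response is the goodness of the item's *intended*
#'   category: z-ratings of trials whose rated block mismatches the item's
#'   category (e.g. /t/-goodness of a /d/-final word) are sign-flipped, so
#'   that an exposure benefit — more category-appropriate ratings — is a
#'   single positive condition effect across both blocks. This requires a
#'   `category` column on the rating table (join it from the token table if
#'   absent). `align = "none"` analyzes raw z-ratings.
#' @param include_category Add the intended category of the rated token as
#'   a covariate (requires a `category` column).
#' @param align Response alignment policy, see above.
#' @param mode Regression backend; see Details in
#'   [model_fit_regression()].
#' @return A `regression_result` (term, estimate, se, t, p) with the
#'   grouping structure recorded.
#' @export
exposure_effect_regression <- function(ratings, include_category = FALSE,
                                       align = c("category_match", "none"),
                                       mode = c("auto", "lmer", "fixed")) {
  mode <- match.arg(mode)
  align <- match.arg(align)
  ratings <- tibble::as_tibble(ratings)
  if (any(is.na(ratings$z_rating))) {
    stop("ratings must be z-scored first", call. = FALSE)
  }
  if (length(unique(ratings$condition)) < 2) {
    stop("both exposure conditions must be present", call. = FALSE)
  }
  dat <- ratings
  if (align == "category_match") {
    if (!"category" %in% names(dat)) {
      stop("align = \"category_match\" requires a category column on the ",
           "rating table (join from the token table)", call. = FALSE)
    }
    match_block <- ifelse(dat$category == "d", "d_goodness", "t_goodness")
    dat$z_rating <- ifelse(dat$block == match_block,
                           dat$z_rating, -dat$z_rating)
  }
  dat$cond_c <- code_condition(dat$condition)
  terms <- "cond_c"
  labels <- c(cond_c = "condition")
  if (length(unique(dat$language)) > 1) {
    dat$exp_c <- code_experiment(dat$language)
    terms <- c("cond_c", "exp_c", "cond_c:exp_c")
    labels <- c(cond_c = "condition", exp_c = "experiment",
                `cond_c:exp_c` = "condition:experiment")
  }
  if (include_category) {
    if (!"category" %in% names(dat)) {
      stop("include_category requires a category column", call. = FALSE)
    }
    dat$cat_c <- ifelse(dat$category == "d", 0.5, -0.5)
    terms <- c(terms, "cat_c")
    labels <- c(labels, cat_c = "category")
  }
  fit_rating_regression(dat, terms, mode, labels)
}

#' Trial-level regression of ratings on the ideal observer's posterior
#'
#' The central model-to-behavior test: does the observer's posterior
#' probability of the rated category predict listeners' z-scored goodness
#' ratings trial by trial? Each trial is joined to the prediction matching
#' its token, block and condition; the predictor is `p_d` for /d/-goodness
#' blocks and `p_t` for /t/-goodness blocks, on the probability scale
#' (an affine rescaling would change only the coefficient's scale, not its
#' significance).
#'
#' @param ratings z-scored rating table.
#' @param predictions Prediction table as in [by_item_means()].
#' @param controls Character subset of
#'   `c("condition", "experiment", "interaction")` to include as covariates.
#' @param mode `"auto"` (default) fits by-participant/by-item random
#'   intercepts via lmerTest, falling back to OLS with participant-cluster
#'   robust SEs if the hierarchical fit fails; `"lmer"` and `"fixed"` force
#'   a backend. The backend used is recorded in the result.
#' @return A `regression_result`; the row of interest is term `posterior`.
#' @export
model_fit_regression <- function(ratings, predictions, controls = character(),
                                 mode = c("auto", "lmer", "fixed")) {
  mode <- match.arg(mode)
  ratings <- tibble::as_tibble(ratings)
  predictions <- tibble::as_tibble(predictions)
  if (any(is.na(ratings$z_rating))) {
    stop("ratings must be z-scored first", call. = FALSE)
  }
  dat <- dplyr::inner_join(
    ratings,
    predictions[, c("token_id", "condition", "block", "p_d", "p_t")],
    by = c("token_id", "condition", "block")
  )
  if (nrow(dat) < nrow(ratings)) {
    stop(nrow(ratings) - nrow(dat),
         " rating trial(s) have no matching prediction", call. = FALSE)
  }
  dat$posterior <- ifelse(dat$block == "d_goodness", dat$p_d, dat$p_t)
  if (stats::var(dat$posterior) == 0) {
    stop("posterior predictor has zero variance", call. = FALSE)
  }
  terms <- "posterior"
  labels <- c(posterior = "posterior")
  if ("condition" %in% controls || "interaction" %in% controls) {
    dat$cond_c <- code_condition(dat$condition)
    terms <- c(terms, "cond_c")
    labels <- c(labels, cond_c = "condition")
  }
  if ("experiment" %in% controls || "interaction" %in% controls) {
    dat$exp_c <- code_experiment(dat$language)
    terms <- c(terms, "exp_c")
    labels <- c(labels, exp_c = "experiment")
  }
  if ("interaction" %in% controls) {
    terms <- c(terms, "cond_c:exp_c")
    labels <- c(labels, `cond_c:exp_c` = "condition:experiment")
  }
  fit_rating_regression(dat, terms, mode, labels)
}

#' Item-level agreement between model and listeners
#'
#' Pearson correlation of by-item mean z-scored ratings with the observer's
#' posterior ratings — a linear-agreement diagnostic justified by the
#' linear link between categorization and goodness observed for stimuli of
#' this kind. Because the posterior-to-rating scaling is affine, this
#' correlation is unchanged by the scaling.
#'
#' @param item_table Output of [by_item_means()].
#' @return List with `pearson_r` and `n_items`.
#' @export
item_level_agreement <- function(item_table) {
  item_table <- tibble::as_tibble(item_table)
  x <- item_table$mean_z_rating
  y <- item_table$posterior_rating
  if (length(x) < 3) stop("need >= 3 items", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant variable; correlation undefined", call. = FALSE)
  }
  list(pearson_r = stats::cor(x, y), n_items = length(x))
}

#' Serialize a regression result to CSV
#'
#' @param result A `regression_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
regression_result_to_csv <- function(result, path) {
  readr::write_csv(tibble::as_tibble(result), path, progress = FALSE)
  invisible(path)
}
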