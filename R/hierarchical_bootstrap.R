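#' Bootstrap configuration
#'
#' @param n_samples Number of bootstrap samples (default 1000).
#' @param seed Integer seed for the dedicated resampling stream.
#' @param target_structure List with `n_participants_per_condition` and
#'   `n_ratings_per_participant`: the size and structure the first
#'   experiment's data are down-sampled to (typically the smaller
#'   experiment's structure, e.g. 60 ratings each from ~11-12 participants
#'   per condition).
#' @param alpha Two-sided significance threshold inside each replicate
#'   (default 0.05).
#' @param mode Regression backend used inside replicates; default
#'   `"fixed"` (OLS + participant-cluster robust SEs), which is stable on
#'   resampled data where hierarchical fits frequently fail to converge.
#' @param align Response alignment passed to
#'   [exposure_effect_regression()].
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_samples = 1000, seed = 1,
                             target_structure = list(
                               n_participants_per_condition = 12,
                               n_ratings_per_participant = 60
                             ),
                             alpha = 0.05,
                             mode = "fixed",
                             align = "category_match") {
  stopifnot(n_samples >= 1,
            target_structure$n_participants_per_condition >= 1,
            target_structure$n_ratings_per_participant >= 1,
            alpha > 0, alpha < 1)
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         target_structure = target_structure, alpha = alpha,
         mode = mode, align = align),
    class = "bootstrap_config"
  )
}

#' Two-stage hierarchical resample of a rating table
#'
#' Respects the grouping structure of the data: first participants are
#' sampled with replacement within each exposure condition, then each
#' sampled participant contributes a with-replacement sample of their own
#' trials. Resampled participants receive fresh unique ids so that a
#' participant drawn twice counts as two distinct grouping units —
#' without relabeling, repeated draws would collapse into one cluster and
#' understate between-participant variance.
#'
#' Consumes the caller's RNG stream (seed at a higher level, e.g. via
#' [run_bootstrap()]).
#'
#' @param ratings Rating table.
#' @param target List with `n_participants_per_condition` and
#'   `n_ratings_per_participant`.
#' @return Resampled rating table with
#'   `n_conditions * n_participants_per_condition * n_ratings_per_participant`
#'   rows.
#' @export
resample_hierarchical <- function(ratings, target) {
  ratings <- tibble::as_tibble(ratings)
  conds <- sort(unique(as.character(ratings$condition)))
  if (length(conds) == 0) stop("empty rating table", call. = FALSE)
  out <- vector("list", 0)
  for (cond in conds) {
    sub <- ratings[ratings$condition == cond, ]
    ids <- unique(sub$participant_id)
    if (length(ids) == 0) stop("empty condition: ", cond, call. = FALSE)
    drawn <- sample(ids, target$n_participants_per_condition, replace = TRUE)
    by_id <- split(seq_len(nrow(sub)), sub$participant_id)
    for (j in seq_along(drawn)) {
      rows <- by_id[[drawn[j]]]
      take <- sample(rows, target$n_ratings_per_participant, replace = TRUE)
      piece <- sub[take, ]
      piece$participant_id <- sprintf("bs_%s_%03d", cond, j)
      out[[length(out) + 1]] <- piece
    }
  }
  dplyr::bind_rows(out)
}

# Observed grouping structure of a rating table, used to resample an
# experiment at its own size.
observed_structure <- function(ratings) {
  per_part <- table(ratings$participant_id)
  per_cond <- tapply(ratings$participant_id, ratings$condition,
                     function(x) length(unique(x)))
  list(
    n_participants_per_condition = as.integer(round(mean(per_cond))),
    n_ratings_per_participant = as.integer(round(stats::median(per_part)))
  )
}

#' Down-sampling hierarchical bootstrap across two experiments
#'
#' Asks whether a difference in exposure effects between two experiments
#' could be explained by their difference in size: per bootstrap sample,
#' the first (larger) experiment is down-sampled to
#' `config$target_structure` (the second experiment's size and structure),
#' the second is resampled at its own structure, and the exposure analysis
#' is refit on the combined resample (condition x experiment interaction)
#' and within each experiment (simple effects of condition). Tallies the
#' proportion of samples in which the interaction stays significant and,
#' per experiment, how often the simple effect goes in the predicted
#' (positive) direction and how often it is significant in either
#' direction.
#'
#' @param ratings_english z-scored rating table of the experiment to be
#'   down-sampled.
#' @param ratings_swedish z-scored rating table of the reference
#'   experiment.
#' @param config A [bootstrap_config()].
#' @return A `bootstrap_summary`: proportions as above, the vector of
#'   interaction t-values (for [tail_probability()]), the count of
#'   replicate fits that failed (excluded from denominators), and the
#'   seed.
#' @export
run_bootstrap <- function(ratings_english, ratings_swedish, config) {
  stopifnot(inherits(config, "bootstrap_config"))
  ratings_english <- tibble::as_tibble(ratings_english)
  ratings_swedish <- tibble::as_tibble(ratings_swedish)
  if (any(is.na(ratings_english$z_rating)) || any(is.na(ratings_swedish$z_rating))) {
    stop("both tables must be z-scored", call. = FALSE)
  }
  sv_structure <- observed_structure(ratings_swedish)

  one_sample <- function() {
    en_b <- resample_hierarchical(ratings_english, config$target_structure)
    sv_b <- resample_hierarchical(ratings_swedish, sv_structure)
    # distinct participant ids across experiments
    en_b$participant_id <- paste0("en_", en_b$participant_id)
    sv_b$participant_id <- paste0("sv_", sv_b$participant_id)
    combined <- dplyr::bind_rows(en_b, sv_b)
    fit_comb <- exposure_effect_regression(combined, align = config$align,
                                           mode = config$mode)
    fit_en <- exposure_effect_regression(en_b, align = config$align,
                                         mode = config$mode)
    fit_sv <- exposure_effect_regression(sv_b, align = config$align,
                                         mode = config$mode)
    row_of <- function(fit, term) {
      i <- match(term, fit$term)
      c(est = fit$estimate[i], t = fit$t[i], p = fit$p[i])
    }
    list(
      interaction = row_of(fit_comb, "condition:experiment"),
      english = row_of(fit_en, "condition"),
      swedish = row_of(fit_sv, "condition")
    )
  }

  results <- with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(b) {
      tryCatch(one_sample(), error = function(e) NULL)
    })
  })
  failed <- sum(vapply(results, is.null, logical(1)))
  ok <- results[!vapply(results, is.null, logical(1))]
  if (length(ok) == 0) stop("all bootstrap replicate fits failed", call. = FALSE)
  n_ok <- length(ok)

  get <- function(slot, field) {
    vapply(ok, function(r) unname(r[[slot]][field]), numeric(1))
  }
  per_experiment <- lapply(c(english = "english", swedish = "swedish"), function(s) {
    est <- get(s, "est"); p <- get(s, "p")
    list(
      prop_predicted_direction = mean(est > 0),
      prop_significant_predicted = mean(p < config$alpha & est > 0),
      prop_significant_opposite = mean(p < config$alpha & est < 0)
    )
  })

  structure(
    list(
      n_samples = n_ok,
      n_failed = failed,
      prop_interaction_significant = mean(get("interaction", "p") < config$alpha),
      per_experiment = per_experiment,
      t_interaction_distribution = get("interaction", "t"),
      alpha = config$alpha,
      seed = config$seed
    ),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Hierarchical bootstrap summary (", x$n_samples, " samples",
      if (x$n_failed > 0) paste0(", ", x$n_failed, " failed fits excluded"),
      ")\n", sep = "")
  cat(sprintf("  interaction significant (alpha = %g): %.1f%%\n",
              x$alpha, 100 * x$prop_interaction_significant))
  for (e in names(x$per_experiment)) {
    pe <- x$per_experiment[[e]]
    cat(sprintf(
      "  %s: predicted direction %.1f%%, significant-predicted %.1f%%, significant-opposite %.1f%%\n",
      e, 100 * pe$prop_predicted_direction,
      100 * pe$prop_significant_predicted,
      100 * pe$prop_significant_opposite
    ))
  }
  invisible(x)
}

#' One-sided tail probability of an observed t-value
#'
#' Proportion of bootstrap t-values as small or smaller than the observed
#' one — e.g. how often resamples of one experiment produce an effect as
#' weak as the one observed in the other experiment.
#'
#' @param t_distribution Non-empty numeric vector of t-values.
#' @param observed_t Observed t-value.
#' @return Proportion in \[0, 1\].
#' @export
tail_probability <- function(t_distribution, observed_t) {
  if (length(t_distribution) == 0) {
    stop("empty t-value vector", call. = FALSE)
  }
  mean(t_distribution <= observed_t)
}

#' Serialize a bootstrap summary to JSON
#'
#' @param summary A `bootstrap_summary`.
#' @param path Optional output file.
#' @param include_t Include the per-sample interaction t-values.
#' @return JSON string (invisibly if written).
#' @export
bootstrap_summary_to_json <- function(summary, path = NULL, include_t = TRUE) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  payload <- unclass(summary)
  if (!include_t) payload$t_interaction_distribution <- NULL
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
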