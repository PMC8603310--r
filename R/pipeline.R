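#' Build a run configuration for the full analysis
#'
#' Exactly one of `preset` or (`tokens_path` + `ratings_path`) must be
#' supplied. The single `seed` is expanded into independent per-stage
#' substreams, so e.g. toggling the bootstrap does not perturb token
#' generation.
#'
#' @param preset Scenario preset name (see [expand_preset()]) for a
#'   synthetic run.
#' @param tokens_path,ratings_path CSV paths for a real-data run.
#' @param second_preset Preset for the comparison experiment used by the
#'   bootstrap stage; defaults to an independent draw of `preset` relabeled
#'   as the other language (a pure size-and-structure comparison).
#' @param preset_overrides Overrides forwarded to [expand_preset()].
#' @param predictors Context predictors for cue correction; `NULL` (default)
#'   auto-detects `context_*` columns.
#' @param priors Category priors, default uniform.
#' @param rating_range_policy `"fixed"` uses `c(-1, 1)`; `"empirical"` uses
#'   the observed range of z-scored by-item mean ratings.
#' @param regression_mode `"auto"`, `"lmer"` or `"fixed"`.
#' @param bootstrap `NULL` to skip, else a [bootstrap_config()].
#' @param out_dir Output directory for report artifacts; `NULL` writes
#'   nothing.
#' @param seed Global integer seed.
#' @return A `run_config`.
#' @export
run_config <- function(preset = NULL, tokens_path = NULL, ratings_path = NULL,
                       second_preset = NULL, preset_overrides = list(),
                       predictors = NULL,
                       priors = c(d = 0.5, t = 0.5),
                       rating_range_policy = c("fixed", "empirical"),
                       regression_mode = c("auto", "lmer", "fixed"),
                       bootstrap = NULL,
                       out_dir = NULL, seed = 1) {
  have_preset <- !is.null(preset)
  have_paths <- !is.null(tokens_path) && !is.null(ratings_path)
  if (have_preset == have_paths) {
    stop("specify exactly one of: preset, or tokens_path + ratings_path",
         call. = FALSE)
  }
  structure(
    list(
      preset = preset, tokens_path = tokens_path, ratings_path = ratings_path,
      second_preset = second_preset, preset_overrides = preset_overrides,
      predictors = predictors, priors = priors,
      rating_range_policy = match.arg(rating_range_policy),
      regression_mode = match.arg(regression_mode),
      bootstrap = bootstrap, out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

write_stage <- function(out_dir, name, writer) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  writer(file.path(out_dir, name))
  invisible(NULL)
}

# One experiment's worth of analysis: tokens -> correction -> observers ->
# predictions (-> synthetic ratings if spec given) -> z-scoring.
analyze_experiment <- function(tokens, ratings, spec, priors, predictors,
                               rating_range, label) {
  log_msg(label, "fitting context model on native tokens")
  native <- tokens[tokens$accent == "native", ]
  preds <- predictors %||% context_columns(tokens)
  cmodel <- fit_context_model(native, preds)
  corrected <- correct_cues(tokens, cmodel, unseen = "zero")

  log_msg(label, "building control and d_exposure observers")
  nat_c <- corrected[corrected$accent == "native", ]
  non_c <- corrected[corrected$accent == "nonnative", ]
  observers <- list(
    control = build_condition_observer("control", nat_c, non_c, priors),
    d_exposure = build_condition_observer("d_exposure", nat_c, non_c, priors)
  )
  test_tokens <- corrected[corrected$phase == "test", ]

  log_msg(label, "computing posterior ratings for ", nrow(test_tokens),
          " test tokens")
  predictions <- dplyr::bind_rows(lapply(
    c("control", "d_exposure"),
    function(cond) dplyr::bind_rows(lapply(
      c("d_goodness", "t_goodness"),
      function(blk) {
        pr <- posterior_ratings(observers[[cond]], test_tokens, blk, rating_range)
        pr$condition <- cond
        pr
      }
    ))
  ))

  if (is.null(ratings)) {
    log_msg(label, "generating synthetic ratings")
    ratings <- generate_rating_experiment(spec, observers, test_tokens,
                                          rating_range)
  }
  ratings <- zscore_within_participant(ratings)

  effect <- exposure_effect_prediction(
    observers$control, observers$d_exposure, test_tokens,
    rating_range = rating_range
  )

  list(
    tokens = tokens, corrected = corrected, context_model = cmodel,
    observers = observers, test_tokens = test_tokens,
    predictions = predictions, ratings = ratings, effect = effect
  )
}

#' Run the full exposure-adaptation analysis
#'
#' Executes the pipeline end to end: load or generate tokens; fit the
#' C-CuRE context model on native tokens and correct all cues; build the
#' control and /d/-exposure ideal observers; compute posterior ratings on
#' the test tokens; load or simulate the rating experiment and z-score it;
#' aggregate to item level and compute model-human agreement and the
#' trial-level regressions; optionally run the cross-experiment
#' hierarchical bootstrap. Stage outputs are written to `config$out_dir`
#' as they are produced, so partial failures leave inspectable
#' intermediates; any stage error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: per-experiment stage objects, regression
#'   results, item-level agreement, exposure-effect summary, optional
#'   bootstrap summary, and the settings in force.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  rating_range <- c(-1, 1)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- load or generate primary experiment ---------------------------------
  primary <- stage("load", {
    if (!is.null(config$preset)) {
      spec <- expand_preset(config$preset, utils::modifyList(
        list(seed = config$seed), config$preset_overrides
      ))
      list(tokens = generate_production_tokens(spec), ratings = NULL,
           spec = spec)
    } else {
      list(tokens = read_tokens(config$tokens_path),
           ratings = read_ratings(config$ratings_path), spec = NULL)
    }
  })
  write_stage(out_dir, "tokens.csv",
              function(p) write_tokens(primary$tokens, p))

  res <- stage("analyze", analyze_experiment(
    primary$tokens, primary$ratings, primary$spec, config$priors,
    config$predictors, rating_range, "primary"
  ))
  write_stage(out_dir, "tokens_corrected.csv",
              function(p) write_tokens(res$corrected, p))
  write_stage(out_dir, "context_model.json",
              function(p) context_model_to_json(res$context_model, p))
  write_stage(out_dir, "observer_control.json",
              function(p) observer_to_json(res$observers$control, p))
  write_stage(out_dir, "observer_d_exposure.json",
              function(p) observer_to_json(res$observers$d_exposure, p))
  write_stage(out_dir, "predictions.csv",
              function(p) readr::write_csv(res$predictions, p, progress = FALSE))
  write_stage(out_dir, "ratings.csv",
              function(p) write_ratings(res$ratings, p))

  # -- rating-linkage stage ------------------------------------------------
  if (config$rating_range_policy == "empirical") {
    item0 <- by_item_means(res$ratings, res$predictions)
    rating_range <- range(item0$mean_z_rating)
    if (diff(rating_range) <= 0) rating_range <- c(-1, 1)
  }
  linkage <- stage("linkage", {
    item <- by_item_means(res$ratings, res$predictions)
    list(
      item_means = item,
      agreement = item_level_agreement(item),
      exposure_regression = exposure_effect_regression(
        res$ratings, mode = config$regression_mode
      ),
      model_fit = model_fit_regression(
        res$ratings, res$predictions, mode = config$regression_mode
      )
    )
  })
  write_stage(out_dir, "item_means.csv",
              function(p) readr::write_csv(linkage$item_means, p, progress = FALSE))
  write_stage(out_dir, "exposure_regression.csv",
              function(p) regression_result_to_csv(linkage$exposure_regression, p))
  write_stage(out_dir, "model_fit_regression.csv",
              function(p) regression_result_to_csv(linkage$model_fit, p))

  # -- optional bootstrap against a second experiment ----------------------
  boot <- NULL
  second <- NULL
  if (!is.null(config$bootstrap)) {
    boot <- stage("bootstrap", {
      if (!is.null(config$preset)) {
        second_name <- config$second_preset %||% config$preset
        other_lang <- if (primary$spec$language == "english") "swedish" else "english"
        spec2 <- expand_preset(second_name, utils::modifyList(
          list(seed = config$seed + 101L), config$preset_overrides
        ))
        if (spec2$language == primary$spec$language) spec2$language <- other_lang
        second <- analyze_experiment(
          generate_production_tokens(spec2), NULL, spec2, config$priors,
          config$predictors, rating_range, "second"
        )
        run_bootstrap(res$ratings, second$ratings, config$bootstrap)
      } else {
        stop("bootstrap on real data requires both experiments' tables; ",
             "call run_bootstrap() directly")
      }
    })
    write_stage(out_dir, "bootstrap.json",
                function(p) bootstrap_summary_to_json(boot, p))
  }

  settings <- list(
    seed = config$seed,
    preset = config$preset,
    coding = "deviation +/-0.5 (d_exposure, english = +0.5)",
    regression_mode = config$regression_mode,
    rating_range = rating_range,
    priors = as.list(config$priors),
    ridge = 0,
    alpha = if (!is.null(config$bootstrap)) config$bootstrap$alpha else 0.05,
    config_hash = digest_config(config)
  )
  report <- structure(
    list(
      primary = res, second = second, linkage = linkage,
      bootstrap = boot, settings = settings
    ),
    class = "run_report"
  )
  write_stage(out_dir, "report.txt", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
  })
  report
}

# Small stable fingerprint of the configuration, stamped into the report.
digest_config <- function(config) {
  s <- jsonlite::toJSON(
    config[setdiff(names(config), "bootstrap")],
    auto_unbox = TRUE, force = TRUE, null = "null"
  )
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %% 1000000L
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Accent-adaptation ideal-observer analysis ==\n")
  cat("settings:\n")
  for (nm in names(x$settings)) {
    v <- x$settings[[nm]]
    cat("  ", nm, ": ", paste(format(unlist(v)), collapse = ", "), "\n", sep = "")
  }
  cat("\nexposure-effect prediction (posterior-rating delta, exposure - control):\n")
  print(x$primary$effect$summary)
  cat("\nitem-level agreement: r =",
      sprintf("%.3f", x$linkage$agreement$pearson_r),
      "over", x$linkage$agreement$n_items, "items\n")
  cat("\nexposure regression (behavioral):\n")
  print(x$linkage$exposure_regression)
  cat("\nmodel-fit regression (z-rating ~ posterior):\n")
  print(x$linkage$model_fit)
  if (!is.null(x$bootstrap)) {
    cat("\n")
    print(x$bootstrap)
  }
  invisible(x)
}
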