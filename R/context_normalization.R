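#' Fit a C-CuRE-style context model
#'
#' Computing Cues Relative to Expectations: each cue (vowel, closure, burst
#' duration) is regressed on categorical context predictors by ordinary
#' least squares, so that a token's cue value can later be re-expressed as
#' its residual from the contextual expectation plus the grand mean. This
#' removes systematic effects of segmental, supra-segmental and talker
#' context from the cue space before category distributions are estimated.
#'
#' Predictors are dummy (treatment) coded with the first level in sorted
#' order as reference. The coding only affects coefficient labels: the
#' fitted values, which are all the correction uses, are identical under any
#' full-rank coding.
#'
#' @param tokens Token table; rows with `NA` burst are excluded from the
#'   burst sub-model (their count is logged).
#' @param predictors Character vector of context predictor columns (e.g.
#'   `"talker_id"`, `"context_vowel"`). Empty gives an intercept-only model,
#'   under which correction is the identity.
#' @return A `context_model`: one OLS sub-model per cue with grand mean,
#'   named coefficients (`"predictor=level"`), and residual SD.
#' @export
fit_context_model <- function(tokens, predictors = character()) {
  tokens <- tibble::as_tibble(tokens)
  bad <- setdiff(predictors, names(tokens))
  if (length(bad) > 0) {
    stop("unknown context predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  level_sets <- lapply(predictors, function(p) sort(unique(as.character(tokens[[p]]))))
  names(level_sets) <- predictors

  fit_one <- function(cue) {
    keep <- !is.na(tokens[[cue]])
    if (cue == "burst_ms" && any(!keep)) {
      log_msg("context", sum(!keep), " token(s) without burst excluded from burst sub-model")
    }
    dat <- tokens[keep, , drop = FALSE]
    y <- dat[[cue]]
    X <- matrix(1, nrow = nrow(dat), ncol = 1, dimnames = list(NULL, "(intercept)"))
    col_pred <- "(intercept)"
    for (p in predictors) {
      lv <- level_sets[[p]]
      for (l in lv[-1]) {
        X <- cbind(X, as.numeric(as.character(dat[[p]]) == l))
        colnames(X)[ncol(X)] <- paste0(p, "=", l)
        col_pred <- c(col_pred, p)
      }
    }
    if (nrow(X) < ncol(X) + 1) {
      stop(sprintf(
        "too few tokens to fit context model for %s: %d token(s), %d parameter(s); no residual degrees of freedom",
        cue, nrow(X), ncol(X)
      ), call. = FALSE)
    }
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
      aliased <- unique(col_pred[match(dropped, colnames(X))])
      stop("rank-deficient context design; aliased predictor(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qr_x, y)
    resid <- y - drop(X %*% beta)
    list(
      grand_mean = mean(y),
      intercept = unname(beta[1]),
      coefficients = if (ncol(X) > 1) beta[-1] else setNames(numeric(0), character(0)),
      residual_sd = sqrt(sum(resid^2) / (nrow(X) - ncol(X))),
      n = nrow(X)
    )
  }

  model <- list(
    cues = setNames(lapply(CUE_COLS, fit_one), CUE_COLS),
    predictors = predictors,
    levels = level_sets,
    fitted_on = list(
      n = nrow(tokens),
      predictors = predictors,
      levels = level_sets
    )
  )
  class(model) <- "context_model"
  model
}

#' @export
print.context_model <- function(x, ...) {
  cat("C-CuRE context model\n")
  cat("  fitted on", x$fitted_on$n, "tokens;",
      length(x$predictors), "predictor(s):",
      paste(x$predictors, collapse = ", "), "\n")
  for (cue in names(x$cues)) {
    m <- x$cues[[cue]]
    cat(sprintf("  %s: grand mean %.1f ms, residual sd %.1f ms, %d contrast(s)\n",
                cue, m$grand_mean, m$residual_sd, length(m$coefficients)))
  }
  invisible(x)
}

# Model-predicted cue value for each row of `tokens` under one cue sub-model.
# Unseen-level policy is enforced by check_unseen_levels() (once per table).
predict_context <- function(model, tokens, cue) {
  m <- model$cues[[cue]]
  pred <- rep(m$intercept, nrow(tokens))
  for (p in model$predictors) {
    keys <- paste0(p, "=", as.character(tokens[[p]]))
    contrib <- m$coefficients[keys]
    contrib[is.na(contrib)] <- 0  # reference or unseen level
    pred <- pred + unname(contrib)
  }
  pred
}

check_unseen_levels <- function(model, tokens, unseen) {
  for (p in model$predictors) {
    new_lv <- setdiff(unique(as.character(tokens[[p]])), model$levels[[p]])
    if (length(new_lv) > 0) {
      if (unseen == "strict") {
        stop(sprintf("unseen level(s) of %s at prediction time: %s",
                     p, paste(new_lv, collapse = ", ")), call. = FALSE)
      }
      warning(sprintf("unseen level(s) of %s treated as zero contribution: %s",
                      p, paste(new_lv, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Correct cue values for context
#'
#' Re-expresses each cue as (observed - contextual expectation) + grand
#' mean, per the C-CuRE scheme: what remains is the part of the cue not
#' explained by context, recentred on the fitting set's mean so corrected
#' values stay on the ms scale. Table length, row order and all non-cue
#' fields are preserved. Missing bursts stay missing.
#'
#' @param tokens Token table to correct.
#' @param model A [fit_context_model()] result.
#' @param unseen Policy for context levels absent from the fitting set:
#'   `"strict"` (default) errors; `"zero"` assigns the level zero
#'   contribution with a warning.
#' @return The token table with corrected `vowel_ms`, `closure_ms`,
#'   `burst_ms`.
#' @export
correct_cues <- function(tokens, model, unseen = c("strict", "zero")) {
  stopifnot(inherits(model, "context_model"))
  unseen <- match.arg(unseen)
  tokens <- tibble::as_tibble(tokens)
  check_unseen_levels(model, tokens, unseen)
  out <- tokens
  for (cue in CUE_COLS) {
    pred <- predict_context(model, tokens, cue)
    out[[cue]] <- tokens[[cue]] - pred + model$cues[[cue]]$grand_mean
  }
  out
}

#' Serialize a context model to JSON
#'
#' @param model A `context_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
context_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "context_model"))
  payload <- list(
    predictors = model$predictors,
    levels = model$levels,
    cues = lapply(model$cues, function(m) {
      list(
        grand_mean = m$grand_mean,
        intercept = m$intercept,
        coefficients = as.list(m$coefficients),
        residual_sd = m$residual_sd,
        n = m$n
      )
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
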