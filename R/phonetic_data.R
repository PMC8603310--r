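#' Canonical column names and factor levels for token and rating tables
#'
#' Token tables describe one recorded word token per row: design labels
#' (talker, language, accent, exposure/test phase, intended category) plus
#' three duration cues in milliseconds — the duration of the vowel preceding
#' the final stop, of the stop closure, and of the burst release. Any column
#' named `context_*` is treated as a categorical context predictor for cue
#' normalization. Rating tables describe one Likert trial per row.
#'
#' @name schema
#' @keywords internal
NULL

TOKEN_REQUIRED <- c(
  "token_id", "word", "minimal_pair_id", "talker_id", "language",
  "accent", "phase", "category", CUE_COLS
)
RATING_REQUIRED <- c(
  "participant_id", "token_id", "block", "condition", "language", "raw_rating"
)

LEVELS <- list(
  language = c("english", "swedish"),
  accent = c("native", "nonnative"),
  phase = c("exposure", "test"),
  category = c("d", "t"),
  block = c("d_goodness", "t_goodness"),
  condition = c("control", "d_exposure")
)

check_levels <- function(x, field) {
  bad <- setdiff(unique(as.character(x)), LEVELS[[field]])
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s value(s): %s (allowed: %s)",
      field, paste(bad, collapse = ", "), paste(LEVELS[[field]], collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' Validate a token table
#'
#' Checks the invariants of the token schema: required columns present,
#' durations numeric, finite and non-negative, `token_id` unique, enum
#' columns restricted to their level sets, and test-phase tokens carrying a
#' non-empty `minimal_pair_id` whose two members bear distinct words and the
#' categories d and t. A missing burst (`NA` in `burst_ms`) is allowed as an
#' explicit sentinel for unreleased stops; such tokens are excluded from
#' Gaussian fitting downstream.
#'
#' @param tokens A data frame of phonetic tokens (canonical columns).
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_tokens <- function(tokens) {
  tokens <- tibble::as_tibble(tokens)
  missing_cols <- setdiff(TOKEN_REQUIRED, names(tokens))
  if (length(missing_cols) > 0) {
    stop("token table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cue in CUE_COLS) {
    v <- tokens[[cue]]
    if (!is.numeric(v)) {
      stop(sprintf("column %s is not numeric", cue), call. = FALSE)
    }
    # NA burst = unreleased stop sentinel; NA is not allowed in other cues
    bad_na <- which(is.na(v))
    if (cue != "burst_ms" && length(bad_na) > 0) {
      stop(sprintf("row %d: missing or non-numeric %s", bad_na[1], cue),
           call. = FALSE)
    }
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad) > 0) {
      stop(sprintf("row %d: invalid %s = %s (durations must be finite and >= 0)",
                   bad[1], cue, format(v[bad[1]])), call. = FALSE)
    }
  }
  dup <- tokens$token_id[duplicated(tokens$token_id)]
  if (length(dup) > 0) {
    stop("duplicate token_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (f in c("language", "accent", "phase", "category")) check_levels(tokens[[f]], f)

  test_tok <- tokens[tokens$phase == "test", ]
  if (nrow(test_tok) > 0) {
    empty_mp <- which(is.na(test_tok$minimal_pair_id) | test_tok$minimal_pair_id == "")
    if (length(empty_mp) > 0) {
      stop("test-phase token without minimal_pair_id (e.g. token_id ",
           test_tok$token_id[empty_mp[1]], ")", call. = FALSE)
    }
    by_pair <- split(test_tok, test_tok$minimal_pair_id)
    for (pair in by_pair) {
      if (length(unique(pair$word)) < nrow(pair) ||
          !setequal(unique(pair$category), c("d", "t"))) {
        stop("minimal pair ", pair$minimal_pair_id[1],
             " must contain distinct words with categories {d, t}", call. = FALSE)
      }
    }
  }
  invisible(tokens)
}

#' Validate a rating table
#'
#' @param ratings A data frame of rating trials (canonical columns).
#' @return The validated tibble (invisibly). Duplicated
#'   (participant, token, block) rows are kept but flagged with a warning,
#'   since deduplication policy is analysis-dependent.
#' @export
validate_ratings <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  missing_cols <- setdiff(RATING_REQUIRED, names(ratings))
  if (length(missing_cols) > 0) {
    stop("rating table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  r <- ratings$raw_rating
  bad <- which(is.na(r) | r != as.integer(r) | r < 1 | r > 7)
  if (length(bad) > 0) {
    stop(sprintf("row %d: raw_rating = %s outside the 7-point scale {1..7}",
                 bad[1], format(ratings$raw_rating[bad[1]])), call. = FALSE)
  }
  for (f in c("block", "condition", "language")) check_levels(ratings[[f]], f)
  key <- paste(ratings$participant_id, ratings$token_id, ratings$block, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicated (participant_id, token_id, block) row(s) kept",
            call. = FALSE)
  }
  if (!"z_rating" %in% names(ratings)) ratings$z_rating <- NA_real_
  invisible(ratings)
}

#' Read a production-token table from CSV
#'
#' Reads a UTF-8, comma-delimited token file and validates every row. The
#' optional `dialect` argument maps foreign column names onto the canonical
#' schema so exported tables from other tooling load without editing.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named character vector mapping canonical name -> column
#'   name in the file, e.g. `c(vowel_ms = "vdur")`. Unmapped columns are used
#'   as-is.
#' @return A tibble of validated tokens, row order preserved.
#' @export
read_tokens <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(df)) {
        stop("dialect column not in file: ", dialect[[canon]], call. = FALSE)
      }
      names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(TOKEN_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop("token file missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble::as_tibble(df))
  }
  df$token_id <- as.character(df$token_id)
  df$minimal_pair_id <- as.character(df$minimal_pair_id %||% "")
  df$minimal_pair_id[is.na(df$minimal_pair_id)] <- ""
  validate_tokens(df)
  tibble::as_tibble(df)
}

#' Write a token table to CSV
#'
#' @param tokens Validated token table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(tokens, path) {
  readr::write_csv(tibble::as_tibble(tokens), path, progress = FALSE)
  invisible(path)
}

#' Read a rating table from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble of validated rating records; `z_rating` is unset (NA)
#'   until [zscore_within_participant()] is applied.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(RATING_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop("rating file missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    df$z_rating <- numeric(0)
    return(tibble::as_tibble(df))
  }
  df$participant_id <- as.character(df$participant_id)
  df$token_id <- as.character(df$token_id)
  validate_ratings(df)
  df$z_rating <- NA_real_
  tibble::as_tibble(df)
}

#' Write a rating table to CSV
#'
#' @param ratings Rating table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  readr::write_csv(tibble::as_tibble(ratings), path, progress = FALSE)
  invisible(path)
}

#' Descriptive cue summaries by group
#'
#' Per-group token count and per-cue mean and sample standard deviation,
#' in the spirit of the descriptive production comparisons that motivate the
#' modeling (native vs. non-native cue distributions).
#'
#' @param tokens Token table.
#' @param group_by Character vector of grouping columns; empty for global
#'   statistics.
#' @return A tibble with one row per observed group: `n`, then
#'   `<cue>_mean` and `<cue>_sd` for each cue. Counts sum to `nrow(tokens)`.
#' @export
summarize_tokens <- function(tokens, group_by = character()) {
  tokens <- tibble::as_tibble(tokens)
  if (nrow(tokens) == 0) {
    return(tibble::tibble(n = integer(0)))
  }
  bad <- setdiff(group_by, names(tokens))
  if (length(bad) > 0) {
    stop("unknown grouping column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grouped <- if (length(group_by) > 0) {
    dplyr::group_by(tokens, dplyr::across(dplyr::all_of(group_by)))
  } else {
    tokens
  }
  dplyr::summarise(
    grouped,
    n = dplyr::n(),
    dplyr::across(
      dplyr::all_of(CUE_COLS),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~stats::sd(.x, na.rm = TRUE)),
      .names = "{.col}_{.fn}"
    ),
    .groups = "drop"
  )
}

# Context predictor columns follow the context_* naming convention.
context_columns <- function(tokens) {
  grep("^context_", names(tokens), value = TRUE)
}
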