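#' @importFrom rlang .data
#' @importFrom stats coef cor lm model.matrix pnorm predict pt qt rnorm sd setNames var vcov
#' @importFrom utils head
NULL

# Cue dimension order is fixed pipeline-wide.
CUE_COLS <- c("vowel_ms", "closure_ms", "burst_ms")

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so seeded stages form independent streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-stage substream seed from a global seed, keeping the result
# inside 32-bit integer range. Stage names map to fixed small offsets so
# toggling one stage never perturbs another.
derive_seed <- function(seed, stage) {
  offsets <- c(
    tokens = 11L, ratings = 23L, bootstrap = 37L, folds = 41L,
    oracle = 53L, simulation = 67L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + off
}

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
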