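#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so that library internals never perturb
#' user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from one root seed.  Offsets keep the
# stages' streams distinct while staying inside R's 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, impute = 23L, screen = 37L, validate = 51L,
    survival = 67L, gsea = 83L, folds = 101L, tumors = 131L, auc = 157L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

ss_log <- function(fmt, ...) {
  message(sprintf(paste0("[socscreen] ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
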