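#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream. All randomness in the package funnels
#' through this helper.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Structured logging to stderr; results go to files/stdout only.
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write the effective configuration + version stamp next to run outputs.
write_run_snapshot <- function(dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snap <- list(
    tool = "m6amnet",
    version = .m6amnet_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(snap, file.path(dir, "run-config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(snap)
}
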