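`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so package functions never clobber global random-number state. A
#' `NULL` seed evaluates the code against the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483629)
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_f <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
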