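#' @keywords internal
"_PACKAGE"

# Logging -----------------------------------------------------------------

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L)

pl_log <- function(level, ...) {
  threshold <- getOption("platimg.log_level", "INFO")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Deterministic RNG scoping ------------------------------------------------

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package internals never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed.  Keeps values well
# inside 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

# Rounding and formatting --------------------------------------------------

#' Round half away from zero
#'
#' Commercial rounding used when reporting metrics as whole percentages
#' (0.865 -> 87%), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(86.5) # 87
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a proportion as a whole percentage
#'
#' @param x Proportion in `[0, 1]`.
#' @return Integer percentage, rounded half away from zero.
#' @export
percent_round <- function(x) {
  round_half_up(100 * x)
}

# Misc ---------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
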