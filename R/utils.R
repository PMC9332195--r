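#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation so that one user-facing seed drives every
# stage (trajectories, spectra, CV folds, splits) without correlated streams.
# Kept strictly below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 48271 + index * 16807 + 12345) %% 2147483647L)
}

assert_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < min || (!allow_zero && x == min)) {
    stop(sprintf("'%s' must be %s %s", name,
                 if (allow_zero) ">=" else ">", format(min)), call. = FALSE)
  }
  invisible(x)
}

# sample standard deviation (n - 1), the convention used throughout
sd1 <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
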