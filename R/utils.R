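#' @keywords internal
"_PACKAGE"

# Round half away from zero at `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible child seed from a parent seed and a string tag.
# Stays below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) %% 97 + 1))
  as.integer((as.double(seed) * 69069 + h * 2654435761) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state. All of
#' the package's randomness flows through this (no hidden global state).
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Percentile with linear interpolation between order statistics (type 7),
# pinned explicitly so null percentiles are deterministic and documented.
percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
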