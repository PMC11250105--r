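#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation: one user seed fans out to independent
# per-stage seeds so stages can be re-run in isolation. Kept below 2^31 - 1.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single probability in [0, 1]")
  invisible(x)
}

assert_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stop_config(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

assert_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Truncated normal draw via inverse CDF (deterministic given the RNG state).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# Log-normal with unit mean and given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
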