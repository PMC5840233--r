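#' @importFrom stats rnorm runif rbinom median sd quantile
#' @importFrom utils write.csv read.csv head tail
#' @importFrom Matrix nnzero
NULL

# Argument checking helpers -------------------------------------------------

stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("dar_argument_error", "error")))
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_arg("`", name, "` must be a single finite number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_arg("`", name, "` = ", x, " is outside the allowed range ",
             if (strict_lower) "(" else "[", lower, ", ", upper,
             if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop_arg("`", name, "` must be an integer >= ", min)
  }
  as.integer(x)
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    stop_arg("`", name, "` must contain only 0/1 values")
  }
  invisible(x)
}

# Seed handling: all stochastic constructors take an explicit `seed` and leave
# the caller's RNG stream untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Deterministic fan-out of one master seed into per-stage seeds.  Stage k gets
# master * 31 + k reduced into 32-bit integer range, so independent stages
# never share a stream yet are reproducible from the master alone.
derive_seed <- function(master, stage) {
  as.integer((as.double(master) * 31 + stage) %% 2147483647)
}
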