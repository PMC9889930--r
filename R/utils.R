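# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Validate a single positive integer-ish scalar.
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  as.numeric(x)
}

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (length(x) < min_len) {
    stop(sprintf("`%s` must have at least %d elements (got %d)", name, min_len, length(x)),
         call. = FALSE)
  }
  if (anyNA(x) || !all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  as.numeric(x)
}

# Deterministic child seed below 2^31, mixed from a base seed and stream ids.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1103515245 + v * 12345 + 7) %% 2147483629
  as.integer(h)
}

# Least-squares slope of y on x (natural scale); used for log-log fits.
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}
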