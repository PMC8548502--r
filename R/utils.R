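#' @keywords internal
"_PACKAGE"

## internal validation helpers ------------------------------------------------

stop_config <- function(...) {
  stop(structure(class = c("plastisel_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("plastisel_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ..., config = FALSE) {
  if (!isTRUE(ok)) {
    if (config) stop_config(...) else stop_validation(...)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Tiny FNV-1a string hash used for provenance stamps (not cryptographic).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); keep h as a double in
    ## [0, 2^32) to stay clear of R's 32-bit integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply by FNV prime 16777619 modulo 2^32 without integer overflow
    h <- (h * 403) %% 4294967296
    h <- (h * 41623) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Truncated normal draw via inverse-CDF; used for CT_MAX generation.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = centre - half, upper = centre + half)
}
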