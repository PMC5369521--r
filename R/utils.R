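# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a per-gel RNG seed from the run seed; kept below 2^31.
.gel_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(index)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Trapezoidal area between two curves sampled at common (sorted) abscissae.
.abs_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  o <- order(x)
  pracma::trapz(x[o], abs(y)[o])
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
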