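#' @keywords internal
"_PACKAGE"

## unit convention: all internal coordinates are nm, all times are s.
## conversions to/from pixels and um happen only at I/O boundaries.
.NM_PER_UM <- 1000
.NM2_PER_UM2 <- 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf,
                              strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
          if (strict_min) "(" else "[", min, max, if (strict_max) ")" else "]")
  invisible(x)
}

## deterministic per-stage child seed from a single root seed; keeps results
## reproducible when a stage is re-run in isolation.  Stays below 2^31 - 1.
child_seed <- function(root_seed, stage_index) {
  root <- as.numeric(root_seed) %% 2147483647
  as.integer((root * 48271 + 7919 * as.numeric(stage_index)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
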