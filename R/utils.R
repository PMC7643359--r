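# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# derive a stage-specific seed from a master seed; stays below 2^31
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + offset) %% .Machine$integer.max)
}

# standardize columns, returning centers/scales for later reuse
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  if (any(sdv <= 0)) {
    stopf("degenerate column(s) with zero variance: %s",
          paste(colnames(x)[sdv <= 0], collapse = ", "))
  }
  list(x = sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/"), center = mu, scale = sdv)
}
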