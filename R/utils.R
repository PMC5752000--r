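# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a stage label, kept below
# 2^31 so it is always a valid R integer seed.  Every stochastic operation in
# the package draws from a stream derived this way, so a single master seed
# reproduces the whole pipeline.
derive_seed <- function(seed, label, replicate = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131 + as.numeric(replicate)) %%
    2147483629)
}

# with a local RNG state so callers' streams are not disturbed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# shoelace area of a closed ring given x/y vectors (absolute value)
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
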