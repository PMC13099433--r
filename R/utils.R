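# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure functions of
# their arguments.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("rng_seed must be a single finite number", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(abs(seed) %% 2147483646L))
  expr
}

# Deterministic substream seed derived from a master seed and a counter;
# stays inside 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((abs(as.numeric(master)) * 48271 + as.numeric(k) * 7919) %%
               2147483629)
}

# Linear-interpolation percentile (type 7), the convention used everywhere
# a percentile appears in this package.
pctile <- function(x, p) {
  stats::quantile(x, p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
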