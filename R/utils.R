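# Internal helpers: argument checking and small numeric utilities.

stop_config <- function(msg) abort(msg, class = "rbptraits_config_error")

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_config(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_config(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stop_config(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

# Geometric mean that returns NA when any element is zero (median-of-ratios
# convention: such genes are excluded from the reference).
geomean_nonzero <- function(x) {
  if (any(x == 0)) return(NA_real_)
  exp(mean(log(x)))
}

# Run an expression under a local RNG state seeded from `seed`, restoring the
# caller's RNG afterwards, so generators are deterministic without clobbering
# the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible child seed from a base seed and a stream label.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1103L + as.integer(h %% 99991L)) %% 2147483563L
}
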