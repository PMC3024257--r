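# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library functions never perturb user sessions.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Permutation p-value with the +1 convention (never exactly zero).
perm_pvalue <- function(n_extreme, n_perm) (1 + n_extreme) / (n_perm + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_coexmod <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop_coexmod(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
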