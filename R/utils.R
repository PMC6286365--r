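# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

# Lognormal deviates with exact mean `m` and coefficient of variation `cv`.
# cv = 0 returns `m` unchanged so noise-free runs are bitwise deterministic.
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  m * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Derive a stream-specific seed from a user seed. Kept well below 2^31.
derive_seed <- function(seed, offset) {
  ((as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)) %% 2147483L + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_bad("`%s` must be a single non-missing number", name)
  }
  if (strict_lower && x <= lower) {
    stop_bad("`%s` must be > %g (got %g)", name, lower, x)
  }
  if (x < lower || x > upper) {
    stop_bad("`%s` must be in [%g, %g] (got %g)", name, lower, upper, x)
  }
  invisible(x)
}
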