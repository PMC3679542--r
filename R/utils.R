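# Internal numeric / RNG helpers shared across modules.

# Run `code` under a local RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All simulator randomness flows through this so that
# identical config + seed give bit-identical output regardless of the caller's
# RNG state, and each entity (train, bead, trap run) can own a sub-stream.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a child seed from a parent seed and an entity index; keeps sub-streams
# decoupled under entity reordering while staying inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1299721) %% 2147483647)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g.", name, min))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %g.", name, min))
  }
  if (x > max) {
    abort(sprintf("`%s` must be <= %g.", name, max))
  }
  invisible(x)
}

# 1D Tukey (tapered cosine) window of length n with taper fraction alpha.
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

# Signed FFT frequencies (cycles per unit), matching stats::fft ordering.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}
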