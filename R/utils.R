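# internal helpers shared across modules

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normal truncated to [lo, hi] by rejection; degenerate sd = 0 returns the
# mean clamped into the interval.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# 4PL in inhibition orientation: y = bottom + (top - bottom)/(1 + (x/ic50)^hill)
four_pl <- function(x, top, bottom, ic50, hill) {
  y <- rep(top, length(x))
  pos <- x > 0
  y[pos] <- bottom + (top - bottom) / (1 + (x[pos] / ic50)^hill)
  y
}
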