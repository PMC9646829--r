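# Seed-scoped evaluation: runs code under a fixed RNG seed and restores the
# caller's RNG state afterwards, so seeded generators do not perturb the
# session stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncated-at-zero normal draw by rejection; means here are far from 0 so
# rejection is cheap.
rtruncnorm0 <- function(n, mean, sd) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= 0
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}
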