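# Shared fixtures, generated in code (no stored data). Computed once per
# test run.

fix_phantom_64 <- generate_phantom(phantom_spec(64, 64, 5, seed = 2))
fix_phantom_320 <- generate_phantom(phantom_spec(320, 320, 6, seed = 3))

# Brute-force double-loop valid cross-correlation (independent oracle).
loop_xcorr_valid <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  Ho <- nrow(x) - kh + 1; Wo <- ncol(x) - kw + 1
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw))
      acc <- acc + x[i + a - 1, j + b - 1] * k[a, b]
    out[i, j] <- acc
  }
  out
}

# Brute-force MSE (independent of mse_metric's vectorized path).
loop_mse <- function(x, y) {
  acc <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    acc <- acc + (x[i, j] - y[i, j])^2
  acc / (nrow(x) * ncol(x))
}

random_residuals <- function(d, seed = 1) {
  set.seed(seed)
  lapply(1:4, function(i) matrix(rnorm(prod(d)), d[1], d[2]))
}
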