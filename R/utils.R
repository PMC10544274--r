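# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from a parent seed, kept within 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

# round() in R rounds half to even; band/line counts use half-away-from-zero.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("'%s' must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stopf("'%s' contains non-finite values", name)
  invisible(x)
}

check_same_shape <- function(x, y, nx = "x", ny = "y") {
  if (!identical(dim(x), dim(y)))
    stopf("'%s' (%s) and '%s' (%s) must have the same shape",
          nx, paste(dim(x), collapse = "x"), ny, paste(dim(y), collapse = "x"))
  invisible(NULL)
}

# Separable Gaussian smoothing with edge replication, output same size.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  pad_rows <- function(m, r) rbind(m[rep(1L, r), , drop = FALSE], m,
                                   m[rep(nrow(m), r), , drop = FALSE])
  xp <- pad_rows(x, r)
  xp <- t(pad_rows(t(xp), r))
  k2 <- outer(g, g)
  cpp_xcorr2_valid(xp, k2)
}
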