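#' Mean squared error
#'
#' @param x,y Equal-shaped numeric matrices.
#' @return Mean squared per-pixel difference (symmetric in its arguments).
#' @export
mse_metric <- function(x, y) {
  check_same_shape(x, y, "x", "y")
  mean((x - y)^2)
}

# 2-D Gaussian window, normalized to sum 1.
gaussian_window <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# Same-size filtering with reflected borders (used by the VIF pyramid so
# that the four-scale decomposition is defined down to 32-pixel images).
filter_same_reflect <- function(x, w) {
  rh <- (nrow(w) - 1L) %/% 2L
  rw <- (ncol(w) - 1L) %/% 2L
  ri <- c(rev(seq_len(rh) + 1L), seq_len(nrow(x)),
          nrow(x) - seq_len(rh))
  ci <- c(rev(seq_len(rw) + 1L), seq_len(ncol(x)),
          ncol(x) - seq_len(rw))
  cpp_xcorr2_valid(x[ri, ci, drop = FALSE], w)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11-pixel Gaussian window (`sigma = 1.5`),
#' stabilizing constants `K1 = 0.01`, `K2 = 0.03`, and population (window)
#' statistics; local maps are evaluated on the valid region only (no
#' padding). The data range defaults to `max - min` of the reference `x`.
#' SSIM is symmetric in `x` and `y` once `data_range` is fixed.
#'
#' @param x Reference image.
#' @param y Test image of the same shape.
#' @param data_range Intensity range; defaults to `diff(range(x))`.
#' @param window_size,sigma Gaussian window parameters.
#' @return Scalar in `[-1, 1]` (1 iff `y == x`).
#' @export
ssim_metric <- function(x, y, data_range = NULL, window_size = 11L,
                        sigma = 1.5) {
  check_same_shape(x, y, "x", "y")
  if (any(dim(x) < window_size))
    stopf("image (%s) is smaller than the SSIM window (%d)",
          paste(dim(x), collapse = "x"), window_size)
  if (is.null(data_range)) data_range <- diff(range(x))
  if (data_range <= 0) data_range <- 1
  w <- gaussian_window(window_size, sigma)
  mu_x <- cpp_xcorr2_valid(x, w)
  mu_y <- cpp_xcorr2_valid(y, w)
  sxx <- cpp_xcorr2_valid(x * x, w) - mu_x^2
  syy <- cpp_xcorr2_valid(y * y, w) - mu_y^2
  sxy <- cpp_xcorr2_valid(x * y, w) - mu_x * mu_y
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
       ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}

#' Pixel-domain Visual Information Fidelity (VIF)
#'
#' Information-fidelity quality metric computed in the pixel domain over
#' four dyadic scales. At each scale both images are Gaussian-filtered
#' (window `2^(4-s+1)+1`, sd `window/5`, reflected borders, same-size
#' output) and downsampled by two (scales
#' 2..4); local means/variances/covariances over the same window feed the
#' per-pixel gain `g = sigma_xy / sigma_x^2` and residual variance
#' `sv2 = sigma_y^2 - g * sigma_xy`, and the metric is the ratio of summed
#' `log(1 + g^2 sigma_x^2 / (sv2 + sigma_nsq))` to summed
#' `log(1 + sigma_x^2 / sigma_nsq)` terms. The argument order is fixed:
#' `x` is the reference. Values can exceed 1 when the test image carries
#' more reference-consistent information (e.g. contrast enhancement).
#'
#' @param x Reference image (at least 32 pixels per side).
#' @param y Test image of the same shape.
#' @param sigma_nsq Visual-noise variance constant (default 2.0).
#' @return Non-negative scalar; 1 when `y == x`.
#' @export
vif_metric <- function(x, y, sigma_nsq = 2.0) {
  check_same_shape(x, y, "x", "y")
  if (any(dim(x) < 32))
    stopf("VIF needs images of at least 32 pixels per side (got %s)",
          paste(dim(x), collapse = "x"))
  eps <- 1e-10
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    w <- gaussian_window(N, N / 5)
    if (scale > 1) {
      x <- filter_same_reflect(x, w)
      y <- filter_same_reflect(y, w)
      x <- x[seq(1, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]
      y <- y[seq(1, nrow(y), 2), seq(1, ncol(y), 2), drop = FALSE]
    }
    mu_x <- filter_same_reflect(x, w); mu_y <- filter_same_reflect(y, w)
    sxx <- pmax(filter_same_reflect(x * x, w) - mu_x^2, 0)
    syy <- pmax(filter_same_reflect(y * y, w) - mu_y^2, 0)
    sxy <- filter_same_reflect(x * y, w) - mu_x * mu_y
    g <- sxy / (sxx + eps)
    sv2 <- syy - g * sxy
    g[sxx < eps] <- 0
    sv2[sxx < eps] <- syy[sxx < eps]
    sv2[sv2 < eps] <- eps
    g[g < 0] <- 0
    num <- num + sum(log10(1 + g^2 * sxx / (sv2 + sigma_nsq)))
    den <- den + sum(log10(1 + sxx / sigma_nsq))
  }
  num / den
}

#' Per-pair quality report
#'
#' Bundles the three evaluation metrics for one reference/test image pair.
#'
#' @param x Reference image.
#' @param y Test image.
#' @param data_range Optional SSIM data range (defaults to the reference's).
#' @return A one-row data frame with columns `mse`, `ssim`, `vif`.
#' @export
metric_report <- function(x, y, data_range = NULL) {
  data.frame(mse = mse_metric(x, y),
             ssim = ssim_metric(x, y, data_range = data_range),
             vif = vif_metric(x, y))
}
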