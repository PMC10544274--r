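#' Artefact parameter specifications
#'
#' Constructors for the parameter sets of the four corruption simulators.
#' Each validates the physically meaningful ranges used throughout the
#' package:
#'
#' * `bias_field_spec()`: multiplicative bias field drawn from a Gaussian
#'   spatial random field with covariance `exp(-(pi/4) * (r/l)^2)` on a
#'   low-resolution grid; `strength` is the fractional intensity variation
#'   in `[0.10, 1.00]`, the length scale `l` lies in `(10, 50)` grid units.
#'   Three normalization conventions are available: the default
#'   `"reciprocal"` maps a strength `s` to `[1 - s/2, 1/(1 - s/2)]`, the
#'   only convention that reproduces both conventional anchor ranges
#'   (10 % -> `[0.95, 1.05]`, 100 % -> `[0.5, 2]`); `"half-span"` maps `s`
#'   to `[1 - s/2, 1 + s/2]`; `"symmetric"` maps `s` to `[1 - s, 1 + s]`
#'   (the convention under which 5/10/20 % fields mean `[0.95, 1.05]`,
#'   `[0.9, 1.1]`, `[0.8, 1.2]` in correction experiments).
#' * `mask_spec()`: Cartesian k-space line-selection masks. Acceleration
#'   must be 2, 3, 4, or 8, with a fully sampled center band of 16, 12, 8,
#'   or 4 % of the lines respectively; `kind` selects fastMRI-style
#'   equidistant or random sampling of the remaining budget, or a
#'   `"centered"` mask keeping only the band.
#' * `rigid_motion_spec()`: piecewise-constant rigid motion; a fraction
#'   `corrupt_fraction` in `[0.30, 0.80]` of the PE lines is replaced, split
#'   into 4--24 contiguous segments whose rotation/translation parameters
#'   are zero-mean Gaussian with standard deviations 12 degrees and 30
#'   voxels (per axis).
#' * `periodic_motion_spec()`: respiratory phase error
#'   `phi(ky) = ky * Delta * sin(alpha*ky + beta)` applied for
#'   `|ky| > ky0`, with `Delta` in `[20, 120]` pixels, `alpha` in
#'   `[0.1, 5]`, `beta` in `[0, pi/4]`, and the protected center half-width
#'   `ky0` in `(pi/10, pi/8]`.
#' * `noise_spec()`: complex Gaussian k-space noise at a target
#'   `SNR = 20*log10(S/N)` dB, `snr_db` in `[-12, 10]`, where `S` is the
#'   mean absolute k-space value and `N` the noise standard deviation.
#'
#' @param strength Fractional intensity variation in `[0.10, 1.00]`.
#' @param length_scale Gaussian-covariance length scale, in low-res grid
#'   units, strictly inside `(10, 50)`.
#' @param variance Covariance amplitude (default 50; the min--max
#'   normalization makes the field range independent of it).
#' @param lowres_size Side of the low-resolution synthesis grid (>= 8).
#' @param range_convention `"reciprocal"`, `"half-span"`, or `"symmetric"`
#'   (see above).
#' @param kind One of `"equidistant"`, `"random"`, `"centered"`.
#' @param accel Acceleration factor: 2, 3, 4, or 8.
#' @param n_lines Total number of phase-encoding lines.
#' @param pe_axis Phase-encoding axis, `1` (rows) or `2` (columns).
#' @param corrupt_fraction Fraction of PE lines to corrupt, `[0.30, 0.80]`.
#' @param n_segments Number of contiguous corrupted segments, 4--24.
#' @param rot_std,trans_std Rigid-motion standard deviations (degrees,
#'   voxels per axis).
#' @param protect_center_frac Optional fraction of center lines excluded
#'   from corruption (evaluation-time setting; default 0).
#' @param delta Motion extent in pixels, `[20, 120]`.
#' @param alpha Respiratory period parameter, `[0.1, 5]`.
#' @param beta Respiratory phase in radians, `[0, pi/4]`.
#' @param ky0 Protected center half-width in radians, `(pi/10, pi/8]`.
#' @param snr_db Target signal-to-noise ratio in decibels, `[-12, 10]`.
#' @param seed Integer seed for the simulator's random draws.
#' @return A spec object of the corresponding class.
#' @name artefact-specs
NULL

#' @rdname artefact-specs
#' @export
bias_field_spec <- function(strength, length_scale, variance = 50,
                            lowres_size = 32L,
                            range_convention = c("reciprocal", "half-span",
                                                 "symmetric"),
                            seed = 1L) {
  if (strength < 0.10 || strength > 1.00)
    stopf("'strength' must lie in [0.10, 1.00] (got %g)", strength)
  if (length_scale <= 10 || length_scale >= 50)
    stopf("'length_scale' must lie strictly inside (10, 50) (got %g)", length_scale)
  if (lowres_size < 8) stopf("'lowres_size' must be >= 8")
  range_convention <- match.arg(range_convention)
  structure(list(strength = strength, length_scale = length_scale,
                 variance = variance, lowres_size = as.integer(lowres_size),
                 range_convention = range_convention, seed = as.integer(seed)),
            class = "bias_field_spec")
}

#' @rdname artefact-specs
#' @export
mask_spec <- function(kind = c("equidistant", "random", "centered"),
                      accel, n_lines, pe_axis = 2L, seed = 1L) {
  kind <- match.arg(kind)
  if (!accel %in% c(2, 3, 4, 8))
    stopf("'accel' must be one of 2, 3, 4, 8 (got %s)", toString(accel))
  if (n_lines < 4) stopf("'n_lines' must be >= 4")
  if (!pe_axis %in% c(1L, 2L)) stopf("'pe_axis' must be 1 or 2")
  structure(list(kind = kind, accel = as.integer(accel),
                 n_lines = as.integer(n_lines), pe_axis = as.integer(pe_axis),
                 seed = as.integer(seed)),
            class = "mask_spec")
}

#' @rdname artefact-specs
#' @export
rigid_motion_spec <- function(corrupt_fraction, n_segments, rot_std = 12,
                              trans_std = 30, pe_axis = 2L,
                              protect_center_frac = 0, seed = 1L) {
  if (corrupt_fraction < 0.30 || corrupt_fraction > 0.80)
    stopf("'corrupt_fraction' must lie in [0.30, 0.80] (got %g)", corrupt_fraction)
  if (n_segments < 4 || n_segments > 24)
    stopf("'n_segments' must lie in [4, 24] (got %s)", toString(n_segments))
  if (rot_std < 0 || trans_std < 0) stopf("motion standard deviations must be >= 0")
  if (protect_center_frac < 0 || protect_center_frac >= 1)
    stopf("'protect_center_frac' must lie in [0, 1)")
  structure(list(corrupt_fraction = corrupt_fraction,
                 n_segments = as.integer(n_segments), rot_std = rot_std,
                 trans_std = trans_std, pe_axis = as.integer(pe_axis),
                 protect_center_frac = protect_center_frac,
                 seed = as.integer(seed)),
            class = "rigid_motion_spec")
}

#' @rdname artefact-specs
#' @export
periodic_motion_spec <- function(delta, alpha, beta, ky0, pe_axis = 2L,
                                 seed = 1L) {
  if (delta < 20 || delta > 120) stopf("'delta' must lie in [20, 120] (got %g)", delta)
  if (alpha < 0.1 || alpha > 5) stopf("'alpha' must lie in [0.1, 5] (got %g)", alpha)
  if (beta < 0 || beta > pi / 4) stopf("'beta' must lie in [0, pi/4] (got %g)", beta)
  if (ky0 <= pi / 10 || ky0 > pi / 8)
    stopf("'ky0' must lie in (pi/10, pi/8] (got %g)", ky0)
  structure(list(delta = delta, alpha = alpha, beta = beta, ky0 = ky0,
                 pe_axis = as.integer(pe_axis), seed = as.integer(seed)),
            class = "periodic_motion_spec")
}

#' @rdname artefact-specs
#' @export
noise_spec <- function(snr_db, seed = 1L) {
  if (snr_db < -12 || snr_db > 10)
    stopf("'snr_db' must lie in [-12, 10] (got %g)", snr_db)
  structure(list(snr_db = snr_db, seed = as.integer(seed)), class = "noise_spec")
}

## ---------------------------------------------------------------- bias field

#' Draw the low-resolution Gaussian spatial random field
#'
#' Synthesizes a stationary zero-mean Gaussian random field with correlation
#' `exp(-(pi/4) * (r/l)^2)` (scaled by `variance`) on the
#' `lowres_size x lowres_size` grid, by circulant embedding on an enlarged
#' torus: the covariance kernel is evaluated on a torus large enough for the
#' Gaussian to decay, its eigenvalues are obtained by FFT (tiny negative
#' values from truncation are clipped to zero), and white noise is filtered
#' by the square root of the spectrum.
#'
#' @param spec A [bias_field_spec()].
#' @return A `lowres_size x lowres_size` numeric matrix (unnormalized field).
#' @export
simulate_srf_lowres <- function(spec) {
  n <- spec$lowres_size
  l <- spec$length_scale
  # torus side: Gaussian cov drops below ~1e-9 at r = l*sqrt(4/pi*log(1e9))
  reach <- ceiling(l * sqrt(4 / pi * log(1e9)))
  M <- 2^ceiling(log2(max(2 * n, n + reach)))
  idx <- 0:(M - 1)
  d <- pmin(idx, M - idx)
  r2 <- outer(d^2, d^2, "+")
  C <- spec$variance * exp(-(pi / 4) * r2 / l^2)
  lam <- Re(fft(C))
  lam[lam < 0] <- 0
  with_seed(spec$seed, {
    xi <- matrix(rnorm(M * M), M, M)
    y <- Re(fft(sqrt(lam) * fft(xi), inverse = TRUE)) / (M * M)
    y[seq_len(n), seq_len(n)]
  })
}

# Separable cubic-spline upsampling of a small grid to `shape`.
spline_upsample <- function(m, shape) {
  n1 <- nrow(m); n2 <- ncol(m)
  x1 <- seq(1, n1, length.out = shape[1])
  x2 <- seq(1, n2, length.out = shape[2])
  tmp <- apply(m, 2, function(col) splinefun(seq_len(n1), col)(x1))  # H x n2
  t(apply(tmp, 1, function(row) splinefun(seq_len(n2), row)(x2)))   # H x W
}

#' Simulate a multiplicative bias field
#'
#' Draws the low-resolution spatial random field, upsamples it smoothly with
#' separable cubic splines to `shape`, and min--max normalizes it to the
#' multiplicative interval implied by `strength` and `range_convention`
#' (attaining the interval endpoints exactly). The result is a strictly
#' positive field to be applied with [apply_bias()].
#'
#' @param shape Length-2 integer vector, the output field size.
#' @param spec A [bias_field_spec()].
#' @return Numeric matrix of dimension `shape`, with attribute `"bounds"`
#'   giving the normalized `(min, max)`.
#' @export
simulate_bias_field <- function(shape, spec) {
  s <- spec$strength
  bounds <- switch(spec$range_convention,
                   "reciprocal" = c(1 - s / 2, 1 / (1 - s / 2)),
                   "half-span" = c(1 - s / 2, 1 + s / 2),
                   "symmetric" = c(1 - s, 1 + s))
  if (bounds[1] <= 0)
    stopf("normalized field bounds [%g, %g] are not strictly positive; reduce 'strength' or use the half-span convention",
          bounds[1], bounds[2])
  low <- simulate_srf_lowres(spec)
  f <- spline_upsample(low, shape)
  rng <- range(f)
  if (rng[2] > rng[1]) {
    f <- bounds[1] + (bounds[2] - bounds[1]) * (f - rng[1]) / (rng[2] - rng[1])
  } else {
    f[] <- mean(bounds)
  }
  attr(f, "bounds") <- bounds
  f
}

#' Apply a multiplicative bias field
#'
#' @param image Numeric matrix.
#' @param field Strictly positive numeric matrix of the same shape.
#' @return `image * field`.
#' @export
apply_bias <- function(image, field) {
  check_image(image); check_image(field, "field")
  check_same_shape(image, field, "image", "field")
  if (any(field <= 0)) stopf("'field' must be strictly positive")
  image * field
}

#' Ensemble lag correlation of low-resolution field draws
#'
#' Estimates the spatial correlation of the synthesized random field at a
#' given horizontal lag from a list of independent low-resolution draws, for
#' checking the field against its closed-form Gaussian correlation
#' `exp(-(pi/4) * (lag/l)^2)` (which equals `exp(-pi/4) ~ 0.456` at
#' `lag = l`).
#'
#' @param fields List of equally sized numeric matrices.
#' @param lag Horizontal pixel offset (0 <= lag < ncol).
#' @return The pooled product-moment correlation at that lag.
#' @export
srf_lag_correlation <- function(fields, lag) {
  n2 <- ncol(fields[[1]])
  if (lag < 0 || lag >= n2) stopf("'lag' must lie in [0, %d)", n2)
  a <- unlist(lapply(fields, function(f) f[, seq_len(n2 - lag)]))
  b <- unlist(lapply(fields, function(f) f[, seq_len(n2 - lag) + lag]))
  stats::cor(a, b)
}

## --------------------------------------------------------------------- masks

band_percent <- function(accel) c(`2` = 16, `3` = 12, `4` = 8, `8` = 4)[[as.character(accel)]]

#' Build a Cartesian line-selection mask
#'
#' The center band of `round(band% * n_lines)` contiguous lines around the DC
#' line is always fully selected (band width 16/12/8/4 % for acceleration
#' 2/3/4/8). For `"equidistant"` and `"random"` kinds the remaining budget of
#' `round(n_lines/accel) - band` lines is taken from the non-band lines at a
#' fixed stride with a seeded random offset, or uniformly without
#' replacement, respectively. The `"centered"` kind selects only the band.
#' Counts use round-half-away-from-zero.
#'
#' @param spec A [mask_spec()].
#' @return Logical vector of length `n_lines` with attributes `spec` and
#'   `n_selected`.
#' @export
make_mask <- function(spec) {
  n <- spec$n_lines
  band_n <- as.integer(round_half_up(band_percent(spec$accel) / 100 * n))
  budget <- as.integer(round_half_up(n / spec$accel))
  dc <- dc_index(n)
  first <- dc - (band_n - 1L) %/% 2L
  band <- first:(first + band_n - 1L)
  mask <- logical(n)
  mask[band] <- TRUE
  if (spec$kind != "centered") {
    if (band_n > budget)
      stopf("center band (%d lines) exceeds the sampling budget (%d lines) for accel %d at n_lines=%d",
            band_n, budget, spec$accel, n)
    m <- budget - band_n
    nonband <- setdiff(seq_len(n), band)
    if (m > 0) {
      sel <- with_seed(spec$seed, {
        if (spec$kind == "equidistant") {
          stride <- (n - band_n) %/% m
          offset <- sample.int(stride, 1) - 1L
          nonband[offset + 1L + stride * (seq_len(m) - 1L)]
        } else {
          sample(nonband, m)
        }
      })
      mask[sel] <- TRUE
    }
  }
  attr(mask, "spec") <- spec
  attr(mask, "n_selected") <- sum(mask)
  mask
}

#' Zero-fill unselected k-space lines
#'
#' Selected lines are kept bit-identical; unselected lines are set to zero
#' (the zero-filled reconstruction convention).
#'
#' @param k Complex k-space matrix (as from [to_kspace()]).
#' @param mask Logical vector from [make_mask()], one entry per PE line.
#' @param pe_axis Phase-encoding axis; defaults to the mask's own spec, then
#'   to the `pe_axis` attribute of `k`, then to 2.
#' @return The masked k-space matrix.
#' @export
apply_mask <- function(k, mask, pe_axis = NULL) {
  if (is.null(pe_axis)) {
    sp <- attr(mask, "spec")
    pe_axis <- if (!is.null(sp)) sp$pe_axis else attr(k, "pe_axis")
    if (is.null(pe_axis)) pe_axis <- 2L
  }
  if (length(mask) != n_pe_lines(k, pe_axis))
    stopf("mask length (%d) does not match the number of PE lines (%d)",
          length(mask), n_pe_lines(k, pe_axis))
  if (pe_axis == 1L) k[!mask, ] <- 0 else k[, !mask] <- 0
  k
}

#' Subsample an image through its k-space
#'
#' Composition `to_kspace -> apply_mask -> from_kspace`: the retrospective
#' undersampling used to emulate accelerated acquisition, returning the
#' zero-filled reconstruction.
#'
#' @param image Numeric matrix.
#' @param spec A [mask_spec()]; its `n_lines` must match the image extent
#'   along `pe_axis`.
#' @return List with elements `image` (corrupted slice), `mask`, and
#'   `pe_axis`.
#' @export
subsample_image <- function(image, spec) {
  check_image(image)
  n <- dim(image)[spec$pe_axis]
  if (spec$n_lines != n)
    stopf("'n_lines' (%d) does not match image extent along pe_axis %d (%d)",
          spec$n_lines, spec$pe_axis, n)
  mask <- make_mask(spec)
  k <- to_kspace(image, spec$pe_axis)
  u <- from_kspace(apply_mask(k, mask, spec$pe_axis))
  attr(u, "imag_norm") <- NULL
  list(image = u, mask = mask, pe_axis = spec$pe_axis)
}

## -------------------------------------------------------------- rigid motion

# Rigid in-plane transform: rotation (degrees, about the image center) plus
# translation (pixels), bilinear interpolation, zero padding. The inverse
# mapping convention: output pixel x takes the value of the input at
# R(-theta) (x - c) + c - t.
rigid_transform <- function(img, angle_deg, ty, tx) {
  h <- nrow(img); w <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- cos(th) * yy + sin(th) * xx + cy - ty
  sx <- -sin(th) * yy + cos(th) * xx + cx - tx
  i0 <- floor(sy); j0 <- floor(sx)
  fy <- sy - i0; fx <- sx - j0
  pick <- function(i, j) {
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    ii <- pmin(pmax(i, 1), h); jj <- pmin(pmax(j, 1), w)
    v <- matrix(img[cbind(as.vector(ii), as.vector(jj))], h, w)
    v * ok
  }
  pick(i0, j0) * (1 - fy) * (1 - fx) + pick(i0 + 1, j0) * fy * (1 - fx) +
    pick(i0, j0 + 1) * (1 - fy) * fx + pick(i0 + 1, j0 + 1) * fy * fx
}

#' Corrupt an image with piecewise-constant rigid motion
#'
#' Selects `round(corrupt_fraction * n_lines)` PE lines as `n_segments`
#' contiguous, non-overlapping runs placed uniformly at random. For each
#' segment one rigid transform (rotation about the image center and per-axis
#' translation, drawn from zero-mean Gaussians with the spec's standard
#' deviations) is applied in image space; the transformed image's k-space
#' lines replace that segment's lines. All non-corrupted lines are copied
#' verbatim from the clean k-space. An optional protected center band
#' (`protect_center_frac`) is never corrupted.
#'
#' @param image Numeric matrix.
#' @param spec A [rigid_motion_spec()].
#' @return List with `image` (corrupted slice), `kspace` (the assembled
#'   corrupted k-space, in which non-corrupted lines are verbatim copies of
#'   the clean k-space), and `segments`, a data frame with one row per
#'   segment (`rot_deg`, `ty`, `tx`) and a list column `lines` of corrupted
#'   line indices.
#' @export
apply_rigid_motion <- function(image, spec) {
  check_image(image)
  pe <- spec$pe_axis
  n <- dim(image)[pe]
  k0 <- to_kspace(image, pe)
  protected <- integer(0)
  if (spec$protect_center_frac > 0) {
    pb <- as.integer(round_half_up(spec$protect_center_frac * n))
    if (pb > 0) {
      first <- dc_index(n) - (pb - 1L) %/% 2L
      protected <- first:(first + pb - 1L)
    }
  }
  avail <- setdiff(seq_len(n), protected)
  n_corrupt <- as.integer(round_half_up(spec$corrupt_fraction * n))
  n_corrupt <- min(n_corrupt, length(avail))
  nseg <- min(spec$n_segments, n_corrupt)
  res <- with_seed(spec$seed, {
    # segment lengths: random composition of n_corrupt into nseg parts >= 1
    lens <- if (nseg > 1) {
      cuts <- sort(sample.int(n_corrupt - 1L, nseg - 1L))
      diff(c(0L, cuts, n_corrupt))
    } else n_corrupt
    # gaps: spread the free lines into nseg+1 slots (zeros allowed)
    free <- length(avail) - n_corrupt
    gaps <- if (free > 0) tabulate(sample.int(nseg + 1L, free, replace = TRUE),
                                   nbins = nseg + 1L) else integer(nseg + 1L)
    pos <- cumsum(gaps[seq_len(nseg)] + c(0L, lens[-nseg])) + 1L
    segs <- lapply(seq_len(nseg), function(s) avail[pos[s] + 0:(lens[s] - 1L)])
    pars <- data.frame(rot_deg = rnorm(nseg, 0, spec$rot_std),
                       ty = rnorm(nseg, 0, spec$trans_std),
                       tx = rnorm(nseg, 0, spec$trans_std))
    list(segs = segs, pars = pars)
  })
  k <- k0
  for (s in seq_along(res$segs)) {
    p <- res$pars[s, ]
    img_t <- rigid_transform(image, p$rot_deg, p$ty, p$tx)
    kt <- to_kspace(img_t, pe)
    idx <- res$segs[[s]]
    if (pe == 1L) k[idx, ] <- kt[idx, ] else k[, idx] <- kt[, idx]
  }
  out <- from_kspace(k)
  attr(out, "imag_norm") <- NULL
  segments <- res$pars
  segments$lines <- res$segs
  list(image = out, kspace = k, segments = segments)
}

## ----------------------------------------------------------- periodic motion

#' Respiratory phase error
#'
#' `phi(ky) = ky * Delta * sin(alpha * ky + beta)` for `|ky| > ky0`, else 0.
#' Vectorized over `ky`.
#'
#' @param ky Normalized phase-encode coordinate(s) in `(-pi, pi]`.
#' @param spec A [periodic_motion_spec()].
#' @return Phase error(s) in radians.
#' @export
phase_error <- function(ky, spec) {
  ifelse(abs(ky) > spec$ky0,
         ky * spec$delta * sin(spec$alpha * ky + spec$beta), 0)
}

#' Corrupt with periodic (respiratory) motion
#'
#' `periodic_motion_kspace()` multiplies every k-space entry on PE line `ky`
#' by `exp(-1i * phi(ky))`, with `phi` from [phase_error()]. The factor has
#' unit modulus, so every k-space magnitude is preserved exactly, and lines
#' inside the protected center `|ky| <= ky0` are left bit-identical (they
#' are not touched at all). `apply_periodic_motion()` is the image-level
#' composition `to_kspace -> periodic_motion_kspace -> from_kspace`.
#'
#' @param k Complex k-space matrix (as from [to_kspace()]).
#' @param image Numeric matrix.
#' @param spec A [periodic_motion_spec()].
#' @return `periodic_motion_kspace`: the phase-corrupted k-space;
#'   `apply_periodic_motion`: the corrupted slice (real matrix).
#' @export
periodic_motion_kspace <- function(k, spec) {
  pe <- spec$pe_axis
  n <- n_pe_lines(k, pe)
  phi <- phase_error(pe_coordinates(n), spec)
  idx <- which(phi != 0)
  fac <- exp(-1i * phi[idx])
  if (pe == 1L) k[idx, ] <- k[idx, ] * fac else
    k[, idx] <- sweep(k[, idx, drop = FALSE], 2, fac, `*`)
  k
}

#' @rdname periodic_motion_kspace
#' @export
apply_periodic_motion <- function(image, spec) {
  check_image(image)
  k <- periodic_motion_kspace(to_kspace(image, spec$pe_axis), spec)
  out <- from_kspace(k)
  attr(out, "imag_norm") <- NULL
  out
}

## --------------------------------------------------------------------- noise

#' Corrupt an image with complex Gaussian k-space noise
#'
#' Computes `S`, the mean absolute k-space value, sets the per-component
#' noise standard deviation `N = S / 10^(snr_db/20)` so that
#' `SNR = 20*log10(S/N)` equals the target, adds independent zero-mean
#' Gaussian noise of standard deviation `N` to the real and imaginary parts
#' of every k-space entry, and inverse transforms.
#'
#' @param image Numeric matrix with nonzero energy.
#' @param spec A [noise_spec()].
#' @return The corrupted slice, with attributes `noise_sd_target` (`N`) and
#'   `noise_sd_realized` (the standard deviation of the drawn noise sample).
#' @export
add_noise <- function(image, spec) {
  check_image(image)
  k <- to_kspace(image)
  S <- mean(Mod(k))
  if (S == 0) stopf("'image' is identically zero; SNR is undefined")
  N <- S / 10^(spec$snr_db / 20)
  with_seed(spec$seed, {
    re <- rnorm(length(k), 0, N)
    im <- rnorm(length(k), 0, N)
    kn <- k + complex(real = re, imaginary = im)
    out <- from_kspace(matrix(kn, nrow(k), ncol(k)))
    attr(out, "imag_norm") <- NULL
    attr(out, "noise_sd_target") <- N
    attr(out, "noise_sd_realized") <- sd(c(re, im))
    out
  })
}

## ------------------------------------------------------------- random sample

artefact_labels <- c("bias", "subsampling", "motion", "noise")

#' Draw one randomly corrupted training sample
#'
#' Picks one of the four artefact types uniformly at random, draws its
#' parameters uniformly from their admissible ranges, applies it to the
#' clean slice, and returns the paired sample. The `"brain"` profile uses
#' rigid motion only; the `"pelvic"` profile picks rigid or periodic motion
#' with equal probability. Fully reproducible from `seed`.
#'
#' @param clean Numeric matrix (the artefact-free slice).
#' @param seed Integer seed.
#' @param profile `"brain"` or `"pelvic"`.
#' @return An object of class `artefact_sample`: list with `clean`,
#'   `corrupted`, `label` (1 = bias, 2 = subsampling, 3 = motion,
#'   4 = noise), and `params` (the spec actually drawn).
#' @export
draw_sample <- function(clean, seed, profile = c("brain", "pelvic")) {
  check_image(clean, "clean")
  profile <- match.arg(profile)
  child <- derive_seed(seed, 1L)
  drawn <- with_seed(seed, {
    y <- sample.int(4L, 1L)
    sp <- switch(y,
      bias_field_spec(strength = runif(1, 0.10, 1.00),
                      length_scale = runif(1, 10, 50), seed = child),
      {
        pe <- sample(c(1L, 2L), 1L)
        mask_spec(kind = sample(c("equidistant", "random", "centered"), 1),
                  accel = sample(c(2L, 3L, 4L, 8L), 1L),
                  n_lines = dim(clean)[pe], pe_axis = pe, seed = child)
      },
      {
        if (profile == "pelvic" && runif(1) < 0.5) {
          periodic_motion_spec(delta = runif(1, 20, 120),
                               alpha = runif(1, 0.1, 5),
                               beta = runif(1, 0, pi / 4),
                               ky0 = runif(1, pi / 10, pi / 8),
                               pe_axis = sample(c(1L, 2L), 1L), seed = child)
        } else {
          rigid_motion_spec(corrupt_fraction = runif(1, 0.30, 0.80),
                            n_segments = sample(4:24, 1L),
                            pe_axis = sample(c(1L, 2L), 1L), seed = child)
        }
      },
      noise_spec(snr_db = runif(1, -12, 10), seed = child))
    list(y = y, sp = sp)
  })
  y <- drawn$y; sp <- drawn$sp
  u <- switch(y,
              apply_bias(clean, simulate_bias_field(dim(clean), sp)),
              subsample_image(clean, sp)$image,
              if (inherits(sp, "periodic_motion_spec"))
                apply_periodic_motion(clean, sp)
              else apply_rigid_motion(clean, sp)$image,
              add_noise(clean, sp))
  attributes(u)[setdiff(names(attributes(u)), "dim")] <- NULL
  structure(list(clean = clean, corrupted = u, label = y, params = sp),
            class = "artefact_sample")
}

#' @export
print.artefact_sample <- function(x, ...) {
  cat(sprintf("artefact_sample: %dx%d slice, label %d (%s)\n",
              nrow(x$clean), ncol(x$clean), x$label, artefact_labels[x$label]))
  invisible(x)
}
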