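#' Fourier conventions for k-space work
#'
#' All simulators and the dual-domain model share one set of conventions:
#' centered 2-D discrete Fourier transforms with orthonormal scaling, the DC
#' component pinned to index `ceiling(n/2)` on each axis (1-based), and
#' "k-space line" meaning one full index along the phase-encoding axis.
#' With orthonormal scaling, Parseval's identity holds exactly:
#' `sum(|x|^2) == sum(|K|^2)`.
#'
#' @name kspace-conventions
#' @keywords internal
NULL

# 1-based index of the DC line on an axis of length n.
dc_index <- function(n) as.integer(ceiling(n / 2))

circshift <- function(x, s) {
  n <- length(x)
  if (n == 0) return(x)
  x[((seq_len(n) - 1 - s) %% n) + 1]
}

# Move DC from index 1 to dc_index(n) on both axes (and back).
kshift <- function(m) {
  sr <- dc_index(nrow(m)) - 1L; sc <- dc_index(ncol(m)) - 1L
  m[circshift(seq_len(nrow(m)), sr), circshift(seq_len(ncol(m)), sc), drop = FALSE]
}
ikshift <- function(m) {
  sr <- dc_index(nrow(m)) - 1L; sc <- dc_index(ncol(m)) - 1L
  m[circshift(seq_len(nrow(m)), -sr), circshift(seq_len(ncol(m)), -sc), drop = FALSE]
}

#' Centered orthonormal 2-D Fourier transform
#'
#' @param image A finite numeric (or complex) matrix.
#' @param pe_axis Which axis is phase-encoding: `1` (rows) or `2` (columns).
#'   Carried as an attribute on the result so downstream line operations know
#'   which direction was acquired line by line.
#' @return A complex matrix of the same shape with DC at the grid center
#'   (index `ceiling(n/2)` per axis), scaled by `1/sqrt(H*W)`, with
#'   attribute `pe_axis`.
#' @export
to_kspace <- function(image, pe_axis = 2L) {
  if (!all(is.finite(Mod(image)))) stopf("'image' contains non-finite values")
  if (!pe_axis %in% c(1L, 2L)) stopf("'pe_axis' must be 1 or 2")
  k <- kshift(fft(image)) / sqrt(length(image))
  attr(k, "pe_axis") <- as.integer(pe_axis)
  k
}

#' Inverse centered orthonormal 2-D Fourier transform
#'
#' Returns the real part of the inverse transform; the magnitude of the
#' largest residual imaginary component is attached as attribute
#' `"imag_norm"` for diagnostics (it is ~0 for Hermitian-symmetric k-space).
#'
#' @param k Complex matrix as produced by [to_kspace()].
#' @return A real matrix with attribute `imag_norm`.
#' @export
from_kspace <- function(k) {
  z <- fft(ikshift(k), inverse = TRUE) / sqrt(length(k))
  out <- Re(z)
  attr(out, "imag_norm") <- max(abs(Im(z)))
  out
}

#' Crop an image in Fourier space
#'
#' Transforms, keeps the centered `out_shape` block of k-space, inverse
#' transforms, and rescales so a constant image maps to the same constant.
#' This is the standard way large scanner matrices (e.g. 512x512) are reduced
#' to the model size (320x320) without ringing from image-space cropping.
#'
#' @param image Numeric matrix.
#' @param out_shape Length-2 integer vector `(rows, cols)`, each no larger
#'   than the corresponding input dimension.
#' @return Numeric matrix of shape `out_shape`.
#' @export
fourier_crop <- function(image, out_shape) {
  check_image(image)
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 2 || any(out_shape < 1))
    stopf("'out_shape' must be two positive integers")
  if (any(out_shape > dim(image)))
    stopf("'out_shape' (%s) exceeds input shape (%s)",
          paste(out_shape, collapse = "x"), paste(dim(image), collapse = "x"))
  k <- to_kspace(image)
  ctr <- c(dc_index(nrow(image)), dc_index(ncol(image)))
  new_ctr <- c(dc_index(out_shape[1]), dc_index(out_shape[2]))
  r0 <- ctr[1] - new_ctr[1]
  c0 <- ctr[2] - new_ctr[2]
  kc <- k[r0 + seq_len(out_shape[1]), c0 + seq_len(out_shape[2]), drop = FALSE]
  scale <- sqrt(prod(out_shape) / length(image))
  out <- from_kspace(kc) * scale
  attr(out, "imag_norm") <- NULL
  out
}

#' Normalized phase-encode coordinates
#'
#' Evenly spaced coordinates with spacing `2*pi/n` on the half-open interval
#' `(-pi, pi]`, with the DC line at exactly 0 at index `ceiling(n/2)` --
#' the same index the centered transform assigns to DC.
#'
#' @param n_lines Number of phase-encoding lines (>= 2).
#' @return Numeric vector of length `n_lines`, monotonically increasing.
#' @export
pe_coordinates <- function(n_lines) {
  if (!is.numeric(n_lines) || length(n_lines) != 1 || n_lines < 2)
    stopf("'n_lines' must be a single integer >= 2")
  n <- as.integer(n_lines)
  2 * pi * (seq_len(n) - dc_index(n)) / n
}

# Extract / replace one PE line (a full row or column) of a matrix.
get_line <- function(m, i, pe_axis) if (pe_axis == 1L) m[i, ] else m[, i]
set_line <- function(m, i, pe_axis, v) {
  if (pe_axis == 1L) m[i, ] <- v else m[, i] <- v
  m
}
n_pe_lines <- function(m, pe_axis) if (pe_axis == 1L) nrow(m) else ncol(m)

#' Read or write fastMRI-dialect k-space HDF5 files
#'
#' The dialect is a single dataset named `"kspace"` holding `n_slices`
#' complex 2-D grids. The reader accepts the compound real/imaginary layout
#' produced by h5py (fields `r`/`i`, shape `(n, H, W)`), a native complex
#' dataset, or a real array of shape `(n, H, W, 2)` whose last axis stacks
#' the real and imaginary planes. The writer emits the `(n, H, W, 2)` layout
#' (the installed HDF5 binding cannot create compound complex types) and the
#' reader round-trips it.
#'
#' @param path File path.
#' @param slices For the writer, a list of equally sized complex matrices.
#' @return `read_kspace_h5`: list of complex matrices with attribute
#'   `source_shape`; `write_kspace_h5`: `path`, invisibly.
#' @export
read_kspace_h5 <- function(path) {
  if (!file.exists(path)) stopf("k-space file not found: %s", path)
  arr <- rhdf5::h5read(path, "kspace", compoundAsDataFrame = FALSE)
  rhdf5::h5closeAll()
  if (is.list(arr) && all(c("r", "i") %in% names(arr))) {
    # rhdf5 returns compound fields with dimensions in storage order
    # (reversed relative to the logical (n, H, W) layout)
    re <- aperm(arr$r, rev(seq_along(dim(arr$r))))
    im <- aperm(arr$i, rev(seq_along(dim(arr$i))))
    arr <- array(complex(real = as.numeric(re), imaginary = as.numeric(im)),
                 dim = dim(re))
  } else if (is.numeric(arr) && length(dim(arr)) == 4 && dim(arr)[4] == 2) {
    cx <- complex(real = as.numeric(arr[, , , 1]),
                  imaginary = as.numeric(arr[, , , 2]))
    arr <- array(cx, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3)
    stopf("dataset 'kspace' in %s has unsupported shape (%s)",
          path, paste(dim(arr), collapse = "x"))
  out <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ])
  attr(out, "source_shape") <- dim(arr)
  out
}

#' @rdname read_kspace_h5
#' @export
write_kspace_h5 <- function(slices, path) {
  arr <- aperm(simplify2array(slices), c(3, 1, 2))
  out <- array(0, dim = c(dim(arr), 2))
  out[, , , 1] <- Re(arr)
  out[, , , 2] <- Im(arr)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(out, path, "kspace")
  rhdf5::h5closeAll()
  invisible(path)
}
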