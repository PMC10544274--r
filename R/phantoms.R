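#' Specify a synthetic anatomical phantom
#'
#' A phantom is a piecewise-constant 2-D slice built from nested, randomly
#' posed ellipses ("tissues") with Gaussian-smoothed boundaries. Phantoms give
#' the corruption simulators and the edge-sensitive convolutional loss
#' realistic intensity plateaus and gradient structure to act on, without any
#' dataset download.
#'
#' @param height,width Grid size in pixels; both must be at least 32.
#' @param n_regions Number of nested elliptical tissue regions (>= 1).
#' @param intensity_range Length-2 numeric `(lo, hi)`; interior intensities
#'   are drawn uniformly from this interval and the background sits at `lo`.
#'   The default `(0, 1)` matches the convention that images are normalized
#'   to `[0, 1]` before corruption.
#' @param edge_softness Standard deviation, in pixels, of the Gaussian used
#'   to smooth region boundaries. `0` keeps hard edges.
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(height = 320L, width = 320L, n_regions = 6L,
                         intensity_range = c(0, 1), edge_softness = 1,
                         seed = 1L) {
  if (!is.numeric(height) || length(height) != 1 || height < 32)
    stopf("'height' must be a single number >= 32 (got %s)", toString(height))
  if (!is.numeric(width) || length(width) != 1 || width < 32)
    stopf("'width' must be a single number >= 32 (got %s)", toString(width))
  if (!is.numeric(n_regions) || length(n_regions) != 1 || n_regions < 1)
    stopf("'n_regions' must be a single number >= 1")
  if (length(intensity_range) != 2 || !all(is.finite(intensity_range)) ||
      intensity_range[1] > intensity_range[2])
    stopf("'intensity_range' must be finite (lo, hi) with lo <= hi")
  if (!is.numeric(edge_softness) || edge_softness < 0)
    stopf("'edge_softness' must be a non-negative number of pixels")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_regions = as.integer(n_regions),
                 intensity_range = as.numeric(intensity_range),
                 edge_softness = as.numeric(edge_softness),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%d, %d regions, intensities [%g, %g], softness %g px, seed %d\n",
              x$height, x$width, x$n_regions, x$intensity_range[1],
              x$intensity_range[2], x$edge_softness, x$seed))
  invisible(x)
}

#' Generate one synthetic phantom slice
#'
#' Draws `n_regions` nested ellipses (each placed inside its parent with
#' shrinking semi-axes and a random orientation), fills each with a constant
#' intensity drawn uniformly from `intensity_range`, smooths boundaries with
#' a Gaussian of width `edge_softness`, and returns the slice. Values stay
#' inside `intensity_range` by construction (smoothing is a convex
#' combination).
#'
#' @param spec A [phantom_spec()].
#' @return A `height x width` numeric matrix.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$height; w <- spec$width
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  with_seed(spec$seed, {
    img <- matrix(lo, h, w)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    # outermost ellipse roughly centered, filling most of the grid
    cy <- h / 2 + runif(1, -0.05, 0.05) * h
    cx <- w / 2 + runif(1, -0.05, 0.05) * w
    a <- runif(1, 0.32, 0.42) * h
    b <- runif(1, 0.32, 0.42) * w
    for (k in seq_len(spec$n_regions)) {
      th <- runif(1, 0, pi)
      val <- runif(1, lo, hi)
      dy <- yy - cy; dx <- xx - cx
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[inside] <- val
      # next region nests inside this one
      shrink <- runif(1, 0.55, 0.8)
      max_off <- (1 - shrink) * 0.5
      cy <- cy + runif(1, -max_off, max_off) * a
      cx <- cx + runif(1, -max_off, max_off) * b
      a <- a * shrink
      b <- b * shrink
    }
    if (spec$edge_softness > 0) img <- gaussian_smooth(img, spec$edge_softness)
    img
  })
}

#' Generate a stack of independent phantom slices
#'
#' Each slice uses a child seed derived deterministically from `seed`, so the
#' whole stack is reproducible from `(spec, seed)` while slices differ from
#' one another.
#'
#' @param spec A [phantom_spec()]; its own `seed` field is ignored here.
#' @param n_slices Number of slices (>= 1).
#' @param seed Integer seed for the stack.
#' @return A list of `n_slices` matrices.
#' @export
generate_dataset <- function(spec, n_slices, seed = 1L) {
  if (!is.numeric(n_slices) || length(n_slices) != 1 || n_slices < 1)
    stopf("'n_slices' must be a single number >= 1 (got %s)", toString(n_slices))
  lapply(seq_len(n_slices), function(i) {
    si <- spec
    si$seed <- derive_seed(seed, i)
    generate_phantom(si)
  })
}

#' Write or read a phantom stack as HDF5
#'
#' The file holds one dataset named `"slices"` with shape `(n, H, W)` and a
#' root attribute `"spec"` carrying the generating spec as JSON.
#'
#' @param slices List of equally sized matrices.
#' @param path Output file path (overwritten if present).
#' @param spec Optional [phantom_spec()] stored alongside the data.
#' @return `path`, invisibly.
#' @export
write_phantom_h5 <- function(slices, path, spec = NULL) {
  arr <- simplify2array(slices)            # H x W x n
  arr <- aperm(arr, c(3, 1, 2))            # n x H x W
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(arr, path, "slices")
  if (!is.null(spec)) {
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(as.character(jsonlite::toJSON(unclass(spec),
                                                          auto_unbox = TRUE)),
                            fid, "spec")
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_phantom_h5
#' @export
read_phantom_h5 <- function(path) {
  if (!file.exists(path)) stopf("phantom file not found: %s", path)
  arr <- rhdf5::h5read(path, "slices")
  rhdf5::h5closeAll()
  lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ])
}
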