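#' The nine-kernel bank of the convolutional loss
#'
#' Returns the ordered kernel bank used by [combined_conv_loss()]: the 3x3
#' identity stencil `I_E`, the Prewitt top/right operators (`I_PT`, `I_PR`),
#' the 3x3 and 5x5 Sobel top/right operators (`I_S3T`, `I_S3R`, `I_S5T`,
#' `I_S5R`), and the 3x3 and 5x5 Laplace operators (`I_L3`, `I_L5`).
#' Stencils are applied unflipped (cross-correlation); since each stencil
#' equals plus or minus its 180-degree flip this only fixes a sign that the
#' squared loss ignores, but it keeps hand-computed oracles unambiguous.
#'
#' @param deltas Named numeric vector of per-kernel scaling factors in
#'   `[0, 1]`; defaults to [default_deltas()] for the brain model.
#' @return An object of class `kernel_bank`: list with `kernels` (named list
#'   of integer matrices) and `deltas`.
#' @export
kernel_bank <- function(deltas = default_deltas("brain")) {
  kernels <- list(
    I_E   = matrix(c(0, 0, 0,  0, 1, 0,  0, 0, 0), 3, 3, byrow = TRUE),
    I_PT  = matrix(c(-1, -1, -1,  0, 0, 0,  1, 1, 1), 3, 3, byrow = TRUE),
    I_PR  = matrix(c(1, 0, -1,  1, 0, -1,  1, 0, -1), 3, 3, byrow = TRUE),
    I_S3T = matrix(c(-1, -2, -1,  0, 0, 0,  1, 2, 1), 3, 3, byrow = TRUE),
    I_S3R = matrix(c(1, 0, -1,  2, 0, -2,  1, 0, -1), 3, 3, byrow = TRUE),
    I_S5T = matrix(c(-2, -2, -4, -2, -2,
                     -1, -1, -2, -1, -1,
                      0,  0,  0,  0,  0,
                      1,  1,  2,  1,  1,
                      2,  2,  4,  2,  2), 5, 5, byrow = TRUE),
    I_S5R = matrix(c(2, 1, 0, -1, -2,
                     2, 1, 0, -1, -2,
                     4, 2, 0, -2, -4,
                     2, 1, 0, -1, -2,
                     2, 1, 0, -1, -2), 5, 5, byrow = TRUE),
    I_L3  = matrix(c(0, -1, 0,  -1, 4, -1,  0, -1, 0), 3, 3, byrow = TRUE),
    I_L5  = matrix(c( 0,  0, -1,  0,  0,
                      0, -1, -2, -1,  0,
                     -1, -2, 16, -2, -1,
                      0, -1, -2, -1,  0,
                      0,  0, -1,  0,  0), 5, 5, byrow = TRUE))
  deltas <- unlist(deltas)
  if (!all(names(kernels) %in% names(deltas)))
    stopf("'deltas' must name all nine kernels (%s)",
          paste(names(kernels), collapse = ", "))
  deltas <- deltas[names(kernels)]
  if (any(deltas < 0 | deltas > 1)) stopf("'deltas' must lie in [0, 1]")
  structure(list(kernels = kernels, deltas = deltas), class = "kernel_bank")
}

#' Shipped loss scaling factors
#'
#' The per-kernel scaling factors, regularization weight `alpha`, and
#' base-10 log learning rate that a Bayesian hyper-parameter search settled
#' on for the multi-task models trained with the convolutional loss on
#' brain and pelvic data. Shipped as defaults; they are not re-optimized
#' here.
#'
#' @param profile `"brain"` or `"pelvic"`.
#' @return `default_deltas()`: named numeric vector of nine scaling factors;
#'   `default_hyperparams()`: list with `deltas`, `alpha`, `lr_log10`,
#'   `optimizer`.
#' @export
default_deltas <- function(profile = c("brain", "pelvic")) {
  profile <- match.arg(profile)
  switch(profile,
    brain = c(I_E = 0.30, I_PT = 0.83, I_PR = 0.25, I_S3T = 0.74,
              I_S3R = 0.30, I_S5T = 0.21, I_S5R = 0.72, I_L3 = 0.09,
              I_L5 = 0.82),
    pelvic = c(I_E = 0.13, I_PT = 0.23, I_PR = 0.03, I_S3T = 0.84,
               I_S3R = 0.23, I_S5T = 0.14, I_S5R = 0.91, I_L3 = 0.38,
               I_L5 = 0.77))
}

#' @rdname default_deltas
#' @export
default_hyperparams <- function(profile = c("brain", "pelvic")) {
  profile <- match.arg(profile)
  list(deltas = default_deltas(profile),
       alpha = switch(profile, brain = 0.87, pelvic = 0.89),
       lr_log10 = switch(profile, brain = -3.91, pelvic = -3.88),
       optimizer = "rmsprop")
}

#' Single-kernel convolutional loss
#'
#' `mean((I*x - I*xhat)^2)` where `*` is valid-region cross-correlation with
#' the (odd-sized) stencil `I`: the mean squared difference of the two
#' convolved images, evaluated only where the stencil's support fits
#' entirely inside the image (no padding). All-zero border rows/columns of
#' the stencil are trimmed before convolution, so the 3x3 identity stencil
#' acts on every pixel and the loss then equals the plain MSE exactly.
#'
#' @param kernel Odd-sized numeric matrix stencil.
#' @param x,xhat Equal-shaped numeric matrices.
#' @return Non-negative scalar.
#' @export
conv_loss <- function(kernel, x, xhat) {
  check_same_shape(x, xhat, "x", "xhat")
  if (nrow(kernel) %% 2 == 0 || ncol(kernel) %% 2 == 0)
    stopf("'kernel' must have odd dimensions")
  kernel <- trim_zero_border(kernel)
  if (any(dim(kernel) > dim(x)))
    stopf("'kernel' (%s) is larger than the image (%s)",
          paste(dim(kernel), collapse = "x"), paste(dim(x), collapse = "x"))
  d <- cpp_xcorr2_valid(x - xhat, kernel)
  mean(d^2)
}

# Drop leading/trailing all-zero rows and columns of a stencil (keeps the
# evaluation region as large as the stencil's true support allows).
trim_zero_border <- function(k) {
  if (all(k == 0)) return(k[1, 1, drop = FALSE] * 0)
  rows <- which(rowSums(k != 0) > 0)
  cols <- which(colSums(k != 0) > 0)
  k[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}

#' Combined nine-kernel convolutional loss
#'
#' The delta-weighted sum of the nine single-kernel losses over the bank:
#' `sum_k delta_k * conv_loss(I_k, x, xhat)`. Linear in each delta; with
#' `deltas = c(I_E = 1, rest = 0)` it reduces to the (interior) MSE.
#'
#' @param bank A [kernel_bank()].
#' @param x,xhat Equal-shaped numeric matrices.
#' @return Non-negative scalar.
#' @export
combined_conv_loss <- function(bank, x, xhat) {
  if (!inherits(bank, "kernel_bank")) stopf("'bank' must be a kernel_bank")
  terms <- vapply(names(bank$kernels), function(nm) {
    if (bank$deltas[[nm]] == 0) 0 else
      bank$deltas[[nm]] * conv_loss(bank$kernels[[nm]], x, xhat)
  }, numeric(1))
  sum(terms)
}

#' Label-masked multi-task loss
#'
#' Evaluates `base_loss(v, u + p_y)`: only the residual head matching the
#' sample's artefact label `y` enters the loss; the indicator masking makes
#' the value (and its gradients) exactly invariant to the other heads.
#'
#' @param base_loss Function of two images returning a scalar (e.g.
#'   [mse_metric()] or a closure over [combined_conv_loss()]).
#' @param v Artefact-free image.
#' @param u Corrupted image.
#' @param residuals List of four correction maps `p1..p4` (a `ResidualSet`),
#'   each the same shape as `u`.
#' @param y Artefact label in `1..4`.
#' @return Scalar loss.
#' @export
multitask_loss <- function(base_loss, v, u, residuals, y) {
  if (!is.numeric(y) || length(y) != 1 || !y %in% 1:4)
    stopf("'y' must be a single label in 1..4 (got %s)", toString(y))
  if (length(residuals) != 4) stopf("'residuals' must hold four maps")
  check_same_shape(u, residuals[[y]], "u", sprintf("p%d", y))
  check_same_shape(v, u, "v", "u")
  base_loss(v, u + residuals[[y]])
}

#' Squared-L2 residual regularizer
#'
#' `alpha * sum(residual^2)`, added once per residual head; it penalizes
#' large corrections, encouraging the model to leave the input unchanged
#' unless an artefact is detected.
#'
#' @param residual Numeric matrix.
#' @param alpha Non-negative weight.
#' @return Non-negative scalar.
#' @export
l2_residual_reg <- function(residual, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    stopf("'alpha' must be a single non-negative number")
  alpha * sum(residual^2)
}
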