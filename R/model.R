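#' Configure the dual-branch residual correction network
#'
#' The model is two structurally identical encoder--decoder branches. The
#' image branch consumes the corrupted slice directly; the k-space branch
#' consumes its centered Fourier transform (real/imaginary as two channels)
#' and maps each head's two-channel output back through an inverse-Fourier
#' layer. Each branch is twelve convolutional blocks: an input feature
#' block, five strided (stride-2) downsampling blocks with
#' `base_channels * 2^d` channels for depth `d = 0..4`, five upsampling
#' blocks (nearest-neighbor resize + convolutions) whose inputs are
#' concatenated with the matching strided block's output (U-Net skips), and
#' an output block. Every block holds `convs_per_block` 3x3 convolutions,
#' each followed by per-channel normalization (optional) and a LeakyReLU
#' with slope 0.2. Four 1x1 convolutional heads per branch emit the
#' artefact-specific residuals; corresponding heads of the two branches are
#' summed. At the reference configuration (320x320, base 64, 3 convs per
#' block, normalization on) the model has 75.5 million trainable
#' parameters.
#'
#' @param input_size Input side length in pixels; must be divisible by 32
#'   (five stride-2 levels).
#' @param base_channels Channels of the first block (64 in the reference
#'   model); depth `d` uses `base_channels * 2^d`.
#' @param convs_per_block Convolutions per block (reference: 3).
#' @param kernel_size Convolution kernel size (reference: 3).
#' @param leaky_slope LeakyReLU negative slope.
#' @param n_heads Number of residual heads (one per artefact; fixed at 4).
#' @param use_batchnorm Whether each convolution is followed by per-channel
#'   normalization.
#' @param seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_size = 320L, base_channels = 64L,
                         convs_per_block = 3L, kernel_size = 3L,
                         leaky_slope = 0.2, n_heads = 4L,
                         use_batchnorm = TRUE, seed = 1L) {
  if (input_size %% 32 != 0)
    stopf("'input_size' must be divisible by 32 (got %d)", input_size)
  if (base_channels < 1 || convs_per_block < 1)
    stopf("'base_channels' and 'convs_per_block' must be >= 1")
  if (kernel_size %% 2 == 0) stopf("'kernel_size' must be odd")
  if (n_heads != 4L) stopf("'n_heads' is fixed at 4 (one per artefact)")
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 depth_levels = 5L,
                 convs_per_block = as.integer(convs_per_block),
                 kernel_size = as.integer(kernel_size),
                 leaky_slope = leaky_slope, n_heads = 4L,
                 use_batchnorm = isTRUE(use_batchnorm),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Count trainable parameters
#'
#' Pure function of the configuration: sums convolution weights and biases,
#' normalization scale/shift pairs, and the eight 1x1 head convolutions
#' (image-branch heads emit one channel, k-space-branch heads two).
#'
#' @param config A [model_config()].
#' @return Total number of trainable scalars.
#' @export
count_model_params <- function(config) {
  total <- 0
  for (branch in c("img", "ksp")) {
    cin <- if (branch == "img") 1L else 2L
    ops <- branch_ops(config, cin)
    for (op in ops) {
      if (op$kind == "conv") total <- total + op$k^2 * op$cin * op$cout + op$cout
      if (op$kind == "bn") total <- total + 2 * op$c
    }
    hout <- if (branch == "img") 1L else 2L
    total <- total + config$n_heads * (attr(ops, "out_channels") * hout + hout)
  }
  total
}

#' Build the dual-branch model
#'
#' Instantiates all weights (He initialization, seeded from the config) and
#' reports the trainable parameter count, which always equals
#' [count_model_params()].
#'
#' @param config A [model_config()].
#' @return An object of class `mrforge_model`: an environment holding the
#'   configuration, the parameter list, and the per-branch op sequences.
#'   Its `n_params` field is the trainable parameter count.
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) stopf("'config' must be a model_config")
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$ops <- list(img = branch_ops(config, 1L), ksp = branch_ops(config, 2L))
  with_seed(config$seed, {
    params <- c(init_branch_params(model$ops$img, config, "img"),
                init_branch_params(model$ops$ksp, config, "ksp"))
    tc_img <- attr(model$ops$img, "out_channels")
    tc_ksp <- attr(model$ops$ksp, "out_channels")
    for (i in seq_len(config$n_heads)) {
      params[[paste0("img_H", i, "_W")]] <-
        array(rnorm(tc_img, 0, 1 / sqrt(tc_img)), dim = c(1L, 1L, tc_img, 1L))
      params[[paste0("img_H", i, "_b")]] <- numeric(1)
      params[[paste0("ksp_H", i, "_W")]] <-
        array(rnorm(tc_ksp * 2, 0, 1 / sqrt(tc_ksp)), dim = c(1L, 1L, tc_ksp, 2L))
      params[[paste0("ksp_H", i, "_b")]] <- numeric(2)
    }
    model$params <- params
  })
  model$n_params <- sum(vapply(model$params, length, numeric(1)))
  stopifnot(model$n_params == count_model_params(config))
  class(model) <- "mrforge_model"
  model
}

#' @export
print.mrforge_model <- function(x, ...) {
  cat(sprintf("mrforge_model: %dx%d input, base %d, %d convs/block, %s normalization\n",
              x$config$input_size, x$config$input_size, x$config$base_channels,
              x$config$convs_per_block,
              if (x$config$use_batchnorm) "with" else "no"))
  cat(sprintf("  trainable parameters: %s (%.1f million)\n",
              format(x$n_params, big.mark = ","), x$n_params / 1e6))
  invisible(x)
}

#' Z-normalize an image
#'
#' `(x - mean(x)) / sd(x)` over all pixels (sample standard deviation), so
#' the output has mean 0 and standard deviation exactly 1. Affine-invariant:
#' `a*x + b` (a > 0) maps to the same output as `x`.
#'
#' @param image Numeric matrix with nonzero variance.
#' @return The normalized matrix.
#' @export
znorm <- function(image) {
  s <- sd(image)
  if (!is.finite(s) || s == 0) stopf("'image' has zero variance; cannot Z-normalize")
  (image - mean(image)) / s
}

# znorm forward/backward used inside the training objective (sample sd).
znorm_fwd <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- sqrt(sum((x - mu)^2) / (n - 1))
  list(y = (x - mu) / s, s = s, n = n)
}
znorm_bwd <- function(g, cache, y) {
  (g - mean(g) - y * sum(g * y) / (cache$n - 1)) / cache$s
}

# Heads: 1x1 convolutions from the trunk activation; k-space heads return a
# two-channel map that the inverse-Fourier layer reduces to a real residual.
head_fwd <- function(model, branch, trunk, i) {
  nm <- paste0(branch, "_H", i)
  h <- conv_fwd(trunk, model$params[[paste0(nm, "_W")]],
                model$params[[paste0(nm, "_b")]], 1L, 0L)
  if (branch == "ksp") ifft_real_fwd(h) else h[, , 1]
}

#' Run the model on a corrupted slice
#'
#' Computes the four residual maps `p1..p4` (summed over the two branches)
#' and the reconstruction `vhat = znorm(u + p1 + p2 + p3 + p4)`.
#' Deterministic for fixed weights.
#'
#' @param model A built [build_model()] object.
#' @param u Numeric matrix matching the configured input size (any size
#'   divisible by 32 is accepted).
#' @return List with `residuals` (list of four matrices) and
#'   `reconstruction` (Z-normalized matrix).
#' @export
forward_model <- function(model, u) {
  check_image(u, "u")
  if (nrow(u) %% 32 != 0 || ncol(u) %% 32 != 0)
    stopf("input size (%s) must be divisible by 32", paste(dim(u), collapse = "x"))
  cfg <- model$config
  fi <- forward_branch(model$params, model$ops$img,
                       array(u, c(dim(u), 1L)), cfg, "img")
  fk <- forward_branch(model$params, model$ops$ksp, fft_channels(u), cfg, "ksp")
  residuals <- lapply(seq_len(cfg$n_heads), function(i) {
    head_fwd(model, "img", fi$out, i) + head_fwd(model, "ksp", fk$out, i)
  })
  s <- u + Reduce(`+`, residuals)
  list(residuals = residuals, reconstruction = znorm(s))
}

## ------------------------------------------------------------ loss gradients

mse_loss_grad <- function(v, s) 2 * (s - v) / length(s)

conv_loss_grad <- function(bank, v, s) {
  g <- matrix(0, nrow(v), ncol(v))
  for (nm in names(bank$kernels)) {
    dl <- bank$deltas[[nm]]
    if (dl == 0) next
    kk <- trim_zero_border(bank$kernels[[nm]])
    D <- cpp_xcorr2_valid(v - s, kk)
    # adjoint of valid cross-correlation: pad and correlate with the
    # 180-degree flipped stencil
    ph <- nrow(kk) - 1L; pw <- ncol(kk) - 1L
    Dp <- matrix(0, nrow(D) + 2 * ph, ncol(D) + 2 * pw)
    Dp[ph + seq_len(nrow(D)), pw + seq_len(ncol(D))] <- D
    kf <- kk[rev(seq_len(nrow(kk))), rev(seq_len(ncol(kk))), drop = FALSE]
    g <- g - dl * (2 / length(D)) * cpp_xcorr2_valid(Dp, kf)
  }
  g
}

## ------------------------------------------------------------------ training

# One full forward + backward for a single (v, u, y) sample. Returns the
# objective pieces and the parameter gradient list. The data term is the
# base loss on Z-normalized images; the indicator masking means it only
# touches head y, while the L2 regularizer touches every head.
sample_grad <- function(model, v, u, y, base, bank, alpha) {
  cfg <- model$config
  fi <- forward_branch(model$params, model$ops$img,
                       array(u, c(dim(u), 1L)), cfg, "img")
  fk <- forward_branch(model$params, model$ops$ksp, fft_channels(u), cfg, "ksp")
  heads <- lapply(seq_len(4L), function(i) {
    nm_i <- paste0("img_H", i); nm_k <- paste0("ksp_H", i)
    hi <- conv_fwd(fi$out, model$params[[paste0(nm_i, "_W")]],
                   model$params[[paste0(nm_i, "_b")]], 1L, 0L)
    hk <- conv_fwd(fk$out, model$params[[paste0(nm_k, "_W")]],
                   model$params[[paste0(nm_k, "_b")]], 1L, 0L)
    list(hi = hi, hk = hk, p = hi[, , 1] + ifft_real_fwd(hk))
  })
  p_y <- heads[[y]]$p
  s <- u + p_y
  zs <- znorm_fwd(s)
  zv <- znorm_fwd(v)
  data_term <- if (base == "mse") mse_metric(zv$y, zs$y)
               else combined_conv_loss(bank, zv$y, zs$y)
  reg_term <- sum(vapply(heads, function(h) sum(h$p^2), numeric(1))) * alpha
  # gradient of the data term w.r.t. p_y via the znorm layer
  gz <- if (base == "mse") mse_loss_grad(zv$y, zs$y)
        else conv_loss_grad(bank, zv$y, zs$y)
  gs <- znorm_bwd(gz, zs, zs$y)
  grads <- list()
  acc <- function(gl) for (nm in names(gl)) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) gl[[nm]] else grads[[nm]] + gl[[nm]]
  }
  gti <- NULL; gtk <- NULL   # trunk grads
  for (i in seq_len(4L)) {
    gp <- 2 * alpha * heads[[i]]$p
    if (i == y) gp <- gp + gs
    # image head
    nm_i <- paste0("img_H", i)
    gh_i <- array(gp, c(dim(gp), 1L))
    ri <- conv_bwd(fi$out, model$params[[paste0(nm_i, "_W")]], gh_i, 1L, 0L)
    acc(stats::setNames(list(ri$gw, ri$gb),
                        paste0(nm_i, c("_W", "_b"))))
    gti <- if (is.null(gti)) ri$gx else gti + ri$gx
    # k-space head through the inverse-Fourier layer
    nm_k <- paste0("ksp_H", i)
    gh_k <- ifft_real_bwd(gp)
    rk <- conv_bwd(fk$out, model$params[[paste0(nm_k, "_W")]], gh_k, 1L, 0L)
    acc(stats::setNames(list(rk$gw, rk$gb),
                        paste0(nm_k, c("_W", "_b"))))
    gtk <- if (is.null(gtk)) rk$gx else gtk + rk$gx
  }
  bi <- backward_branch(model$params, model$ops$img, fi$cache, gti, cfg, "img")
  bk <- backward_branch(model$params, model$ops$ksp, fk$cache, gtk, cfg, "ksp")
  acc(bi$grads); acc(bk$grads)
  list(loss = data_term + reg_term, data = data_term, grads = grads)
}

optimizer_state <- function(params) lapply(params, function(p) p * 0)

optimizer_step <- function(model, state, grads, lr, optimizer = "rmsprop",
                           rho = 0.9, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g^2
    model$params[[nm]] <- model$params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  state
}

#' Train the model on paired artefact samples
#'
#' Minimizes the per-sample objective: the label-masked multi-task data term
#' (base loss on Z-normalized images between the clean slice and
#' `u + p_y`) plus the squared-L2 regularizer `alpha * ||p_i||^2` on every
#' residual head. Mini-batch RMSprop with the shipped default learning rate
#' `10^-3.91`; training stops early when the validation MSE has not
#' improved for `patience` consecutive epochs. Fully seeded.
#'
#' @param model A [build_model()] object (updated in place).
#' @param samples List of `artefact_sample` objects (or lists with `clean`,
#'   `corrupted`, `label`).
#' @param epochs Maximum number of epochs.
#' @param base `"mse"` or `"conv"` (the nine-kernel convolutional loss).
#' @param deltas Scaling factors for the convolutional loss
#'   (default: shipped brain-model values).
#' @param alpha Regularization weight (default: shipped brain-model value).
#' @param lr Learning rate (default `10^-3.91`).
#' @param batch_size Mini-batch size.
#' @param val_fraction Fraction of samples held out for validation.
#' @param patience Early-stopping patience, in epochs, on validation MSE.
#' @param seed Seed for the split and sample order.
#' @param verbose Print per-epoch progress.
#' @return A data frame log with columns `epoch`, `train_loss`, `val_mse`.
#' @export
train_model <- function(model, samples, epochs = 20L, base = c("mse", "conv"),
                        deltas = default_deltas("brain"),
                        alpha = default_hyperparams("brain")$alpha,
                        lr = 10^default_hyperparams("brain")$lr_log10,
                        batch_size = 8L, val_fraction = 0.2, patience = 10L,
                        seed = 1L, verbose = FALSE) {
  base <- match.arg(base)
  bank <- if (base == "conv") kernel_bank(deltas) else NULL
  n <- length(samples)
  if (n < 2) stopf("need at least 2 samples")
  idx <- with_seed(derive_seed(seed, 0L), sample.int(n))
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  if (length(tr_idx) < 1) stopf("training split is empty")
  state <- optimizer_state(model$params)
  val_mse <- function() {
    mean(vapply(val_idx, function(i) {
      sm <- samples[[i]]
      out <- forward_model(model, sm$corrupted)
      mse_metric(znorm(sm$clean), out$reconstruction)
    }, numeric(1)))
  }
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_mse = numeric(0))
  best <- val_mse(); wait <- 0L
  log <- rbind(log, data.frame(epoch = 0L, train_loss = NA_real_, val_mse = best))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample(tr_idx))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
      bg <- NULL
      bl <- 0
      for (i in bidx) {
        sm <- samples[[i]]
        r <- sample_grad(model, sm$clean, sm$corrupted, sm$label, base, bank, alpha)
        bl <- bl + r$loss
        if (is.null(bg)) bg <- r$grads else
          for (nm in names(r$grads)) bg[[nm]] <- bg[[nm]] + r$grads[[nm]]
      }
      for (nm in names(bg)) bg[[nm]] <- bg[[nm]] / length(bidx)
      state <- optimizer_step(model, state, bg, lr)
      ep_loss <- ep_loss + bl / length(bidx)
      nb <- nb + 1L
    }
    vm <- val_mse()
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_mse = vm))
    if (verbose)
      message(sprintf("epoch %d: train %.5f, val MSE %.5f", ep, ep_loss / nb, vm))
    if (vm < best - 1e-12) { best <- vm; wait <- 0L } else wait <- wait + 1L
    if (wait >= patience) break
  }
  log
}

# Zero all head weights and biases (diagnostic: residuals become exactly 0
# and the reconstruction reduces to znorm(u)).
#' @rdname forward_model
#' @param x For `zero_heads()`: a model whose eight head convolutions are
#'   set to zero in place.
#' @export
zero_heads <- function(x) {
  for (br in c("img", "ksp")) for (i in 1:4) {
    x$params[[paste0(br, "_H", i, "_W")]][] <- 0
    x$params[[paste0(br, "_H", i, "_b")]][] <- 0
  }
  invisible(x)
}

#' Scaled-down end-to-end training demonstration
#'
#' Generates a phantom dataset, corrupts every slice with k-space noise at a
#' fixed SNR, trains a small dual-branch model, and evaluates held-out
#' slices: a parameter-recovery-style check that the architecture, losses,
#' gradients, and optimizer work together, at desk scale rather than the
#' reference scale. Defaults: 64x64 slices, 200 samples, base 4 channels,
#' 2 convolutions per block, 12 epochs, learning rate 5e-4 and a
#' mean-scaled regularization weight (`alpha / n_pixels`) -- the scale
#' adaptations are documented in the package vignette.
#'
#' @param seed Master seed for data, weights, and batching.
#' @param n_samples Number of paired samples.
#' @param input_size Slice side length (divisible by 32).
#' @param epochs Maximum epochs.
#' @param snr_db Corruption SNR in dB.
#' @param base_channels,convs_per_block Small-model configuration.
#' @param lr Learning rate.
#' @param val_fraction Held-out fraction.
#' @param verbose Print per-epoch progress.
#' @return List with `log` (training log), `ssim_corrupted`,
#'   `ssim_reconstructed` (held-out means), and the trained `model`.
#' @export
training_smoke <- function(seed = 1L, n_samples = 200L, input_size = 64L,
                           epochs = 12L, snr_db = 0,
                           base_channels = 4L, convs_per_block = 2L,
                           lr = 5e-4, val_fraction = 0.2, verbose = FALSE) {
  spec <- phantom_spec(input_size, input_size, 5, seed = 1)
  slices <- generate_dataset(spec, n_samples, seed = derive_seed(seed, 42))
  samples <- lapply(seq_along(slices), function(i)
    list(clean = slices[[i]],
         corrupted = add_noise(slices[[i]],
                               noise_spec(snr_db, seed = derive_seed(seed, 1000 + i))),
         label = 4L))
  model <- build_model(model_config(input_size, base_channels, convs_per_block,
                                    use_batchnorm = FALSE,
                                    seed = derive_seed(seed, 7)))
  log <- train_model(model, samples, epochs = epochs, base = "mse",
                     alpha = default_hyperparams("brain")$alpha / input_size^2,
                     lr = lr, batch_size = 8L, val_fraction = val_fraction,
                     seed = seed, verbose = verbose)
  n_val <- max(1L, floor(val_fraction * n_samples))
  held <- samples[(n_samples - n_val + 1L):n_samples]
  ss <- vapply(held, function(sm) {
    out <- forward_model(model, sm$corrupted)
    zv <- znorm(sm$clean)
    c(ssim_metric(zv, znorm(sm$corrupted)),
      ssim_metric(zv, out$reconstruction))
  }, numeric(2))
  list(log = log, ssim_corrupted = mean(ss[1, ]),
       ssim_reconstructed = mean(ss[2, ]), model = model)
}
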