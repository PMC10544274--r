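# Internal neural-network primitives: forward and backward passes for the
# layer types used by the dual-branch residual network. Activations are
# (H, W, C) arrays; weights are (kh, kw, C_in, C_out) arrays whose
# column-major flattening matches the compiled im2col kernel.

as_cube <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

conv_fwd <- function(x, W, b, stride = 1L, pad = NULL) {
  kh <- dim(W)[1]; kw <- dim(W)[2]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  wm <- matrix(W, kh * kw * dim(W)[3], dim(W)[4])
  cpp_conv2d_fwd(as_cube(x), wm, b, kh, kw, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, W, gy, stride = 1L, pad = NULL) {
  kh <- dim(W)[1]; kw <- dim(W)[2]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  wm <- matrix(W, kh * kw * dim(W)[3], dim(W)[4])
  r <- cpp_conv2d_bwd(as_cube(x), wm, as_cube(gy), kh, kw,
                      as.integer(stride), as.integer(pad))
  r$gw <- array(r$gw, dim = dim(W))
  r
}

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg)
}
lrelu_bwd <- function(g, neg, slope) {
  g[neg] <- g[neg] * slope
  g
}

# Per-channel normalization over the spatial extent (statistics are computed
# per sample, so inference needs no running moments and is deterministic).
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, d), xhat = xhat, inv = inv, dim = d)
}
bn_bwd <- function(g, cache, gamma) {
  d <- cache$dim
  gm <- matrix(g, d[1] * d[2], d[3])
  ggamma <- colSums(gm * cache$xhat)
  gbeta <- colSums(gm)
  gxhat <- sweep(gm, 2, gamma, `*`)
  t1 <- sweep(gxhat, 2, colMeans(gxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), `*`)
  gx <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}
up2_bwd <- function(g) {
  d <- dim(g)
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2)
  g[o1, o2, , drop = FALSE] + g[o1 + 1, o2, , drop = FALSE] +
    g[o1, o2 + 1, , drop = FALSE] + g[o1 + 1, o2 + 1, , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

## ----------------------------------------------------- branch architecture

# Build the op sequence for one branch: input feature block, five strided
# blocks (channels base*2^d), five upsampling blocks with U-Net concat
# skips, output block. Each "block" is `convs_per_block` conv layers, each
# followed by (optional) normalization and LeakyReLU.
branch_ops <- function(cfg, in_channels) {
  b <- cfg$base_channels
  m <- cfg$convs_per_block
  k <- cfg$kernel_size
  chans <- b * 2^(0:4)
  up_out <- c(4L * b, 2L * b, b, b, b)
  ops <- list()
  lid <- 0L
  add_conv <- function(cin, cout, stride) {
    lid <<- lid + 1L
    ops[[length(ops) + 1L]] <<- list(kind = "conv", name = paste0("L", lid),
                                     cin = cin, cout = cout, k = k,
                                     stride = stride)
    if (cfg$use_batchnorm)
      ops[[length(ops) + 1L]] <<- list(kind = "bn", name = paste0("L", lid),
                                       c = cout)
    ops[[length(ops) + 1L]] <<- list(kind = "lrelu")
    cout
  }
  cur <- in_channels
  for (i in seq_len(m)) cur <- add_conv(cur, b, 1L)
  ops[[length(ops) + 1L]] <- list(kind = "save_skip", id = "ib")
  for (d in 0:4) {
    for (i in seq_len(m)) cur <- add_conv(cur, chans[d + 1], if (i == 1) 2L else 1L)
    if (d < 4) ops[[length(ops) + 1L]] <- list(kind = "save_skip", id = paste0("d", d))
  }
  skip_ids <- c("d3", "d2", "d1", "d0", "ib")
  skip_ch <- c(chans[4], chans[3], chans[2], chans[1], b)
  for (u in 1:5) {
    ops[[length(ops) + 1L]] <- list(kind = "up2")
    ops[[length(ops) + 1L]] <- list(kind = "concat", id = skip_ids[u])
    cur <- cur + skip_ch[u]
    for (i in seq_len(m)) cur <- add_conv(cur, up_out[u], 1L)
  }
  for (i in seq_len(m)) cur <- add_conv(cur, b, 1L)
  attr(ops, "out_channels") <- cur
  ops
}

# He-style initialization for LeakyReLU nonlinearities.
init_branch_params <- function(ops, cfg, prefix) {
  params <- list()
  gain <- sqrt(2 / (1 + cfg$leaky_slope^2))
  for (op in ops) {
    if (op$kind == "conv") {
      fan_in <- op$k * op$k * op$cin
      nm <- paste0(prefix, "_", op$name)
      params[[paste0(nm, "_W")]] <-
        array(rnorm(op$k * op$k * op$cin * op$cout, 0, gain / sqrt(fan_in)),
              dim = c(op$k, op$k, op$cin, op$cout))
      params[[paste0(nm, "_b")]] <- numeric(op$cout)
    } else if (op$kind == "bn") {
      nm <- paste0(prefix, "_", op$name)
      params[[paste0(nm, "_g")]] <- rep(1, op$c)
      params[[paste0(nm, "_be")]] <- numeric(op$c)
    }
  }
  params
}

forward_branch <- function(params, ops, x, cfg, prefix) {
  cache <- vector("list", length(ops))
  skips <- list()
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (op$kind == "conv") {
      nm <- paste0(prefix, "_", op$name)
      cache[[i]] <- x
      x <- conv_fwd(x, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                    op$stride)
    } else if (op$kind == "bn") {
      nm <- paste0(prefix, "_", op$name)
      r <- bn_fwd(x, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]])
      cache[[i]] <- r
      x <- r$y
    } else if (op$kind == "lrelu") {
      r <- lrelu_fwd(x, cfg$leaky_slope)
      cache[[i]] <- r$neg
      x <- r$y
    } else if (op$kind == "up2") {
      x <- up2_fwd(x)
    } else if (op$kind == "concat") {
      cache[[i]] <- dim(x)[3]
      x <- concat_c(x, skips[[op$id]])
    } else if (op$kind == "save_skip") {
      skips[[op$id]] <- x
    }
  }
  list(out = x, cache = cache)
}

backward_branch <- function(params, ops, cache, g, cfg, prefix) {
  grads <- list()
  skip_grads <- list()
  for (i in rev(seq_along(ops))) {
    op <- ops[[i]]
    if (op$kind == "conv") {
      nm <- paste0(prefix, "_", op$name)
      r <- conv_bwd(cache[[i]], params[[paste0(nm, "_W")]], g, op$stride)
      grads[[paste0(nm, "_W")]] <- r$gw
      grads[[paste0(nm, "_b")]] <- r$gb
      g <- r$gx
    } else if (op$kind == "bn") {
      nm <- paste0(prefix, "_", op$name)
      r <- bn_bwd(g, cache[[i]], params[[paste0(nm, "_g")]])
      grads[[paste0(nm, "_g")]] <- r$ggamma
      grads[[paste0(nm, "_be")]] <- r$gbeta
      g <- r$gx
    } else if (op$kind == "lrelu") {
      g <- lrelu_bwd(g, cache[[i]], cfg$leaky_slope)
    } else if (op$kind == "up2") {
      g <- up2_bwd(g)
    } else if (op$kind == "concat") {
      c1 <- cache[[i]]
      skip_grads[[op$id]] <- g[, , (c1 + 1):dim(g)[3], drop = FALSE]
      g <- g[, , seq_len(c1), drop = FALSE]
    } else if (op$kind == "save_skip") {
      if (!is.null(skip_grads[[op$id]])) g <- g + skip_grads[[op$id]]
    }
  }
  list(gx = g, grads = grads)
}

## ----------------------------------------------------------- Fourier layers

# Input layer of the k-space branch: image -> two real channels (Re, Im of
# the centered orthonormal transform). No backward needed: the input is
# data, not a parameter.
fft_channels <- function(u) {
  k <- to_kspace(u)
  array(c(Re(k), Im(k)), dim = c(nrow(u), ncol(u), 2L))
}

# Output layer of the k-space branch heads: two real channels interpreted as
# a complex k-space map, inverse-transformed; the real part is the residual.
ifft_real_fwd <- function(h2) {
  z <- matrix(complex(real = h2[, , 1], imaginary = h2[, , 2]),
              dim(h2)[1], dim(h2)[2])
  Re(fft(ikshift(z), inverse = TRUE)) / sqrt(length(z))
}
# Adjoint: for the symmetric unitary DFT with our shift convention,
# d/d(re,im) of sum(g * Re(F^{-1} z)) is (Re(W g), -Im(W g)) where
# W = t(F^{-1}) = kshift-then-unnormalized-inverse-FFT / sqrt(N).
ifft_real_bwd <- function(g) {
  gz <- kshift(fft(g, inverse = TRUE)) / sqrt(length(g))
  array(c(Re(gz), -Im(gz)), dim = c(nrow(g), ncol(g), 2L))
}
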