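tiny_cfg <- model_config(32, 2, 1, use_batchnorm = FALSE, seed = 11)

test_that("parameter counting is a pure function of the configuration", {
  c1 <- count_model_params(tiny_cfg)
  expect_identical(c1, count_model_params(model_config(32, 2, 1,
                                                       use_batchnorm = FALSE,
                                                       seed = 99)))
  m <- build_model(tiny_cfg)
  expect_identical(m$n_params, c1)
  # batch normalization adds exactly two parameters per convolution channel
  cbn <- count_model_params(model_config(32, 2, 1, use_batchnorm = TRUE))
  expect_gt(cbn, c1)
  expect_error(model_config(100), "divisible")
})

test_that("model construction is seeded and the forward pass deterministic", {
  m1 <- build_model(tiny_cfg)
  m2 <- build_model(tiny_cfg)
  expect_identical(m1$params, m2$params)
  u <- matrix(runif(32 * 32), 32, 32)
  o1 <- forward_model(m1, u)
  expect_identical(o1, forward_model(m1, u))
  expect_length(o1$residuals, 4)
  expect_identical(dim(o1$reconstruction), dim(u))
  expect_error(forward_model(m1, matrix(0, 30, 30)), "divisible")
})

test_that("zeroed heads produce zero residuals and vhat = znorm(u)", {
  m <- build_model(tiny_cfg)
  zero_heads(m)
  u <- matrix(runif(32 * 32), 32, 32)
  out <- forward_model(m, u)
  expect_identical(max(abs(unlist(out$residuals))), 0)
  expect_equal(out$reconstruction, znorm(u), tolerance = 1e-14)
})

test_that("the reconstruction is Z-normalized and znorm is affine-invariant", {
  m <- build_model(tiny_cfg)
  u <- matrix(runif(32 * 32), 32, 32)
  v <- forward_model(m, u)$reconstruction
  expect_lt(abs(mean(v)), 1e-10)
  expect_equal(sd(v), 1, tolerance = 1e-10)
  x <- matrix(rnorm(100), 10, 10)
  expect_equal(znorm(3.2 * x + 7), znorm(x), tolerance = 1e-10)
  expect_error(znorm(matrix(1, 4, 4)), "variance")
  set.seed(30)
  g <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(abs(mean(znorm(g))), 1e-12)
  expect_lt(abs(sd(znorm(g)) - 1), 1e-12)
})

test_that("objective gradients match finite differences for every layer type", {
  set.seed(31)
  for (case in list(list(bn = FALSE, base = "mse"),
                    list(bn = TRUE, base = "mse"),
                    list(bn = FALSE, base = "conv"))) {
    m <- build_model(model_config(32, 2, 1, use_batchnorm = case$bn, seed = 11))
    v <- matrix(runif(32 * 32), 32, 32)
    u <- v + matrix(rnorm(32 * 32, 0, 0.2), 32, 32)
    y <- 2L; alpha <- 0.5
    bank <- kernel_bank()
    r <- mrforge:::sample_grad(m, v, u, y, case$base, bank, alpha)
    lossfn <- function() {
      out <- forward_model(m, u)
      s <- u + out$residuals[[y]]
      dt <- if (case$base == "mse") mse_metric(znorm(v), znorm(s))
            else combined_conv_loss(bank, znorm(v), znorm(s))
      dt + alpha * sum(vapply(out$residuals, function(p) sum(p^2), numeric(1)))
    }
    expect_equal(r$loss, lossfn(), tolerance = 1e-12)
    fd_at <- function(nm, j, eps) {
      p0 <- m$params[[nm]][j]
      m$params[[nm]][j] <- p0 + eps; lp <- lossfn()
      m$params[[nm]][j] <- p0 - eps; lm <- lossfn()
      m$params[[nm]][j] <- p0
      (lp - lm) / (2 * eps)
    }
    for (nm in sample(names(r$grads), 8)) {
      j <- sample(length(m$params[[nm]]), 1)
      an <- r$grads[[nm]][j]
      # central differences; a LeakyReLU kink inside the interval can spoil
      # one step size, so accept the best over several
      rel <- min(vapply(c(1e-6, 1e-5, 1e-7), function(eps) {
        fd <- fd_at(nm, j, eps)
        abs(fd - an) / max(1e-6, abs(fd), abs(an))
      }, numeric(1)))
      expect_lt(rel, 2e-4)
    }
  }
})

test_that("head masking: data-term gradients of non-selected heads are exactly zero", {
  set.seed(32)
  m <- build_model(tiny_cfg)
  v <- matrix(runif(32 * 32), 32, 32)
  u <- v + matrix(rnorm(32 * 32, 0, 0.2), 32, 32)
  y <- 1L
  # with alpha = 0 the only gradient source is the data term
  r <- mrforge:::sample_grad(m, v, u, y, "mse", NULL, 0)
  for (j in setdiff(1:4, y)) {
    for (br in c("img", "ksp")) {
      expect_identical(max(abs(r$grads[[paste0(br, "_H", j, "_W")]])), 0)
      expect_identical(max(abs(r$grads[[paste0(br, "_H", j, "_b")]])), 0)
    }
  }
  # the selected head does receive a data-term gradient
  expect_gt(max(abs(r$grads[[paste0("img_H", y, "_W")]])), 0)
  # with alpha > 0 the non-selected gradients equal the pure regularizer
  alpha <- 0.3
  r2 <- mrforge:::sample_grad(m, v, u, y, "mse", NULL, alpha)
  out <- forward_model(m, u)
  for (j in setdiff(1:4, y)) {
    gp <- 2 * alpha * out$residuals[[j]]
    fk <- mrforge:::forward_branch(m$params, m$ops$img,
                                   array(u, c(32, 32, 1)), m$config, "img")
    rb <- mrforge:::conv_bwd(fk$out, m$params[[paste0("img_H", j, "_W")]],
                             array(gp, c(32, 32, 1)), 1L, 0L)
    expect_equal(r2$grads[[paste0("img_H", j, "_W")]], rb$gw, tolerance = 1e-12)
  }
})

test_that("a few optimizer steps on one sample reduce the objective", {
  set.seed(33)
  m <- build_model(model_config(32, 2, 1, use_batchnorm = FALSE, seed = 3))
  v <- generate_phantom(phantom_spec(32, 32, 3, seed = 4))
  u <- add_noise(v, noise_spec(5, seed = 1))
  attributes(u)[setdiff(names(attributes(u)), "dim")] <- NULL
  st <- mrforge:::optimizer_state(m$params)
  losses <- numeric(6)
  for (i in 1:6) {
    r <- mrforge:::sample_grad(m, v, u, 4L, "mse", NULL, 1e-4)
    losses[i] <- r$loss
    st <- mrforge:::optimizer_step(m, st, r$grads, 1e-3)
  }
  expect_lt(losses[6], losses[1])
})

test_that("training declines validation MSE and early-stops on a plateau", {
  # micro run: just checks the loop mechanics, not correction quality
  set.seed(34)
  slices <- generate_dataset(phantom_spec(32, 32, 4, seed = 1), 12, seed = 9)
  samples <- lapply(seq_along(slices), function(i)
    list(clean = slices[[i]],
         corrupted = local({
           u <- add_noise(slices[[i]], noise_spec(5, seed = i))
           attributes(u)[setdiff(names(attributes(u)), "dim")] <- NULL
           u
         }),
         label = 4L))
  m <- build_model(model_config(32, 2, 1, use_batchnorm = FALSE, seed = 5))
  log <- train_model(m, samples, epochs = 4, base = "mse", alpha = 1e-4,
                     lr = 1e-3, batch_size = 4, seed = 2)
  expect_identical(log$epoch, 0:4)
  expect_lt(log$val_mse[5], log$val_mse[1])
  # patience: a zero learning rate cannot improve, so training halts early
  m2 <- build_model(model_config(32, 2, 1, use_batchnorm = FALSE, seed = 5))
  log2 <- train_model(m2, samples, epochs = 10, base = "mse", alpha = 1e-4,
                      lr = 0, batch_size = 4, patience = 3, seed = 2)
  expect_identical(max(log2$epoch), 3L)
})

test_that("shipped optimizer defaults are exposed through configuration", {
  hp <- default_hyperparams("brain")
  expect_identical(hp$optimizer, "rmsprop")
  expect_equal(10^hp$lr_log10, 1.230269e-4, tolerance = 1e-6)
})
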