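test_that("bias fields attain their configured bounds and stay positive", {
  sp <- bias_field_spec(1.0, 30, seed = 2)           # reciprocal default
  f <- simulate_bias_field(c(96, 96), sp)
  expect_equal(range(f), c(0.5, 2), tolerance = 1e-12)
  sp10 <- bias_field_spec(0.10, 20, seed = 3)
  f10 <- simulate_bias_field(c(64, 64), sp10)
  expect_equal(min(f10), 0.95, tolerance = 1e-12)
  expect_equal(max(f10), 1 / 0.95, tolerance = 1e-12)
  fh <- simulate_bias_field(c(64, 64), bias_field_spec(1.0, 30,
                            range_convention = "half-span", seed = 2))
  expect_equal(range(fh), c(0.5, 1.5), tolerance = 1e-12)
  fs <- simulate_bias_field(c(64, 64), bias_field_spec(0.2, 30,
                            range_convention = "symmetric", seed = 2))
  expect_equal(range(fs), c(0.8, 1.2), tolerance = 1e-12)
  expect_true(all(f > 0))
  # symmetric convention at full strength would hit zero: rejected
  expect_error(simulate_bias_field(c(32, 32), bias_field_spec(1.0, 30,
               range_convention = "symmetric")), "positive")
  # seeded determinism
  expect_identical(f, simulate_bias_field(c(96, 96), sp))
})

test_that("the low-res random field matches its Gaussian correlation function", {
  l <- 12
  fields <- lapply(1:120, function(i)
    simulate_srf_lowres(bias_field_spec(0.5, l, seed = i)))
  expect_equal(srf_lag_correlation(fields, 0), 1, tolerance = 1e-10)
  expect_lt(abs(srf_lag_correlation(fields, l) - exp(-pi / 4)), 0.06)
})

test_that("apply_bias is an exact multiplicative corruption", {
  p <- fix_phantom_64
  expect_identical(apply_bias(p, matrix(1, 64, 64)), p)
  expect_equal(apply_bias(matrix(0.5, 8, 8), matrix(2, 8, 8)),
               matrix(1, 8, 8))
  f <- simulate_bias_field(c(64, 64), bias_field_spec(0.4, 20, seed = 1))
  expect_lt(max(abs(apply_bias(p, f) / f - p)), 1e-12)
  expect_error(apply_bias(p, matrix(1, 32, 32)), "shape")
  expect_error(apply_bias(p, matrix(0, 64, 64)), "positive")
})

test_that("mask arithmetic follows the acceleration/band table", {
  # fastMRI-style: total = round(n/accel), band = round(band% * n)
  m4 <- make_mask(mask_spec("equidistant", 4, 320, seed = 1))
  expect_identical(sum(m4), 80L)                 # round(320/4)
  expect_true(all(m4[148:173]))                  # 26 contiguous center lines
  m8c <- make_mask(mask_spec("centered", 8, 320))
  expect_identical(sum(m8c), 13L)                # round(0.04*320)
  expect_true(all(diff(which(m8c)) == 1))        # contiguous
  expect_true(m8c[160])                          # DC selected
  for (acc in c(2, 3, 4, 8)) {
    mm <- make_mask(mask_spec("random", acc, 320, seed = acc))
    expect_identical(sum(mm), as.integer(round(320 / acc)))
    expect_true(mm[160])
    mc <- make_mask(mask_spec("centered", acc, 320))
    expect_identical(sum(mc), as.integer(floor(c(`2` = 16, `3` = 12, `4` = 8,
                                                 `8` = 4)[[as.character(acc)]] / 100 * 320 + 0.5)))
  }
  # equidistant reproducibility and seed sensitivity of the offset
  e1 <- make_mask(mask_spec("equidistant", 4, 320, seed = 5))
  expect_identical(e1, make_mask(mask_spec("equidistant", 4, 320, seed = 5)))
  expect_error(mask_spec("equidistant", 5, 320), "accel")
})

test_that("apply_mask zero-fills unselected lines and keeps selected ones bit-identical", {
  p <- fix_phantom_64
  k <- to_kspace(p, 2)
  sp <- mask_spec("random", 2, 64, pe_axis = 2, seed = 9)
  m <- make_mask(sp)
  km <- apply_mask(k, m)
  expect_identical(km[, m], k[, m])
  expect_true(all(km[, !m] == 0))
  expect_identical(apply_mask(k, rep(TRUE, 64)), k)
  expect_error(apply_mask(k, rep(TRUE, 63)), "match")
  # energy bookkeeping (Parseval): removed energy equals masked-line energy
  sub <- subsample_image(p, sp)
  expect_true(max(abs(sub$image - p)) > 1e-6)
  expect_equal(sum(Mod(k[, !m])^2),
               sum(p^2) - sum(Mod(apply_mask(k, m))^2), tolerance = 1e-8)
})

test_that("rigid motion preserves non-corrupted lines and honors its ranges", {
  p <- fix_phantom_64
  # all-zero motion parameters: pure FFT roundtrip
  r0 <- apply_rigid_motion(p, rigid_motion_spec(0.5, 8, rot_std = 0,
                                                trans_std = 0, seed = 3))
  expect_lt(max(abs(r0$image - p)), 1e-10)
  k0 <- to_kspace(p, 2)
  for (seed in 1:25) {
    sp <- rigid_motion_spec(runif(1, 0.3, 0.8), sample(4:24, 1), seed = seed)
    r <- apply_rigid_motion(p, sp)
    lines <- unlist(r$segments$lines)
    frac <- length(lines) / 64
    expect_gte(frac, 0.29)
    expect_lte(frac, 0.81)
    expect_lte(nrow(r$segments), 24)
    expect_identical(anyDuplicated(lines), 0L)
    uncor <- setdiff(1:64, lines)
    expect_identical(r$kspace[, uncor], k0[, uncor])
  }
  # protected center band is never corrupted
  sp <- rigid_motion_spec(0.6, 10, protect_center_frac = 0.25, seed = 2)
  r <- apply_rigid_motion(p, sp)
  prot <- 25:40   # round(0.25*64)=16 lines centered on DC index 32
  expect_length(intersect(unlist(r$segments$lines), prot), 0)
})

test_that("the rigid transform matches exact integer translations", {
  p <- fix_phantom_64
  t1 <- mrforge:::rigid_transform(p, 0, 3, 0)
  expect_equal(t1[4:64, ], p[1:61, ], tolerance = 1e-12)
  expect_true(all(t1[1:3, ] == 0))
  t2 <- mrforge:::rigid_transform(p, 0, 0, -2)
  expect_equal(t2[, 1:62], p[, 3:64], tolerance = 1e-12)
  # 360-degree rotation is the identity
  expect_lt(max(abs(mrforge:::rigid_transform(p, 360, 0, 0) - p)), 1e-9)
})

test_that("periodic motion is a per-entry k-space isometry with a protected center", {
  expect_equal(phase_error(pi / 4,
               periodic_motion_spec(40, 1, 0, pi / 9)),
               (pi / 4) * 40 * sin(pi / 4), tolerance = 1e-12)
  expect_identical(phase_error(0, periodic_motion_spec(40, 1, 0.1, pi / 9)), 0)
  expect_identical(phase_error(0.3, periodic_motion_spec(40, 1, 0.1, 0.35)), 0)
  p <- fix_phantom_64
  k0 <- to_kspace(p, 2)
  set.seed(8)
  for (i in 1:20) {
    sp <- periodic_motion_spec(runif(1, 20, 120), runif(1, 0.1, 5),
                               runif(1, 0, pi / 4), runif(1, pi / 10, pi / 8))
    kp <- periodic_motion_kspace(k0, sp)
    expect_lt(max(abs(Mod(kp) - Mod(k0))), 1e-12)
    prot <- which(abs(pe_coordinates(64)) <= sp$ky0)
    expect_identical(kp[, prot], k0[, prot])
  }
  # delta pinned to zero leaves the image untouched
  sp0 <- periodic_motion_spec(20, 1, 0, pi / 9); sp0$delta <- 0
  expect_lt(max(abs(apply_periodic_motion(p, sp0) - p)), 1e-10)
})

test_that("noise injection hits the requested SNR", {
  p <- fix_phantom_320
  S <- mean(Mod(to_kspace(p)))
  u0 <- add_noise(p, noise_spec(0, seed = 1))
  expect_equal(attr(u0, "noise_sd_target"), S, tolerance = 1e-12)
  u20 <- add_noise(p, noise_spec(10, seed = 1))
  expect_equal(attr(u20, "noise_sd_target"), S / 10^(0.5), tolerance = 1e-12)
  for (snr in c(-12, 0, 10)) {
    u <- add_noise(p, noise_spec(snr, seed = snr + 100))
    realized <- 20 * log10(S / attr(u, "noise_sd_realized"))
    expect_lt(abs(realized - snr), 0.2)
  }
  expect_error(add_noise(matrix(0, 32, 32), noise_spec(0)), "zero")
  expect_identical(add_noise(p, noise_spec(0, seed = 5)),
                   add_noise(p, noise_spec(0, seed = 5)))
})

test_that("spec constructors reject out-of-range parameters", {
  expect_error(bias_field_spec(0.05, 30), "strength")
  expect_error(bias_field_spec(0.5, 50), "length_scale")
  expect_error(rigid_motion_spec(0.2, 10), "corrupt_fraction")
  expect_error(rigid_motion_spec(0.5, 30), "n_segments")
  expect_error(periodic_motion_spec(10, 1, 0, 0.35), "delta")
  expect_error(periodic_motion_spec(40, 6, 0, 0.35), "alpha")
  expect_error(periodic_motion_spec(40, 1, 1, 0.35), "beta")
  expect_error(periodic_motion_spec(40, 1, 0, 0.5), "ky0")
  expect_error(noise_spec(-13), "snr_db")
  expect_error(noise_spec(11), "snr_db")
})

test_that("random samples are reproducible, label-balanced, and corrupting", {
  p <- generate_phantom(phantom_spec(32, 32, 4, c(0.1, 1), 0.5, seed = 6))
  s1 <- draw_sample(p, 11)
  expect_identical(s1$corrupted, draw_sample(p, 11)$corrupted)
  expect_identical(dim(s1$corrupted), dim(p))
  n <- 600
  labs <- integer(n)
  changed <- logical(n)
  for (i in seq_len(n)) {
    s <- draw_sample(p, i)
    labs[i] <- s$label
    changed[i] <- max(abs(s$corrupted - s$clean)) > 1e-9
  }
  freq <- tabulate(labs, 4) / n
  se3 <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < se3))
  expect_true(all(changed))
  # pelvic profile draws periodic motion at least once
  kinds <- vapply(1:80, function(i) class(draw_sample(p, i, "pelvic")$params)[1],
                  character(1))
  expect_true("periodic_motion_spec" %in% kinds)
})
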