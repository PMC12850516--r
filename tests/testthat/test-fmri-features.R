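# S-PHOG descriptor: gradient plumbing, magnitude normalization, orientation
# averaging, binning and pyramid structure, invariances, and the smoothing
# noise-robustness advantage over the unsmoothed PHOG baseline; plus the
# seed-deterministic 384-dim volumetric embedding.

test_that("gaussian smoothing preserves constants and realizes the kernel on an impulse", {
  expect_equal(gaussian_smooth(matrix(3, 10, 10), 1), matrix(3, 10, 10))
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  sm <- gaussian_smooth(imp, 1)
  g <- gaussian_kernel_1d(3, 1)          # ceiling(3*sigma) = 3 half-width
  expect_equal(sm[5:11, 5:11], outer(g, g), tolerance = 1e-12)
  set.seed(20)
  img <- matrix(runif(32 * 32), 32)
  # reflect boundaries redistribute mass locally; totals agree to ~boundary order
  expect_lt(abs(sum(gaussian_smooth(img, 1)) - sum(img)) / sum(img), 0.02)
})

test_that("smoothed gradients vanish on constants and track ramps", {
  g0 <- smoothed_gradients(matrix(2, 9, 9), 1)
  expect_equal(g0$Ax, matrix(0, 9, 9))
  expect_equal(g0$Ay, matrix(0, 9, 9))
  ramp <- matrix(rep(1:12, each = 12), 12, 12)     # I(i, j) = j (column index)
  gr <- raw_gradients(ramp)
  expect_equal(gr$Ax[4:9, 4:9], matrix(2, 6, 6))   # centered difference = 2
  expect_equal(gr$Ay[4:9, 4:9], matrix(0, 6, 6))
  # derivative-of-smoothed equals smooth-then-differentiate by linearity
  set.seed(21)
  img <- matrix(rnorm(20 * 20), 20)
  sm <- gaussian_smooth(img, 1.3)
  gs <- smoothed_gradients(img, 1.3)
  gd <- raw_gradients(sm)
  expect_equal(gs$Ax, gd$Ax, tolerance = 1e-12)
  expect_equal(gs$Ay, gd$Ay, tolerance = 1e-12)
})

test_that("normalized magnitude respects its bounds and plug-in cases", {
  z <- normalized_magnitude(matrix(0, 6, 6), matrix(0, 6, 6))
  expect_equal(z, matrix(0, 6, 6))
  # single nonzero gradient pixel: value ~ 1 at that pixel
  Ax <- matrix(0, 9, 9); Ax[5, 5] <- 2
  nm <- normalized_magnitude(Ax, matrix(0, 9, 9), sphog_params(eps = 1e-10))
  expect_equal(nm[5, 5], 1, tolerance = 1e-9)
  # uniform gradient field: interior ~ 1/9 for a 3x3 neighborhood
  u <- normalized_magnitude(matrix(1, 10, 10), matrix(0, 10, 10))
  expect_equal(u[3:8, 3:8], matrix(1 / 9, 6, 6), tolerance = 1e-6)
  set.seed(22)
  r <- normalized_magnitude(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("orientation averaging returns the common angle and flags cancellation", {
  th <- pi / 5
  Ax <- matrix(cos(th), 8, 8); Ay <- matrix(sin(th), 8, 8)
  ori <- smoothed_orientation(Ax, Ay)
  expect_equal(ori[3:6, 3:6], matrix(th, 4, 4), tolerance = 1e-12)
  # balanced orientations (120-degree spacing, period-3 columns) cancel exactly
  angs <- matrix(rep(c(0, 2 * pi / 3, 4 * pi / 3), length.out = 9), 9, 9,
                 byrow = TRUE)
  ori2 <- smoothed_orientation(cos(angs), sin(angs), tol = 1e-12)
  zv <- attr(ori2, "zero_vector")
  expect_true(all(zv[2:8, 2:8]))
  expect_equal(ori2[2:8, 2:8], matrix(0, 7, 7))
  # naive per-pixel oracle
  set.seed(23)
  Ax3 <- matrix(rnorm(100), 10); Ay3 <- matrix(rnorm(100), 10)
  a0 <- atan2(Ay3, Ax3)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    vx <- 0; vy <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- refl(i + di, 10); jj <- refl(j + dj, 10)
      vx <- vx + cos(a0[ii, jj]); vy <- vy + sin(a0[ii, jj])
    }
    oracle[i, j] <- atan2(vy / 9, vx / 9)
  }
  got <- smoothed_orientation(Ax3, Ay3)
  expect_equal(unname(got[seq(100)]), oracle[seq(100)], tolerance = 1e-10)
})

test_that("orientation histogram wraps, localizes and is linear", {
  mag <- matrix(1, 4, 4)
  ori <- matrix(pi / 5, 4, 4)              # 36 degrees -> bin 2 of 9
  h <- orientation_histogram(mag, ori, Z = 9)
  expect_equal(h[2], 16)
  expect_equal(sum(h), 16)
  # unsigned wrap: 190 degrees votes with 10 degrees (bin 1)
  h2 <- orientation_histogram(matrix(1, 2, 2), matrix(190 * pi / 180, 2, 2), Z = 9)
  expect_equal(h2[1], 4)
  h3 <- orientation_histogram(2 * mag, ori, Z = 9)
  expect_equal(h3, 2 * h)
  expect_equal(orientation_histogram(mag, ori,
                                     region = list(rows = 1:2, cols = 1:2), Z = 9)[2], 4)
})

test_that("descriptor lengths, normalization and pyramid consistency hold", {
  ph <- generate_brain_phantom(c(32, 32), lesion = TRUE, seed = 30)
  d01 <- sphog_descriptor(ph)
  expect_length(d01, 45)
  expect_equal(sum(d01), 1, tolerance = 1e-9)
  expect_true(all(d01 >= 0))
  d012 <- sphog_descriptor(ph, sphog_params(levels = 0:2))
  expect_length(d012, 189)
  expect_equal(sum(d012), 1, tolerance = 1e-9)
  # level-0 histogram equals the sum of the level-1 cell histograms
  p <- sphog_params()
  g <- smoothed_gradients(as_mat <- ph$data, p$sigma)
  mag <- normalized_magnitude(g$Ax, g$Ay, p)
  ori <- smoothed_orientation(g$Ax, g$Ay, p)
  h0 <- orientation_histogram(mag, ori, Z = 9)
  cells <- list(1:16, 17:32)
  h1sum <- rep(0, 9)
  for (r in cells) for (cc in cells)
    h1sum <- h1sum + orientation_histogram(mag, ori,
                                           region = list(rows = r, cols = cc), Z = 9)
  expect_equal(h0, h1sum, tolerance = 1e-9)
  expect_error(sphog_descriptor(matrix(0, 7, 7), sphog_params(levels = 0:2)),
               "too small")
  flat <- sphog_descriptor(matrix(0.5, 16, 16))
  expect_true(attr(flat, "degenerate"))
  expect_equal(flat, rep(1 / 45, 45), ignore_attr = TRUE)
})

test_that("descriptor is offset-invariant and scale-stable", {
  ph <- generate_brain_phantom(c(32, 32), lesion = TRUE, seed = 31)
  d <- sphog_descriptor(ph)
  d_off <- sphog_descriptor(ph$data * 1 + 0.2)
  expect_equal(d, d_off, tolerance = 1e-9)
  d_scl <- sphog_descriptor(ph$data * 3)
  expect_equal(d, d_scl, tolerance = 1e-6)
})

test_that("rotating the image by 90 degrees permutes orientation bins", {
  ph <- generate_brain_phantom(c(32, 32), lesion = TRUE, seed = 32)
  p <- sphog_params(levels = 0L, n_bins = 9L)   # single global histogram
  d <- sphog_descriptor(ph$data, p)
  rot <- t(ph$data)[, rev(seq_len(32))]         # 90-degree rotation
  d_rot <- sphog_descriptor(rot, p)
  # orientations shift by 90 degrees = 4.5 bins; compare at coarse 2-bin split
  p2 <- sphog_params(levels = 0L, n_bins = 2L)
  d2 <- sphog_descriptor(ph$data, p2)
  d2_rot <- sphog_descriptor(rot, p2)
  expect_equal(unname(d2[1]), unname(d2_rot[2]), tolerance = 0.05)
  expect_equal(unname(d2[2]), unname(d2_rot[1]), tolerance = 0.05)
  expect_equal(sum(d_rot), 1, tolerance = 1e-9)
})

test_that("smoothing makes the descriptor more noise-stable than raw PHOG", {
  dist_s <- dist_r <- numeric(20)
  for (s in 1:20) {
    ph <- generate_brain_phantom(c(32, 32), lesion = s %% 2 == 0, seed = s)
    pair <- add_noise(ph, noise_spec("gaussian", gaussian_sd = 0.08,
                                     seed = s + 500))
    noisy <- pair$noisy$data
    dist_s[s] <- sum(abs(sphog_descriptor(ph$data) - sphog_descriptor(noisy)))
    dist_r[s] <- sum(abs(phog_descriptor(ph$data) - phog_descriptor(noisy)))
  }
  expect_lt(mean(dist_s), mean(dist_r))
})

test_that("volumetric embedding honours the 384 contract and reacts to lesions", {
  ph <- generate_brain_phantom(c(16, 16), lesion = FALSE, seed = 40)
  e <- deep_embed(ph)
  expect_length(e, 384)
  expect_true(all(is.finite(e)))
  expect_identical(e, deep_embed(ph))
  e2 <- deep_embed(ph, embedder_config(seed = 99))
  expect_false(identical(e, e2))
  ph_l <- generate_brain_phantom(c(16, 16), lesion = TRUE, seed = 40)
  expect_gt(sqrt(sum((deep_embed(ph_l) - e)^2)), 0)
  vol <- generate_brain_phantom(c(12, 12, 8), lesion = TRUE, seed = 41)
  ev <- deep_embed(vol, embedder_config(out_dims = c(20L, 12L)))
  expect_length(ev, 32)
  expect_error(deep_embed(array(0, c(4, 4, 2))), ">= 8")
})
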