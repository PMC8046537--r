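test_that("edge indicator is 1 on constants and matches the formula on a step", {
  g <- edge_indicator(matrix(0.5, 32, 32), sigma = 1.5)
  expect_true(all(g$g == 1))

  # vertical step edge: oracle smooths with an independently coded kernel
  img <- cbind(matrix(0.2, 32, 32), matrix(0.8, 32, 32))
  sigma <- 1.5
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2); k <- k / sum(k)
  sm <- img
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img))) {
      idx <- pmin(pmax(j + (-r:r), 1), ncol(img))    # replicate boundary
      sm[i, j] <- sum(k * img[i, idx])               # 1-D: rows constant
    }
  sm <- sm * 255
  gc <- sm
  for (j in seq_len(ncol(sm))) {
    jm <- max(1, j - 1); jp <- min(ncol(sm), j + 1)
    gc[, j] <- (sm[, jp] - sm[, jm]) / (jp - jm)
  }
  ghat <- max(abs(gc))
  e <- edge_indicator(img, sigma)
  expect_equal(min(e$g), 1 / (1 + ghat^2), tolerance = 1e-8)

  # doubling the intensity scale sharpens the minimum
  e2 <- edge_indicator(img * 2, sigma)
  expect_lt(min(e2$g), min(e$g))
})

test_that("the level set initializes as a signed step on the expanded box", {
  region <- list(bbox = c(21L, 21L, 30L, 30L), area_fraction = 0.04)
  phi <- init_lsf(region, c(50, 50), c0 = 3, margin_px = 5)
  expect_true(all(phi[16:35, 16:35] == -3))
  outside <- matrix(TRUE, 50, 50); outside[16:35, 16:35] <- FALSE
  expect_true(all(phi[outside] == 3))
  # sign changes happen exactly at the rectangle boundary
  flips <- sum(phi[, -1] * phi[, -50] < 0) + sum(phi[-1, ] * phi[-50, ] < 0)
  expect_identical(flips, 2L * 20L + 2L * 20L)

  expect_error(init_lsf(list(bbox = NULL), c(50, 50)), "empty")
  expect_error(init_lsf(list(bbox = c(1L, 1L, 50L, 50L)), c(50, 50)),
               "whole image")
})

test_that("alpha follows the if-then size rule", {
  expect_identical(choose_alpha(list(area_fraction = 0.30)), 5)
  expect_identical(choose_alpha(list(area_fraction = 0.05)), 3)
  expect_identical(choose_alpha(list(area_fraction = 0.15)), 3)  # strict
})

test_that("parameter invariants are enforced", {
  expect_error(drlse_params(mu = 0.05, dt = 8), "mu")
  expect_silent(drlse_params(mu = 0.02, dt = 8))
})

test_that("area evolution is exactly sign-symmetric on a flat indicator", {
  phi0 <- matrix(3, 64, 64)
  phi0[disk_mask(64, r = 12)] <- -3
  g1 <- matrix(1, 64, 64)
  p_in <- drlse_params(alpha = 3, lambda = 0, n_iter = 30, early_stop = FALSE)
  p_out <- drlse_params(alpha = -3, lambda = 0, n_iter = 30, early_stop = FALSE)
  a <- drlse_evolve(phi0, g1, p_in)
  b <- drlse_evolve(-phi0, g1, p_out)
  expect_identical(b$phi, -a$phi)             # exact mirrored evolution
  expect_equal(a$area_trace + b$area_trace, rep(64^2, 30))
})

test_that("non-finite evolution aborts with the iteration index", {
  phi0 <- matrix(3, 32, 32); phi0[16, 16] <- Inf
  expect_error(drlse_evolve(phi0, matrix(1, 32, 32),
                            drlse_params(n_iter = 5)),
               "iteration 1")
})

test_that("mask extraction applies the affine 8-bit map", {
  expect_false(any(extract_mask(matrix(3, 10, 10))))
  expect_true(all(extract_mask(matrix(-3, 10, 10))))

  W <- 100
  phi <- matrix(seq(-3, 3, length.out = W), 40, W, byrow = TRUE)
  m <- extract_mask(phi)
  # hand-solved threshold: phi < 3 * (1 - 2 * 80 / 255)
  cut <- 3 * (1 - 2 * 80 / 255)
  expected_cols <- which(seq(-3, 3, length.out = W) < cut)
  expect_identical(which(m[1, ]), expected_cols)
})

test_that("discrete energy descends after the initialization transient", {
  disk <- disk_mask(100, r = 20)
  img <- matrix(0.9, 100, 100); img[disk] <- 0.2
  phi0 <- init_lsf(list(bbox = hkls:::mask_bbox(disk)), c(100, 100), 3, 10)
  ev <- drlse_evolve(phi0, edge_indicator(img),
                     drlse_params(alpha = 3, n_iter = 150, early_stop = FALSE),
                     track_energy = TRUE)
  e <- ev$energy_trace
  expect_true(all(diff(e[50:length(e)]) <= 1e-6))
  expect_lt(e[length(e)], e[1])
})

test_that("the signed-distance band survives evolution without reinit", {
  rows <- matrix(1:80, 80, 80); cols <- t(rows)
  sdf <- sqrt((rows - 40.5)^2 + (cols - 40.5)^2) - 18
  ev <- drlse_evolve(sdf, matrix(1, 80, 80),
                     drlse_params(mu = 0.02, lambda = 0, alpha = 0,
                                  n_iter = 100, early_stop = FALSE))
  gr <- hkls:::gradient2(ev$phi)
  mag <- sqrt(gr$dr^2 + gr$dc^2)
  band <- abs(ev$phi) < 2
  expect_gte(mean(mag[band] >= 0.7 & mag[band] <= 1.3), 0.95)
})
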