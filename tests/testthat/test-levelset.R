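# Level-set machinery: signed distance, regularized step functions, region
# intensities, energy, evolution.

test_that("signed distance matches closed form and brute force", {
  disc <- raster_disc(16, dims = 53)
  fld <- signed_distance(disc)
  # value at the centre is about -radius (within a voxel)
  expect_lt(abs(fld$phi[27, 27] + 16), 1)
  # |grad phi| ~ 1 away from the zero set, the medial-axis ridge and the
  # grid border (central differences degenerate at all three)
  phi <- fld$phi
  n <- nrow(phi)
  gr <- (phi[c(2:n, n), ] - phi[c(1, 1:(n - 1)), ]) / 2
  gc <- (phi[, c(2:n, n)] - phi[, c(1, 1:(n - 1))]) / 2
  gmag <- sqrt(gr^2 + gc^2)
  interior <- matrix(FALSE, n, n)
  interior[3:(n - 2), 3:(n - 2)] <- TRUE
  away <- abs(phi) > 3 & abs(phi) < 12 & interior
  expect_true(all(abs(gmag[away] - 1) < 0.1))
  # physical spacing scales distances
  fld2 <- signed_distance(disc, spacing_mm = c(2, 2))
  expect_lt(abs(fld2$phi[27, 27] + 32), 2)
  expect_error(signed_distance(matrix(FALSE, 5, 5)), "empty")
  expect_error(signed_distance(matrix(TRUE, 5, 5)), "whole grid")
})

test_that("signed distance agrees with the brute-force oracle on a blob", {
  set.seed(4)
  blob <- matrix(FALSE, 24, 24)
  blob[8:15, 6:12] <- TRUE
  blob[12:19, 11:18] <- TRUE
  fld <- signed_distance(blob)
  dpos <- brute_distance(blob)
  dneg <- brute_distance(!blob)
  expect_lt(max(abs(fld$phi - (dpos - dneg))), 1e-9)
})

test_that("square seeding places the requested seeds with the sign convention", {
  fld <- init_level_set_squares(c(256, 256))
  expect_equal(attr(fld, "n_squares"), 55)
  # negative at seed interiors, positive at the grid corners
  expect_gt(fld$phi[1, 1], 0)
  expect_gt(fld$phi[256, 256], 0)
  expect_true(any(fld$phi < 0))
  one <- init_level_set_squares(c(64, 64), n_squares = 1, square_size = 20)
  expect_lt(one$phi[32, 32], 0)
  expect_gt(one$phi[1, 1], 0)
  # zero crossing sits on the square boundary (20 px square centred between
  # 0-based pixels 21..40, so crossings lie 10 px from its centre 30.5)
  cts <- extract_contour(one)
  expect_length(cts, 1)
  expect_lt(max(abs(apply(abs(cts[[1]]$points - 30.5), 1, max) - 10)), 0.75)
  expect_error(init_level_set_squares(c(16, 16), n_squares = 400), "tile")
})

test_that("regularized Heaviside and Dirac behave as a smoothed step pair", {
  expect_equal(regularized_heaviside(0, 1.5), 0.5)
  expect_gt(regularized_heaviside(1e6, 1.5), 1 - 1e-5)
  expect_lt(regularized_heaviside(-1e6, 1.5), 1e-5)
  phi <- seq(-10, 10, by = 1e-3)
  h <- regularized_heaviside(matrix(phi), 1.5)
  expect_true(all(diff(h) > 0))                      # strictly monotone
  # numerical derivative of H matches the Dirac to 1e-6
  d_num <- diff(h) / 1e-3
  d_ana <- regularized_dirac(matrix(phi[-1] - 5e-4), 1.5)
  expect_lt(max(abs(d_num - d_ana)), 1e-6)
  # Dirac integrates to ~1 along a line crossing the zero set
  expect_lt(abs(sum(regularized_dirac(matrix(phi), 1.5)) * 1e-3 - 1), 0.1)
})

test_that("region intensities reproduce the weighted-mean definitions", {
  # sharp partition of a binary image recovers the two levels
  img <- matrix(0, 16, 16); img[5:10, 5:10] <- 100
  phi <- matrix(1, 16, 16); phi[5:10, 5:10] <- -1
  p <- levelset_params(epsilon = 1e-6)
  expect_lt(abs(region_intensity_inside(img, phi, p) - 100), 1e-3)
  expect_lt(abs(region_intensity_outside(img, phi, p) - 0), 1e-3)
  # constant image: both intensities equal the constant for any field
  cst <- matrix(7, 12, 12)
  set.seed(2); anyphi <- matrix(rnorm(144), 12, 12)
  expect_equal(region_intensity_inside(cst, anyphi, levelset_params()), 7)
  expect_equal(region_intensity_outside(cst, anyphi, levelset_params()), 7)
  # a field with no interior degrades to the global mean (the smoothed
  # indicator weights every pixel equally in its far tail)
  v <- region_intensity_inside(img, matrix(10, 16, 16),
                               levelset_params(epsilon = 1e-9))
  expect_equal(v, mean(img), tolerance = 1e-6)
})

test_that("region means and energy match brute-force summation to 1e-10", {
  set.seed(11)
  for (rep in 1:3) {
    img <- matrix(runif(16 * 16), 16, 16)
    phi <- matrix(rnorm(16 * 16, sd = 3), 16, 16)
    p <- levelset_params(gamma = 0.7, beta_len = 0.4, epsilon = 1.5)
    oracle <- brute_region_energy(img, phi, p$epsilon, p$gamma, p$beta_len)
    expect_lt(abs(region_intensity_inside(img, phi, p) - oracle$i1), 1e-10)
    expect_lt(abs(region_intensity_outside(img, phi, p) - oracle$i2), 1e-10)
    en <- levelset_energy(img, phi, p)
    expect_lt(abs(en$data_in - oracle$data_in), 1e-10)
    expect_lt(abs(en$data_out - oracle$data_out), 1e-10)
    expect_lt(abs(en$area - oracle$area), 1e-10)
    expect_lt(abs(en$length - oracle$length), 1e-10)
    expect_lt(abs(en$total - oracle$total), 1e-10)
  }
})

test_that("evolution recovers phantoms and the energy trace descends", {
  ph <- phantom_slice(12, 40, 0, seed = 3)
  r <- levelset_evolve(ph$image)
  expect_gte(dice(r$mask, ph$mask), 0.98)
  tr <- r$energy
  ok <- tr$total[-1] <= tr$total[-nrow(tr)] * (1 + 1e-6) | tr$reinit[-1]
  expect_true(all(ok))
  # noisy case
  ph2 <- phantom_slice(14, 40, 5, seed = 8)
  r2 <- levelset_evolve(ph2$image)
  expect_gte(dice(r2$mask, ph2$mask), 0.90)
})

test_that("a constant image collapses to an empty mask under an area penalty", {
  r <- levelset_evolve(matrix(5, 48, 48), params = levelset_params(gamma = 0.1))
  expect_equal(sum(r$mask), 0)
})

test_that("constant-kernel evolution equals the classical two-phase model", {
  ph <- phantom_slice(16, 40, 4, seed = 21, dims = c(32, 32))
  f <- ph$image
  f <- (f - min(f)) / (max(f) - min(f))
  phi0 <- init_level_set_squares(c(32, 32))$phi
  p <- levelset_params(reinit_every = 0, mask_stable = 0,
                       rel_tol = 1e-300, window = 1000)
  for (iters in c(1, 3, 7, 12)) {
    pk <- p; pk$max_iter <- iters
    res <- levelset_evolve(f, phi0 = phi0, params = pk)
    ref <- classical_two_phase(f, phi0, p, iters)
    expect_lt(max(abs(res$phi - ref)), 1e-8)
  }
})

test_that("segmentation is equivariant under whole-voxel translation", {
  spec0 <- phantom_spec(12, 40, slab_shape = c(64, 64, 1), noise_sigma = 0,
                        nodule_center = c(31.5, 31.5, 0))
  spec1 <- phantom_spec(12, 40, slab_shape = c(64, 64, 1), noise_sigma = 0,
                        nodule_center = c(37.5, 26.5, 0))
  r0 <- levelset_evolve(generate_phantom(spec0, seed = 1)$volume$intensities[, , 1])
  r1 <- levelset_evolve(generate_phantom(spec1, seed = 1)$volume$intensities[, , 1])
  # shift r0's mask by (+6, -5) and compare
  shifted <- matrix(FALSE, 64, 64)
  idx <- which(r0$mask, arr.ind = TRUE)
  idx[, 1] <- idx[, 1] + 6; idx[, 2] <- idx[, 2] - 5
  shifted[idx] <- TRUE
  expect_identical(shifted, r1$mask)
})

test_that("localized kernel intensities vary in space and stay exact on fields", {
  img <- matrix(0, 24, 24)
  img[4:9, 4:9] <- 30      # bright blob top-left
  img[16:21, 16:21] <- 60  # brighter blob bottom-right
  phi <- matrix(5, 24, 24)
  phi[4:9, 4:9] <- -2
  phi[16:21, 16:21] <- -2
  p <- levelset_params(kernel_sigma = 3, epsilon = 0.5)
  i1 <- region_intensity_inside(img, phi, p)
  expect_true(is.matrix(i1))
  # near each blob the local inside mean tracks that blob's level
  expect_gt(i1[18, 18], i1[6, 6])
  # and matches a direct blur-based evaluation
  hin <- regularized_heaviside(-phi, p$epsilon)
  ref <- gaussian_blur(img * hin, 3) / gaussian_blur(hin, 3)
  expect_lt(max(abs(i1 - ref)), 1e-10)
})

test_that("volume segmentation stacks slices and keeps the nodule component", {
  spec <- phantom_spec(30, 45, slab_shape = c(64, 64, 8),
                       voxel_spacing_mm = 2.5, noise_sigma = 45 / 8)
  ph <- generate_phantom(spec, seed = 13)
  sv <- segment_volume(ph$volume)
  expect_gte(dice(sv$mask, ph$truth$mask), 0.90)
  expect_length(sv$slices, 8)
})
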