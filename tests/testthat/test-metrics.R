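# Nodule measurement: counts, diameters, roundness, solidity type.

test_that("voxel count is exact", {
  expect_equal(voxel_count(array(FALSE, c(4, 4, 4))), 0)
  expect_equal(voxel_count(array(TRUE, c(4, 4, 4))), 64)
  set.seed(1)
  m <- array(runif(6 * 5 * 4) > 0.5, c(6, 5, 4))
  n <- 0
  for (i in 1:6) for (j in 1:5) for (k in 1:4) n <- n + (m[i, j, k] == 1)
  expect_equal(voxel_count(m), n)
})

test_that("equivalent diameter inverts the disc/sphere formulas", {
  disc <- raster_disc(5, dims = 21)
  expect_lt(abs(equivalent_diameter(disc, 1) - 10), 0.3)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(equivalent_diameter(one, 0.5), (6 / pi)^(1 / 3) * 0.5)
  # counting oracle on a random blob
  set.seed(2)
  blob <- array(runif(5 * 5 * 5) > 0.4, c(5, 5, 5))
  v <- sum(blob) * 1.2^3
  expect_lt(abs(equivalent_diameter(blob, 1.2) - (6 * v / pi)^(1 / 3)), 1e-9)
  expect_error(equivalent_diameter(matrix(FALSE, 3, 3)), "empty")
})

test_that("equivalent diameter is invariant to translation and rotation", {
  m <- matrix(FALSE, 30, 30); m[5:12, 8:18] <- TRUE
  d0 <- equivalent_diameter(m, 1)
  shifted <- matrix(FALSE, 30, 30); shifted[15:22, 10:20] <- TRUE
  expect_equal(equivalent_diameter(shifted, 1), d0)
  expect_equal(equivalent_diameter(t(m), 1), d0)  # 90 degree rotation
})

test_that("roundness is ~1 for discs, pi/4 for squares, small for bars", {
  expect_gte(roundness(raster_disc(25, dims = 81)), 0.95)
  sq <- matrix(FALSE, 101, 101); sq[31:71, 31:71] <- TRUE
  expect_lt(abs(roundness(sq) - pi / 4), 0.05)
  bar <- matrix(FALSE, 30, 10); bar[5:24, 5] <- TRUE   # 1 x 20 bar
  expect_lt(roundness(bar), 0.3)
  expect_error(roundness(matrix(FALSE, 4, 4)), "empty")
})

test_that("roundness decreases with ellipse eccentricity at fixed area", {
  vals <- vapply(seq(1, 2.2, length.out = 6), function(s) {
    roundness(raster_ellipse(30 * s, 30 / s))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(max(vals), 1.02)   # never exceeds 1 beyond rasterization slack
})

test_that("multi-component masks are refused with guidance", {
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE
  two[14:17, 14:17] <- TRUE
  expect_error(roundness(two), "separately")
})

test_that("solidity typing round-trips the phantom conventions", {
  mk <- function(cls) generate_phantom(
    phantom_spec(16, 40, slab_shape = c(48, 48, 1), noise_sigma = 0,
                 nodule_class = cls), seed = 1)
  for (cls in c("solid", "semisolid", "nonsolid")) {
    ph <- mk(cls)
    got <- classify_nodule_type(ph$truth$mask, ph$volume$intensities,
                                background_estimate = 100,
                                reference_contrast = 40)
    expect_identical(got, cls)
  }
  # a contrast exactly at a threshold goes to the upper class
  img <- matrix(100, 20, 20); m <- matrix(FALSE, 20, 20)
  m[8:12, 8:12] <- TRUE
  img[m] <- 100 + 0.75 * 40
  expect_identical(
    classify_nodule_type(m, img, 100, reference_contrast = 40), "solid")
  img[m] <- 100 + 0.40 * 40
  expect_identical(
    classify_nodule_type(m, img, 100, reference_contrast = 40), "semisolid")
  expect_error(classify_nodule_type(m, img, 100, reference_contrast = 0),
               "positive")
})

test_that("measurement bundle round-trips phantom diameters", {
  for (d in c(12, 20, 30)) {
    spec <- phantom_spec(d, 40, slab_shape = c(64, 64, 8),
                         voxel_spacing_mm = 1, noise_sigma = 0)
    ph <- generate_phantom(spec, seed = 1)
    meas <- measure_nodule(ph$truth$mask, spacing_mm = 1,
                           image = ph$volume$intensities,
                           background_estimate = 100,
                           reference_contrast = 40)
    # measured in-plane diameter within one voxel diagonal of truth
    expect_lt(abs(meas$staging_diameter_mm - d), sqrt(2))
    expect_identical(meas$nodule_type, "solid")
    expect_gt(meas$roundness, 0.9)
  }
  tab <- measurements_table(list(
    measure_nodule(raster_disc(6, 21), spacing_mm = 2)))
  expect_named(tab, c("id", "diameter_mm", "voxels", "roundness", "type"))
})
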