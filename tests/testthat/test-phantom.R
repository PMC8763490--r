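# Synthetic phantom generator.

test_that("zero-noise phantom is exact: mask volume and contrast", {
  spec <- phantom_spec(10, 40, slab_shape = c(64, 64, 16),
                       voxel_spacing_mm = 1, noise_sigma = 0)
  ph <- generate_phantom(spec, seed = 1)
  img <- ph$volume$intensities
  expect_equal(max(img) - spec$background_intensity, 40)
  # voxel count approximates the sphere volume (4/3 pi r^3, r = 5 mm)
  expect_lt(abs(sum(ph$truth$mask) - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3),
            0.15)
  # image equals background + contrast * indicator exactly
  expect_equal(img, spec$background_intensity + 40 * (ph$truth$mask + 0))
})

test_that("same spec and seed give bit-identical phantoms", {
  spec <- phantom_spec(12, 30, slab_shape = c(32, 32, 4), noise_sigma = 4)
  a <- generate_phantom(spec, seed = 77)
  b <- generate_phantom(spec, seed = 77)
  expect_identical(a$volume$intensities, b$volume$intensities)
  c <- generate_phantom(spec, seed = 78)
  expect_false(identical(a$volume$intensities, c$volume$intensities))
})

test_that("phantoms that do not fit the slab are rejected", {
  expect_error(phantom_spec(100, 40, slab_shape = c(32, 32, 8),
                            voxel_spacing_mm = 1), "fit")
  expect_error(phantom_spec(10, 40, noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(0, 40), "diameter")
})

test_that("solidity classes realize the documented contrast profiles", {
  mk <- function(cls) generate_phantom(
    phantom_spec(16, 40, slab_shape = c(48, 48, 1), noise_sigma = 0,
                 nodule_class = cls), seed = 1)
  solid <- mk("solid"); semi <- mk("semisolid"); non <- mk("nonsolid")
  bg <- 100
  expect_equal(max(solid$volume$intensities) - bg, 40)
  # semisolid: full-contrast core plus half-contrast rim
  vals <- unique(round(semi$volume$intensities[semi$truth$mask] - bg, 9))
  expect_setequal(vals, c(40, 20))
  # nonsolid: uniform sub-threshold contrast
  expect_equal(unique(non$volume$intensities[non$truth$mask] - bg),
               0.35 * 40)
  # the ground-truth mask is the full indicator for every class
  expect_identical(solid$truth$mask, semi$truth$mask)
  expect_identical(solid$truth$mask, non$truth$mask)
})

test_that("sampled specs respect the stated intervals", {
  sp <- sample_spec(seed = 3, diameter_range_mm = c(4, 7),
                    contrast_range = c(20, 23))
  expect_gte(sp$nodule_diameter_mm, 4); expect_lte(sp$nodule_diameter_mm, 7)
  expect_gte(sp$contrast, 20); expect_lte(sp$contrast, 23)
  # degenerate interval pins the value
  expect_equal(sample_spec(seed = 1,
                           diameter_range_mm = c(5, 5))$nodule_diameter_mm, 5)
  expect_error(sample_spec(seed = 1, diameter_range_mm = c(7, 4)), "interval")
  # exhaustive sampling stays within bounds
  ds <- replicate(500, {
    s <- sample_spec(diameter_range_mm = c(8, 12), contrast_range = c(27, 35))
    c(s$nodule_diameter_mm, s$contrast)
  })
  expect_true(all(ds[1, ] >= 8 & ds[1, ] <= 12))
  expect_true(all(ds[2, ] >= 27 & ds[2, ] <= 35))
})

test_that("dataset generation is stratified, labelled and reproducible", {
  items <- generate_dataset(3, seed = 9)
  expect_length(items, 27)
  expect_equal(as.integer(table(vapply(items, `[[`, "", "class"))),
               rep(3L, 9))
  # stage label always equals the staging map applied to the descriptor
  for (it in items) {
    expect_identical(it$label, stage_group(it$truth$tnm))
  }
  again <- generate_dataset(3, seed = 9)
  expect_identical(vapply(items, `[[`, "", "label"),
                   vapply(again, `[[`, "", "label"))
  expect_identical(items[[5]]$volume$intensities,
                   again[[5]]$volume$intensities)
})

test_that("a size bin crossing a TU boundary is rejected", {
  bad <- list(x = list(diameter_cm = c(2.5, 3.5), ln = "LN0", dm = "DM0"))
  expect_error(generate_dataset(2, class_map = bad, seed = 1), "straddles")
  ok <- list(`1A3` = list(diameter_cm = c(2, 3), ln = "LN0", dm = "DM0"))
  items <- generate_dataset(4, class_map = ok, seed = 1)
  expect_true(all(vapply(items, `[[`, "", "label") == "1A3"))
})
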