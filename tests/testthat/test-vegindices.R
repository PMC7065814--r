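# Vegetation-index algebra and the 14-variable table.

test_that("a worked four-band sample evaluates to the known index values", {
  idx <- compute_indices(data.frame(r_blue = 0.05, r_green = 0.08,
                                    r_red = 0.10, r_nir = 0.50))
  expect_equal(idx$NDVI, 0.66667, tolerance = 1e-4)
  expect_equal(idx$SAVI, 0.54545, tolerance = 1e-4)
  expect_equal(idx$OSAVI, 0.61053, tolerance = 1e-4)
  expect_equal(idx$NRI, -0.11111, tolerance = 1e-4)
  expect_equal(idx$GNDVI, 0.72414, tolerance = 1e-4)
  expect_equal(idx$SIPI, 0.81818, tolerance = 1e-4)
  expect_equal(idx$PSRI, 0.10, tolerance = 1e-12)
  expect_equal(idx$EVI, 0.66667, tolerance = 1e-4)
  expect_equal(idx$DVI, 0.40, tolerance = 1e-12)
  expect_equal(idx$RVI, 5.0, tolerance = 1e-12)
})

test_that("equal red and NIR reflectance zeroes the red-NIR contrasts", {
  idx <- compute_indices(data.frame(r_blue = 0.05, r_green = 0.08,
                                    r_red = 0.3, r_nir = 0.3))
  expect_equal(idx$NDVI, 0)
  expect_equal(idx$SAVI, 0)
  expect_equal(idx$OSAVI, 0)
  expect_equal(idx$EVI, 0)
  expect_equal(idx$DVI, 0)
  expect_equal(idx$RVI, 1)
})

test_that("zero denominators flag the sample instead of emitting infinities", {
  idx <- compute_indices(data.frame(r_blue = 0.05, r_green = 0.08,
                                    r_red = 0, r_nir = 0.5))
  expect_true(attr(idx, "flagged"))
  expect_true(all(is.na(idx)))
})

test_that("the EVI variants differ exactly by their third-band term", {
  s <- data.frame(r_blue = 0.04, r_green = 0.09, r_red = 0.1, r_nir = 0.5)
  green <- compute_indices(s, evi_variant = "green")$EVI
  blue <- compute_indices(s, evi_variant = "blue")$EVI
  expect_equal(green, 2.5 * 0.4 / (0.5 + 0.6 - 7.5 * 0.09 + 1))
  expect_equal(blue, 2.5 * 0.4 / (0.5 + 0.6 - 7.5 * 0.04 + 1))
})

test_that("normalized-difference indices stay inside (-1, 1) and identities hold", {
  s <- generate_samples(scene_params(n_samples = 500, seed = 4))
  idx <- compute_indices(s)
  for (v in c("NDVI", "GNDVI", "SIPI", "NRI")) {
    expect_true(all(idx[[v]] > -1 & idx[[v]] < 1))
  }
  expect_equal(idx$DVI, s$r_nir - s$r_red, tolerance = 1e-15)
  expect_equal(idx$RVI * s$r_red, s$r_nir, tolerance = 1e-12)
  expect_true(all(sign(idx$SAVI) == sign(idx$NDVI)))
  expect_true(all(sign(idx$OSAVI) == sign(idx$NDVI)))
})

test_that("the variable table has the canonical 14 columns plus response", {
  s <- generate_samples(scene_params(n_samples = 3, seed = 1))
  vt <- build_variable_table(s)
  expect_equal(nrow(vt), 3)
  expect_identical(names(vt), c(variable_names(), "gpc"))
  # recompute-from-columns oracle
  expect_equal(vt$NDVI, (vt$R_nir - vt$R_red) / (vt$R_nir + vt$R_red),
               tolerance = 1e-15)
})

test_that("flagged samples are excluded from the table with a logged count", {
  s <- generate_samples(scene_params(n_samples = 4, seed = 1))
  s$r_red[2] <- 0
  expect_message(vt <- build_variable_table(s), "excluded 1")
  expect_equal(nrow(vt), 3)
  expect_false(anyNA(vt))
})

test_that("grid index computation agrees cell-wise with the scalar path", {
  set.seed(33)
  bands <- list(
    r_blue = matrix(runif(32 * 32, 0.02, 0.2), 32),
    r_green = matrix(runif(32 * 32, 0.02, 0.3), 32),
    r_red = matrix(runif(32 * 32, 0.02, 0.3), 32),
    r_nir = matrix(runif(32 * 32, 0.2, 0.7), 32)
  )
  grids <- compute_index_grids(bands)
  flat <- data.frame(r_blue = as.vector(bands$r_blue),
                     r_green = as.vector(bands$r_green),
                     r_red = as.vector(bands$r_red),
                     r_nir = as.vector(bands$r_nir))
  idx <- compute_indices(flat)
  for (v in setdiff(variable_names(), c("R_blue", "R_green", "R_red", "R_nir"))) {
    expect_equal(as.vector(grids[[v]]), idx[[v]], tolerance = 1e-12)
  }
})

test_that("masked cells are invalid in every index grid", {
  bands <- lapply(c(0.05, 0.08, 0.1, 0.5), function(v) matrix(v, 4, 4))
  names(bands) <- c("r_blue", "r_green", "r_red", "r_nir")
  mask <- matrix(TRUE, 4, 4); mask[2, 3] <- FALSE
  grids <- compute_index_grids(bands, mask)
  for (g in grids) {
    expect_true(is.na(g[2, 3]))
    expect_equal(sum(is.na(g)), 1)
  }
  # uniform bands give uniform unmasked values equal to the scalar result
  scalar <- compute_indices(data.frame(r_blue = 0.05, r_green = 0.08,
                                       r_red = 0.1, r_nir = 0.5))
  expect_equal(unique(grids$NDVI[mask]), scalar$NDVI)
})

test_that("incongruent grid shapes are an error", {
  bands <- list(r_blue = matrix(0.1, 2, 2), r_green = matrix(0.1, 2, 2),
                r_red = matrix(0.1, 2, 2), r_nir = matrix(0.4, 3, 2))
  expect_error(compute_index_grids(bands), "congruent")
})
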