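test_that("normalisation divides by the fixed 1000-count scale and clips saturation", {
  expect_true(all(normalize_eem(tiny_grid(value = 1000))$intensities == 1))
  expect_true(all(normalize_eem(tiny_grid(value = 0))$intensities == 0))
  g <- tiny_grid(value = 250)
  g$intensities[4, 7] <- 1500  # saturated counts are accepted and clipped
  n <- normalize_eem(g)
  expect_equal(n$intensities[4, 7], 1.0)
  expect_equal(n$intensities[1, 1], 0.25)
})

test_that("constant 1000-count grid maps to an all-255 three-channel image", {
  inp <- to_model_input(tiny_grid(value = 1000))
  expect_equal(dim(inp$pixels), c(160L, 160L, 3L))
  expect_true(all(inp$pixels == 255L))
  expect_true(all(to_model_input(tiny_grid(value = 0))$pixels == 0L))
})

test_that("the three channels are always identical", {
  inp <- to_model_input(tiny_grid(seed = 8))
  expect_equal(max(abs(inp$pixels[, , 1] - inp$pixels[, , 2])), 0L)
  expect_equal(max(abs(inp$pixels[, , 1] - inp$pixels[, , 3])), 0L)
})

test_that("preprocessing is monotone: pointwise-larger grids never give smaller images", {
  for (seed in 1:3) {
    base <- tiny_grid(seed = seed)
    bigger <- base
    bump <- withr::with_seed(seed + 100,
                             matrix(stats::runif(35 * 251, 0, 200), 35, 251))
    bigger$intensities <- clamp_vals <- pmin(base$intensities + bump, 1000)
    a <- to_model_input(base)$pixels
    b <- to_model_input(bigger)$pixels
    expect_true(all(b >= a))
  }
})

test_that("quantisation error is bounded by the 8-bit step", {
  g <- tiny_grid(seed = 5)
  inp <- to_model_input(g)
  ## reconstruct the pre-quantisation resized image independently
  norm <- pmin(g$intensities / 1000, 1)
  w_r <- eemda:::resample_weights(35, 160)
  w_c <- eemda:::resample_weights(251, 160)
  resized <- w_r %*% norm %*% t(w_c)
  expect_lte(max(abs(inp$pixels[, , 1] / 255 - resized)), 0.5 / 255 + 1e-12)
})

test_that("excitation nm-per-pixel reproduces 2.2 under the step-count convention", {
  inp <- to_model_input(tiny_grid())
  expect_equal(round(nm_per_pixel(inp, "excitation", "step"), 1), 2.2)
  expect_equal(nm_per_pixel(inp, "excitation", "step"), 350 / 160)
  expect_equal(nm_per_pixel(inp, "excitation", "span"), 340 / 160)
  ## corner alignment of the wavelength maps
  expect_equal(inp$ex_wavelengths[c(1, 160)], c(300, 640))
  expect_equal(inp$em_wavelengths[c(1, 160)], c(300, 800))
  expect_true(all(diff(inp$ex_wavelengths) > 0))
})

test_that("Rayleigh removal zeroes or interpolates exactly the ridge cells", {
  ## grid nonzero only on the ridge -> zero mode empties it
  p <- synthetic_oil_params(
    fluorophores = list(), rayleigh_amplitude = 500,
    rayleigh_half_width = 10, noise_sd = 0, label_noise_sd = 0)
  g <- simulate_oil(p, 1, seed = 1)[[1]]$grid
  gz <- remove_rayleigh(g, "zero", half_width = 10)
  expect_true(all(gz$intensities == 0))

  ## off-ridge cells are untouched in both modes
  g2 <- tiny_grid(seed = 6)
  off <- abs(outer(g2$excitation, g2$emission, `-`)) > 10
  for (mode in c("zero", "interpolate")) {
    out <- remove_rayleigh(g2, mode, half_width = 10)
    expect_identical(out$intensities[off], g2$intensities[off])
  }

  ## linear-in-emission grids are fixed points of interpolation wherever
  ## the ridge has unmasked neighbours on both sides (away from the
  ## emission-axis edge, where constant continuation applies)
  lin <- tiny_grid(value = 0)
  lin$intensities <- matrix(rep(seq(100, 600, length.out = 251), each = 35),
                            35, 251)
  out <- remove_rayleigh(lin, "interpolate", half_width = 10)
  interior <- which(lin$excitation - 10 > min(lin$emission))
  expect_equal(out$intensities[interior, ], lin$intensities[interior, ],
               tolerance = 1e-12)
})

test_that("resampling preserves constants and exact linear ramps", {
  w <- eemda:::resample_weights(35, 160)
  expect_equal(rowSums(w), rep(1, 160))  # constants preserved
  ramp <- matrix(rep(seq(0, 1, length.out = 251), each = 35), 35, 251)
  out <- eemda:::resample_bilinear(ramp, 160, 160)
  expect_equal(out[1, ], seq(0, 1, length.out = 160), tolerance = 1e-12)
})

test_that("model inputs export to PNG and CSV+JSON sidecar", {
  inp <- to_model_input(tiny_grid(seed = 9))
  png_path <- withr::local_tempfile(fileext = ".png")
  write_model_input_png(inp, png_path)
  expect_true(file.size(png_path) > 0)
  prefix <- withr::local_tempfile()
  paths <- write_model_input(inp, prefix)
  arr <- as.matrix(utils::read.csv(paths[1], header = FALSE))
  expect_equal(dim(arr), c(160L, 160L))
  expect_equal(unname(arr), unname(inp$pixels[, , 1]), ignore_attr = TRUE)
  side <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(side$ex_wavelengths, inp$ex_wavelengths)
})
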