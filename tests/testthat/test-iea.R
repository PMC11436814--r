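test_that("occlusion sweep matches the independent brute-force loop entry for entry", {
  inp <- to_model_input(quiet_dataset(1, 1)$records[[1]]$grid)
  ## constant mock: every entry exactly 0
  hm_const <- occlusion_sweep(constant_mock(0.4), inp, true_value = 0.3)
  expect_equal(dim(hm_const$grid), c(32L, 32L))
  expect_true(all(hm_const$grid == 0))
  expect_equal(hm_const$baseline_ae, 0.1)

  ## linear mock reading one 5x5 region
  rows <- 41:45; cols <- 86:90
  mock <- region_mean_mock(rows, cols)
  hm <- occlusion_sweep(mock, inp, true_value = 0)
  bf <- brute_force_sweep(mock, inp, true_value = 0)
  expect_equal(hm$grid, bf, tolerance = 1e-12)

  ## exactly one nonzero entry at the mapped region, with closed-form value:
  ## occluding the watched region drops the prediction from m to 0, so the
  ## AE change is -m (true value 0, fill 0)
  m_val <- mean(inp$pixels[rows, cols, 1] / 255)
  nz <- which(hm$grid != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1L)
  expect_equal(unname(nz[1, ]), c(9L, 18L))  # region row 9, col 18
  expect_equal(hm$grid[9, 18], -m_val, tolerance = 1e-12)
})

test_that("sweep leaves the input and a trained model bit-identical", {
  ds <- quiet_dataset(2, 2)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  fit <- train_two_phase(inputs, dataset_targets(ds, "K268"),
                         config_I = standin_phase_config("I", epochs = 2),
                         config_II = standin_phase_config("II", epochs = 1),
                         seed = 4)
  model <- fit$model
  before_model <- serialize(model, NULL)
  before_input <- serialize(inputs[[1]], NULL)
  hm <- occlusion_sweep(model, inputs[[1]], true_value = 0.2)
  invisible(band_importance(hm, "emission"))
  invisible(smooth_heatmap(hm))
  invisible(eliminate_band(inputs[[1]], "R2"))
  invisible(evaluate_elimination(model, inputs[[1]], "R1", true_value = 0.2))
  expect_identical(serialize(model, NULL), before_model)
  expect_identical(serialize(inputs[[1]], NULL), before_input)
})

test_that("band-importance strip sums conserve total heatmap mass on both axes", {
  inp <- to_model_input(quiet_dataset(1, 1, seed = 21)$records[[1]]$grid)
  mock <- function(input) mean(input$pixels[, , 1]^1.3) / 1e4
  hm <- occlusion_sweep(mock, inp, true_value = 0.01)
  for (ax in c("emission", "excitation")) {
    bi <- band_importance(hm, ax)
    expect_length(bi$strip_sums, 32L)
    expect_equal(sum(bi$strip_sums), sum(hm$grid), tolerance = 1e-12)
    expect_equal(nrow(bi$wavelength_ranges), 32L)
  }
  ## uniform heatmap: every strip equal, total = v * n_regions
  hu <- hm; hu$grid <- matrix(0.25, 32, 32)
  bi <- band_importance(hu, "emission")
  expect_true(all(abs(bi$strip_sums - bi$strip_sums[1]) < 1e-12))
  expect_equal(sum(bi$strip_sums), 0.25 * 1024)
  ## single-hot heatmap: one nonzero strip per axis at the mapped interval
  hs <- hm; hs$grid <- matrix(0, 32, 32); hs$grid[4, 11] <- 1
  expect_equal(which(band_importance(hs, "excitation")$strip_sums != 0), 4L)
  expect_equal(which(band_importance(hs, "emission")$strip_sums != 0), 11L)
  ## positive-part option
  hn <- hm; hn$grid <- matrix(c(-1, 2), 32, 32)
  expect_equal(sum(band_importance(hn, "emission", positive_part = TRUE)$strip_sums),
               sum(pmax(hn$grid, 0)))
})

test_that("averaging heatmaps obeys identity, k-copy and cancellation laws", {
  inp <- to_model_input(quiet_dataset(1, 1, seed = 31)$records[[1]]$grid)
  hm <- occlusion_sweep(region_mean_mock(11:15, 51:55), inp, true_value = 0.1)
  expect_equal(average_heatmaps(list(hm))$grid, hm$grid)
  expect_equal(average_heatmaps(rep(list(hm), 4))$grid, hm$grid)
  neg <- hm; neg$grid <- -hm$grid
  expect_true(all(average_heatmaps(list(hm, neg))$grid == 0))
  ## geometry mismatch rejected
  other <- occlusion_sweep(constant_mock(), inp, 0.1, region_size = 10,
                           stride = 10)
  expect_error(average_heatmaps(list(hm, other)), "geometry")
})

test_that("smoothing preserves constants and conserves interior mass", {
  inp <- to_model_input(quiet_dataset(1, 1, seed = 41)$records[[1]]$grid)
  hm <- occlusion_sweep(constant_mock(), inp, true_value = 0)
  ## all-zero heatmap -> all-zero smoothed map
  expect_true(all(smooth_heatmap(hm)$smoothed == 0))
  ## constant heatmap -> same constant everywhere
  hc <- hm; hc$grid <- matrix(0.7, 32, 32)
  expect_equal(smooth_heatmap(hc)$smoothed,
               matrix(0.7, 160, 160), tolerance = 1e-9)
  ## single central region: mass conserved (kernel support away from edges)
  h1 <- hm; h1$grid <- matrix(0, 32, 32); h1$grid[16, 16] <- 3
  sm <- smooth_heatmap(h1)
  expect_equal(sum(sm$smoothed), sum(sm$pixel_map), tolerance = 1e-6)
  expect_gt(length(smooth_heatmap(h1)$contours), 0)
})

test_that("band elimination maps nm rectangles to pixels and scores AE changes", {
  inp <- to_model_input(quiet_dataset(1, 1, seed = 51)$records[[1]]$grid)
  ## full-range band with fill 0 blanks the whole image
  full <- eliminate_band(inp, list(ex = c(300, 640), em = c(300, 800)), 0)
  expect_true(all(full$pixels == 0L))
  ## constant mock: AE change is 0 for any elimination
  expect_equal(evaluate_elimination(constant_mock(0.3), inp,
                                    list(ex = c(300, 640), em = c(300, 800)),
                                    true_value = 0.1), 0)
  ## eliminating a band with no signal leaves a localised linear mock alone
  mock <- region_mean_mock(1:10, 1:10)  # watches ex 300-319, em 300-328 nm
  expect_equal(evaluate_elimination(mock, inp, list(ex = c(600, 640),
                                                    em = c(700, 800)),
                                    true_value = 0.5), 0)
  ## eliminating the watched band changes the prediction
  expect_gt(abs(evaluate_elimination(mock, inp, list(ex = c(300, 320),
                                                     em = c(300, 330)),
                                     true_value = mock(inp))), 0)
  ## empty rectangle errors
  expect_error(eliminate_band(inp, list(ex = c(641, 680), em = c(300, 400))),
               "empty|outside")
})

test_that("heatmap export table and mass-fraction accounting are consistent", {
  inp <- to_model_input(quiet_dataset(1, 1, seed = 61)$records[[1]]$grid)
  mock <- region_mean_mock(21:25, 21:25)
  ## truth equals the intact prediction, so occluding the watched region
  ## produces a positive AE increase
  hm <- occlusion_sweep(mock, inp, true_value = mock(inp))
  df <- as_heatmap_df(hm)
  expect_equal(nrow(df), 1024L)
  expect_equal(sum(df$d_ae), sum(hm$grid))
  ## raster order: first row of the table is the top-left region
  expect_equal(df$region_row[1:33], c(rep(1L, 32), 2L))
  mask <- ground_truth_band_mask("R2")
  mf <- heatmap_mass_fraction(hm, mask)
  expect_gte(mf$mass_fraction, 0); expect_lte(mf$mass_fraction, 1)
  expect_equal(mf$area_fraction, mean(mask[seq(3, 158, by = 5), seq(3, 158, by = 5)]))
})
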