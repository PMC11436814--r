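## shared fixtures, all generated in code

## a small valid grid with deterministic values
tiny_grid <- function(oil = "oilA", stage = 0L, value = NULL, seed = 1) {
  ex <- eem_excitation_axis()
  em <- eem_emission_axis()
  m <- if (is.null(value)) {
    withr::with_seed(seed, matrix(stats::runif(35 * 251, 0, 1000), 35, 251))
  } else {
    matrix(value, 35, 251)
  }
  eem_grid(m, ex, em, oil_id = oil, stage_index = stage)
}

## quiet dataset for structural tests
quiet_dataset <- function(n_oils = 2, n_stages = 3, seed = 11, ...) {
  simulate_dataset(n_oils = n_oils, n_stages = n_stages, seed = seed, ...)
}

## mock "models" for IEA tests: plain functions model_input -> scalar
constant_mock <- function(value = 0.5) function(input) value

## mean pixel value (channel 1, [0,1] scale) inside a pixel rectangle
region_mean_mock <- function(rows, cols) {
  function(input) mean(input$pixels[rows, cols, 1L] / 255)
}

## independent brute-force occlusion loop (naive re-allocation per region)
brute_force_sweep <- function(model_fn, input, true_value, region_size = 5,
                              stride = 5, fill_value = 0) {
  side <- dim(input$pixels)[1L]
  n_pos <- floor((side - region_size) / stride) + 1L
  base_ae <- abs(model_fn(input) - true_value)
  out <- matrix(NA_real_, n_pos, n_pos)
  for (i in seq_len(n_pos)) {
    for (j in seq_len(n_pos)) {
      occ <- input
      r <- (i - 1L) * stride + 1L
      cl <- (j - 1L) * stride + 1L
      occ$pixels[r:(r + region_size - 1L),
                 cl:(cl + region_size - 1L), ] <- as.integer(fill_value)
      out[i, j] <- abs(model_fn(occ) - true_value) - base_ae
    }
  }
  out
}
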