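## Information elimination algorithm (IEA): occlude small spectral regions
## of a model input, record the change in absolute prediction error, and
## aggregate the resulting heatmap into excitation/emission band
## importances. The model is only ever evaluated, never retrained, and
## neither the model weights nor the intact input are modified.

as_predictor <- function(model) {
  if (inherits(model, "eem_model"))
    function(inputs) predict(model, inputs)
  else if (is.function(model))
    function(inputs) vapply(inputs, model, numeric(1))
  else stopf("model must be an eem_model or a function(model_input) -> scalar")
}

occlude_pixels <- function(input, rows, cols, fill_value) {
  input$pixels[rows, cols, ] <- as.integer(fill_value)
  input
}

#' Occlusion sweep over a model input
#'
#' Slides a `region_size x region_size` occlusion window over the image in
#' raster order (top-left corner first, then rightwards, then the next row
#' of regions), each time setting the region to `fill_value` in all three
#' channels and recording the change in absolute prediction error relative
#' to the intact input. With the defaults (5 px regions, stride 5, 160 px
#' images) this is a 32 x 32 grid of non-overlapping regions, i.e. 1024
#' model evaluations beyond the baseline.
#'
#' @param model an `eem_model` or a function `model_input -> scalar`.
#' @param input a `model_input` (never mutated).
#' @param true_value the measured indicator value for this input.
#' @param region_size occluded square side in pixels.
#' @param stride step between region corners in pixels.
#' @param fill_value replacement pixel value on the 8-bit scale (default 0,
#'   post-quantisation black -- the same convention used to blank the
#'   Rayleigh ridge).
#' @param batch number of occluded copies scored per model call.
#' @return object of class `occlusion_heatmap`: `grid` (matrix of
#'   AE_occluded - AE_baseline, rows = excitation-axis region index),
#'   `region_size`, `stride`, `fill_value`, `baseline_ae`, source identity
#'   and the input's wavelength maps.
#' @export
occlusion_sweep <- function(model, input, true_value, region_size = 5,
                            stride = 5, fill_value = 0, batch = 256) {
  if (!inherits(input, "model_input")) stopf("input must be a model_input")
  if (region_size < 1 || stride < 1) stopf("region_size and stride must be >= 1")
  side <- dim(input$pixels)[1L]
  if (region_size > side)
    stopf("region_size %d exceeds the image side %d", region_size, side)
  predictor <- as_predictor(model)
  baseline_ae <- abs(predictor(list(input)) - true_value)
  n_pos <- floor((side - region_size) / stride) + 1L
  starts <- (seq_len(n_pos) - 1L) * stride + 1L
  ## raster order: along the emission axis (columns) first, then next row
  pos <- expand.grid(col = starts, row = starts)[, c("row", "col")]
  vals <- numeric(nrow(pos))
  for (ofs in seq(1L, nrow(pos), by = batch)) {
    idx <- ofs:min(ofs + batch - 1L, nrow(pos))
    occluded <- lapply(idx, function(i) {
      r <- pos$row[i]; cl <- pos$col[i]
      occlude_pixels(input, r:(r + region_size - 1L),
                     cl:(cl + region_size - 1L), fill_value)
    })
    vals[idx] <- abs(predictor(occluded) - true_value) - baseline_ae
  }
  structure(
    list(grid = matrix(vals, n_pos, n_pos, byrow = TRUE),
         region_size = as.integer(region_size), stride = as.integer(stride),
         fill_value = fill_value, baseline_ae = as.numeric(baseline_ae),
         side = side, oil_id = input$oil_id, stage_index = input$stage_index,
         ex_wavelengths = input$ex_wavelengths,
         em_wavelengths = input$em_wavelengths),
    class = "occlusion_heatmap")
}

#' @export
print.occlusion_heatmap <- function(x, ...) {
  cat(sprintf("<occlusion_heatmap> %s stage %s: %d x %d regions (%d px, stride %d), baseline AE %.4g\n",
              x$oil_id, x$stage_index, nrow(x$grid), ncol(x$grid),
              x$region_size, x$stride, x$baseline_ae))
  invisible(x)
}

## paint each region's value over its pixel footprint; overlapping
## footprints average their contributions
paint_heatmap <- function(hm) {
  side <- hm$side
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  starts <- (seq_len(nrow(hm$grid)) - 1L) * hm$stride + 1L
  for (i in seq_along(starts)) for (j in seq_along(starts)) {
    r <- starts[i]:(starts[i] + hm$region_size - 1L)
    cl <- starts[j]:(starts[j] + hm$region_size - 1L)
    acc[r, cl] <- acc[r, cl] + hm$grid[i, j]
    cnt[r, cl] <- cnt[r, cl] + 1
  }
  acc[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  acc
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

## separable Gaussian filter with zero padding and boundary renormalisation
## (constants are preserved exactly; interior mass is conserved)
gaussian_filter_2d <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  conv1 <- function(v) {
    full <- stats::convolve(v, rev(k), type = "open")
    r <- (length(k) - 1L) / 2L
    full[(r + 1L):(r + length(v))]
  }
  norm1 <- conv1(rep(1, nrow(m)))
  sm <- apply(m, 2L, conv1) / norm1          # columns convolved
  norm2 <- conv1(rep(1, ncol(m)))
  rows_conv <- apply(sm, 1L, conv1) / norm2  # (ncol x nrow), rows convolved
  t(rows_conv)
}

#' Smooth an occlusion heatmap for display
#'
#' Upsamples the region grid to the pixel grid (each region value painted
#' over its footprint) and applies a Gaussian filter (default sigma = 3
#' px), then extracts contour lines as data. Smoothing is display-only:
#' every quantitative aggregation ([band_importance()],
#' [heatmap_mass_fraction()]) uses the raw region grid.
#'
#' @param hm an `occlusion_heatmap`.
#' @param sigma Gaussian SD in pixels.
#' @param nlevels number of contour levels.
#' @return object of class `smoothed_heatmap`: `pixel_map` (painted, raw),
#'   `smoothed`, `contours` (list of level/x/y polylines in pixel
#'   coordinates), `sigma`, plus the source wavelength maps.
#' @export
smooth_heatmap <- function(hm, sigma = 3, nlevels = 8) {
  painted <- paint_heatmap(hm)
  sm <- gaussian_filter_2d(painted, sigma)
  contours <- if (diff(range(sm)) > 0)
    grDevices::contourLines(seq_len(nrow(sm)), seq_len(ncol(sm)), sm,
                            nlevels = nlevels)
  else list()
  structure(list(pixel_map = painted, smoothed = sm, contours = contours,
                 sigma = sigma, ex_wavelengths = hm$ex_wavelengths,
                 em_wavelengths = hm$em_wavelengths,
                 oil_id = hm$oil_id, stage_index = hm$stage_index),
            class = "smoothed_heatmap")
}

#' Aggregate a heatmap into per-wavelength-band importances
#'
#' Partitions the image into `strip_width`-pixel strips along one axis and
#' sums the raw region AE increases falling in each strip: emission strips
#' are vertical (the top barplot of an overlay figure), excitation strips
#' horizontal (the side barplot). With the default geometry one strip
#' contains exactly one region row/column, and the strip sums together
#' account for the entire heatmap mass.
#'
#' @param hm an `occlusion_heatmap`.
#' @param axis `"emission"` or `"excitation"`.
#' @param strip_width strip width in pixels; region corners must align
#'   with strip boundaries.
#' @param positive_part sum only positive AE increases instead of the raw
#'   signed values.
#' @return object of class `band_importance`: `axis`, `strip_width`,
#'   `strip_sums` and `wavelength_ranges` (data.frame of nm intervals).
#' @export
band_importance <- function(hm, axis = c("emission", "excitation"),
                            strip_width = 5, positive_part = FALSE) {
  axis <- match.arg(axis)
  if (hm$side %% strip_width != 0)
    stopf("strip_width %d does not partition the %d px image", strip_width, hm$side)
  n_strips <- hm$side %/% strip_width
  starts <- (seq_len(nrow(hm$grid)) - 1L) * hm$stride  # 0-based region corners
  strip_of <- starts %/% strip_width + 1L
  g <- hm$grid
  if (positive_part) g <- pmax(g, 0)
  per_pos <- if (axis == "emission") colSums(g) else rowSums(g)
  sums <- as.numeric(rowsum(per_pos, strip_of))
  ## strips with no region corner (possible for exotic strides) sum to 0
  strip_sums <- numeric(n_strips)
  strip_sums[sort(unique(strip_of))] <- sums
  wl <- if (axis == "emission") hm$em_wavelengths else hm$ex_wavelengths
  lo <- wl[(seq_len(n_strips) - 1L) * strip_width + 1L]
  hi <- wl[seq_len(n_strips) * strip_width]
  structure(list(axis = axis, strip_width = as.integer(strip_width),
                 strip_sums = strip_sums,
                 wavelength_ranges = data.frame(lo_nm = lo, hi_nm = hi)),
            class = "band_importance")
}

#' Average occlusion heatmaps across oils
#'
#' Element-wise mean of the region grids (and of the baseline AEs) of
#' heatmaps with identical geometry, e.g. all oils at the last oxidation
#' stage; the source is marked as `"aggregate"`.
#'
#' @param heatmaps list of `occlusion_heatmap` objects.
#' @return an `occlusion_heatmap`.
#' @export
average_heatmaps <- function(heatmaps) {
  if (length(heatmaps) == 0L) stopf("no heatmaps to average")
  h1 <- heatmaps[[1L]]
  for (h in heatmaps)
    if (!identical(dim(h$grid), dim(h1$grid)) ||
        h$region_size != h1$region_size || h$stride != h1$stride ||
        h$side != h1$side)
      stopf("heatmap geometry mismatch: all inputs must share region size, stride and grid shape")
  out <- h1
  out$grid <- Reduce(`+`, lapply(heatmaps, `[[`, "grid")) / length(heatmaps)
  out$baseline_ae <- mean(vapply(heatmaps, `[[`, numeric(1), "baseline_ae"))
  out$oil_id <- "aggregate"
  out$stage_index <- NA_integer_
  out
}

#' Fraction of heatmap mass inside a pixel mask
#'
#' A region counts as inside the mask when its centre pixel is. Used to
#' quantify localisation: if the positive AE-increase mass concentrates in
#' a band beyond that band's area fraction, the model demonstrably relies
#' on that band.
#'
#' @param hm an `occlusion_heatmap`.
#' @param mask logical pixel matrix (same side as the swept input).
#' @param positive_part use only positive AE increases (default) or raw
#'   signed values.
#' @return list with `mass_fraction`, `area_fraction` and `n_regions_in`.
#' @export
heatmap_mass_fraction <- function(hm, mask, positive_part = TRUE) {
  if (!identical(dim(mask), c(hm$side, hm$side)))
    stopf("mask is %d x %d but the swept image side is %d",
          nrow(mask), ncol(mask), hm$side)
  starts <- (seq_len(nrow(hm$grid)) - 1L) * hm$stride + 1L
  centre <- starts + (hm$region_size - 1L) %/% 2L
  inside <- mask[centre, centre]
  g <- if (positive_part) pmax(hm$grid, 0) else hm$grid
  tot <- sum(g)
  list(mass_fraction = if (tot > 0) sum(g[inside]) / tot else NA_real_,
       area_fraction = mean(inside),
       n_regions_in = sum(inside))
}

#' Eliminate a wavelength band from a model input
#'
#' Maps an excitation x emission rectangle (nm) to pixels with the input's
#' wavelength maps and sets those pixels to `fill_value` in all channels --
#' the targeted variant of occlusion used to remove a named substance's
#' bands (e.g. chlorophyll, oxidation products).
#'
#' @param input a `model_input`.
#' @param band `"R1"`, `"R2"` or `list(ex = c(lo, hi), em = c(lo, hi))`
#'   (see [band_rect()]).
#' @param fill_value replacement value on the 8-bit scale.
#' @return the modified `model_input` (the original is untouched).
#' @export
eliminate_band <- function(input, band, fill_value = 0) {
  band <- band_rect(band)
  rows <- which(input$ex_wavelengths >= min(band$ex) &
                  input$ex_wavelengths <= max(band$ex))
  cols <- which(input$em_wavelengths >= min(band$em) &
                  input$em_wavelengths <= max(band$em))
  if (length(rows) == 0L || length(cols) == 0L)
    stopf("band maps to an empty pixel rectangle")
  occlude_pixels(input, rows, cols, fill_value)
}

#' Absolute-error change caused by eliminating a band
#'
#' @param model an `eem_model` or prediction function.
#' @param input a `model_input`.
#' @param band see [eliminate_band()].
#' @param true_value measured indicator value.
#' @param fill_value replacement value on the 8-bit scale.
#' @return `AE_modified - AE_intact` (positive means the band mattered).
#' @export
evaluate_elimination <- function(model, input, band, true_value,
                                 fill_value = 0) {
  predictor <- as_predictor(model)
  ae0 <- abs(predictor(list(input)) - true_value)
  ae1 <- abs(predictor(list(eliminate_band(input, band, fill_value))) -
               true_value)
  as.numeric(ae1 - ae0)
}

#' Heatmap as a tidy table
#'
#' @param hm an `occlusion_heatmap`.
#' @return data.frame with one row per region: region row/column, the
#'   excitation and emission nm ranges the region covers, and the AE
#'   increase `d_ae`.
#' @export
as_heatmap_df <- function(hm) {
  starts <- (seq_len(nrow(hm$grid)) - 1L) * hm$stride + 1L
  ends <- pmin(starts + hm$region_size - 1L, hm$side)
  idx <- expand.grid(col = seq_len(ncol(hm$grid)), row = seq_len(nrow(hm$grid)))
  data.frame(
    region_row = idx$row, region_col = idx$col,
    ex_lo_nm = hm$ex_wavelengths[starts[idx$row]],
    ex_hi_nm = hm$ex_wavelengths[ends[idx$row]],
    em_lo_nm = hm$em_wavelengths[starts[idx$col]],
    em_hi_nm = hm$em_wavelengths[ends[idx$col]],
    d_ae = as.vector(t(hm$grid)))
}

#' Emission spectrum of an EEM at a chosen excitation wavelength
#'
#' Extracts the emission profile at the excitation wavelength nearest to
#' `ex_nm` -- used to inspect the spectral features that an importance
#' heatmap flags (e.g. the chlorophyll 680/720 nm doublet).
#'
#' @param grid an [eem_grid].
#' @param ex_nm excitation wavelength in nm.
#' @return data.frame with `em_nm` and `intensity`.
#' @export
extract_emission_spectrum <- function(grid, ex_nm) {
  i <- which.min(abs(grid$excitation - ex_nm))
  data.frame(em_nm = grid$emission, intensity = grid$intensities[i, ])
}
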