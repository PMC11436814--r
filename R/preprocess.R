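#' Pixel-centre wavelengths of a resampled axis
#'
#' Corner-aligned affine map: pixel 1 sits on the axis minimum, pixel `n`
#' on the axis maximum.
#'
#' @param n number of pixels.
#' @param wl_min,wl_max axis endpoints in nm.
#' @return numeric vector of length `n`.
#' @export
pixel_centre_wavelengths <- function(n, wl_min, wl_max) {
  wl_min + (seq_len(n) - 1) * (wl_max - wl_min) / (n - 1)
}

#' Normalise an EEM to the unit intensity scale
#'
#' Divides every intensity by the fixed full scale of 1000 counts and clips
#' values above 1 (saturated counts). No per-sample or per-dataset
#' statistics are involved, so the step cannot leak information between
#' cross-validation splits.
#'
#' @param grid an [eem_grid].
#' @return the grid with intensities in `[0, 1]`.
#' @export
normalize_eem <- function(grid) {
  validate_eem_grid(grid, strict = FALSE)
  grid$intensities <- clamp(grid$intensities / 1000, 0, 1)
  grid
}

#' Remove the Rayleigh scatter ridge from an EEM
#'
#' Cells with `|emission - excitation| <= half_width` are either zeroed or
#' replaced by linear interpolation along the emission axis between the
#' nearest unmasked neighbours (constant continuation at the axis ends).
#' If the ridge covers an entire emission row, interpolation falls back to
#' zeroing with a warning.
#'
#' @param grid an [eem_grid].
#' @param mode `"zero"` or `"interpolate"`.
#' @param half_width ridge half-width in nm (> 0).
#' @return the modified [eem_grid].
#' @export
remove_rayleigh <- function(grid, mode = c("zero", "interpolate"),
                            half_width = 20) {
  mode <- match.arg(mode)
  if (!is_scalar_number(half_width) || half_width <= 0)
    stopf("half_width must be > 0")
  validate_eem_grid(grid, strict = FALSE)
  m <- grid$intensities
  for (i in seq_along(grid$excitation)) {
    on_ridge <- abs(grid$emission - grid$excitation[i]) <= half_width
    if (!any(on_ridge)) next
    if (mode == "zero" || all(on_ridge)) {
      if (mode == "interpolate" && all(on_ridge))
        warnf("ridge covers the whole emission row at excitation %g nm; zeroing instead",
              grid$excitation[i])
      m[i, on_ridge] <- 0
    } else {
      keep <- which(!on_ridge)
      m[i, on_ridge] <- stats::approx(grid$emission[keep], m[i, keep],
                                      xout = grid$emission[on_ridge],
                                      rule = 2)$y
    }
  }
  grid$intensities <- m
  grid
}

## corner-aligned separable linear resampling, expressed as weight matrices
## so constants are preserved exactly and the map is monotone.
resample_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  pos <- 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 1)
  frac <- pos - i0
  for (k in seq_len(n_out)) {
    w[k, i0[k]] <- 1 - frac[k]
    w[k, i0[k] + 1] <- frac[k]
  }
  w
}

resample_bilinear <- function(m, n_row_out, n_col_out) {
  resample_weights(nrow(m), n_row_out) %*% m %*% t(resample_weights(ncol(m), n_col_out))
}

#' Convert an EEM into a backbone-ready model input
#'
#' Pipeline: optional Rayleigh-ridge handling, fixed-divisor normalisation
#' ([normalize_eem()]), corner-aligned bilinear resampling of the 35 x 251
#' grid to `size x size`, quantisation to 8 bits (`round(value * 255)`,
#' half away from zero), and triplication into three identical channels.
#' The Rayleigh ridge is retained by default; removing it (either mode)
#' is available because it demonstrably does not change the predictions.
#'
#' @param grid an [eem_grid].
#' @param size output image side (pixels).
#' @param rayleigh `"retain"`, `"zero"` or `"interpolate"`.
#' @param rayleigh_half_width ridge half-width in nm for removal modes.
#' @return object of class `model_input`: `pixels` (integer
#'   `size x size x 3` array, rows = excitation), `ex_wavelengths` /
#'   `em_wavelengths` (pixel-centre maps in nm), `oil_id`, `stage_index`.
#' @export
to_model_input <- function(grid, size = 160,
                           rayleigh = c("retain", "zero", "interpolate"),
                           rayleigh_half_width = 20) {
  rayleigh <- match.arg(rayleigh)
  validate_eem_grid(grid, strict = FALSE)
  if (rayleigh != "retain")
    grid <- remove_rayleigh(grid, mode = rayleigh,
                            half_width = rayleigh_half_width)
  norm <- normalize_eem(grid)$intensities
  resized <- clamp(resample_bilinear(norm, size, size), 0, 1)
  q <- matrix(as.integer(clamp(round_half_up(resized * 255), 0, 255)),
              size, size)
  px <- array(0L, dim = c(size, size, 3L))
  px[, , 1] <- q; px[, , 2] <- q; px[, , 3] <- q
  structure(
    list(pixels = px,
         ex_wavelengths = pixel_centre_wavelengths(size, min(grid$excitation),
                                                   max(grid$excitation)),
         em_wavelengths = pixel_centre_wavelengths(size, min(grid$emission),
                                                   max(grid$emission)),
         native_dim = dim(grid$intensities),
         native_step = c(diff(grid$excitation)[1], diff(grid$emission)[1]),
         oil_id = grid$oil_id, stage_index = grid$stage_index),
    class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<model_input> %s stage %d: %d x %d x %d uint8, ex %g-%g nm, em %g-%g nm\n",
              x$oil_id, x$stage_index, d[1], d[2], d[3],
              min(x$ex_wavelengths), max(x$ex_wavelengths),
              min(x$em_wavelengths), max(x$em_wavelengths)))
  invisible(x)
}

#' Nanometres per pixel of a model-input axis
#'
#' Two conventions coexist: `"step"` divides the native sampled span
#' (number of native samples times their spacing, e.g. 35 x 10 nm = 350 nm
#' for excitation) by the image side, giving 2.2 nm/px at one decimal;
#' `"span"` divides the physical wavelength span (340 nm) by the image
#' side. The step convention matches the published per-pixel figure and is
#' the default.
#'
#' @param input a `model_input`.
#' @param axis `"excitation"` or `"emission"`.
#' @param convention `"step"` or `"span"`.
#' @return nm per pixel (unrounded).
#' @export
nm_per_pixel <- function(input, axis = c("excitation", "emission"),
                         convention = c("step", "span")) {
  axis <- match.arg(axis)
  convention <- match.arg(convention)
  side <- dim(input$pixels)[if (axis == "excitation") 1L else 2L]
  if (convention == "step") {
    i <- if (axis == "excitation") 1L else 2L
    input$native_dim[i] * input$native_step[i] / side
  } else {
    wl <- if (axis == "excitation") input$ex_wavelengths else input$em_wavelengths
    (max(wl) - min(wl)) / side
  }
}

#' Map pixel indices to wavelengths
#' @param input a `model_input`.
#' @param axis `"excitation"` or `"emission"`.
#' @param px 1-based pixel indices.
#' @return wavelengths in nm at the pixel centres.
#' @export
pixel_to_nm <- function(input, axis = c("excitation", "emission"), px) {
  axis <- match.arg(axis)
  wl <- if (axis == "excitation") input$ex_wavelengths else input$em_wavelengths
  wl[px]
}

#' Export a model input as a PNG image (for visual inspection)
#' @param input a `model_input`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_input_png <- function(input, path) {
  png::writePNG(input$pixels[, , 1] / 255, target = path)
  invisible(path)
}

#' Export a model input as CSV plus a JSON wavelength sidecar
#'
#' Writes `<prefix>.csv` (one channel of the 8-bit image) and
#' `<prefix>.json` holding the pixel-centre wavelength maps and identity.
#'
#' @param input a `model_input`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_model_input <- function(input, prefix) {
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  utils::write.table(input$pixels[, , 1], csv, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(oil_id = input$oil_id, stage_index = input$stage_index,
         ex_wavelengths = input$ex_wavelengths,
         em_wavelengths = input$em_wavelengths),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
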