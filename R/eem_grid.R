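#' Construct an EEM grid
#'
#' An `eem_grid` holds one fluorescence excitation-emission matrix: a matrix
#' of intensities (counts) with excitation wavelengths on the rows and
#' emission wavelengths on the columns, together with the identity of the
#' sample it was measured from (an oil and its oxidation stage).
#'
#' The standard acquisition geometry is 35 excitation wavelengths
#' (300-640 nm in 10 nm steps) by 251 emission wavelengths (300-800 nm in
#' 2 nm steps), with intensities in 0-1000 counts. Strict validation
#' enforces this geometry; `strict = FALSE` accepts any rectangular grid
#' with consistent, strictly ascending axes (useful for cropped or
#' down-sampled data).
#'
#' @param intensities numeric matrix, excitation x emission, finite and >= 0.
#' @param excitation ascending excitation wavelengths in nm (one per row).
#' @param emission ascending emission wavelengths in nm (one per column).
#' @param oil_id sample label.
#' @param stage_index integer oxidation stage, 0 = fresh.
#' @param strict enforce the standard 35 x 251 geometry.
#' @return an object of class `eem_grid`.
#' @export
eem_grid <- function(intensities,
                     excitation = eem_excitation_axis(),
                     emission = eem_emission_axis(),
                     oil_id = "oil", stage_index = 0L, strict = TRUE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  g <- structure(
    list(intensities = intensities,
         excitation = as.numeric(excitation),
         emission = as.numeric(emission),
         oil_id = as.character(oil_id),
         stage_index = as.integer(stage_index)),
    class = "eem_grid")
  validate_eem_grid(g, strict = strict)
  g
}

#' Standard EEM wavelength axes
#'
#' @return numeric vector of wavelengths in nm: 35 excitation values
#'   (300-640 nm, 10 nm steps) or 251 emission values (300-800 nm, 2 nm
#'   steps).
#' @export
eem_excitation_axis <- function() seq(300, 640, by = 10)

#' @rdname eem_excitation_axis
#' @export
eem_emission_axis <- function() seq(300, 800, by = 2)

#' Validate an EEM grid
#'
#' Checks axis lengths and spacing, matrix shape, finiteness and
#' non-negativity. Called by every constructor and reader.
#'
#' @param g an `eem_grid`.
#' @param strict enforce the standard 35 x 251 geometry (10 nm / 2 nm steps).
#' @return `g`, invisibly; errors on violation.
#' @export
validate_eem_grid <- function(g, strict = TRUE) {
  m <- g$intensities
  if (!is.matrix(m) || !is.numeric(m))
    stopf("intensities must be a numeric matrix")
  if (nrow(m) != length(g$excitation) || ncol(m) != length(g$emission))
    stopf("intensity matrix is %d x %d but axes have %d and %d entries",
          nrow(m), ncol(m), length(g$excitation), length(g$emission))
  if (!is_uniform_ascending(g$excitation))
    stopf("excitation axis must be strictly ascending with uniform spacing")
  if (!is_uniform_ascending(g$emission))
    stopf("emission axis must be strictly ascending with uniform spacing")
  if (strict) {
    if (length(g$excitation) != 35L || !isTRUE(all.equal(diff(g$excitation)[1], 10)))
      stopf("excitation axis must have 35 entries spaced 10 nm (got %d); use strict = FALSE to override",
            length(g$excitation))
    if (length(g$emission) != 251L || !isTRUE(all.equal(diff(g$emission)[1], 2)))
      stopf("emission axis must have 251 entries spaced 2 nm (got %d); use strict = FALSE to override",
            length(g$emission))
  }
  if (any(!is.finite(m)))
    stopf("intensities contain non-finite values")
  if (any(m < 0))
    stopf("intensities must be >= 0 (min = %g)", min(m))
  invisible(g)
}

#' @export
print.eem_grid <- function(x, ...) {
  cat(sprintf("<eem_grid> %s stage %d: %d x %d (ex %g-%g nm, em %g-%g nm), max %0.1f counts\n",
              x$oil_id, x$stage_index, nrow(x$intensities), ncol(x$intensities),
              min(x$excitation), max(x$excitation),
              min(x$emission), max(x$emission), max(x$intensities)))
  invisible(x)
}

#' Quality indicators for one oil at one oxidation stage
#'
#' K232 and K268 are the UV extinction coefficients at 232 nm and 268 nm
#' (dimensionless), regulatory proxies for primary and secondary lipid
#' oxidation products respectively.
#'
#' @param k232,k268 finite non-negative numbers.
#' @return object of class `quality_indicators`.
#' @export
quality_indicators <- function(k232, k268) {
  if (!is_scalar_number(k232) || k232 < 0) stopf("k232 must be a finite number >= 0")
  if (!is_scalar_number(k268) || k268 < 0) stopf("k268 must be a finite number >= 0")
  structure(list(k232 = as.numeric(k232), k268 = as.numeric(k268)),
            class = "quality_indicators")
}

#' @export
print.quality_indicators <- function(x, ...) {
  cat(sprintf("<quality_indicators> K232 = %.3f, K268 = %.3f\n", x$k232, x$k268))
  invisible(x)
}
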