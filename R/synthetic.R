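#' Fluorophore specification for the synthetic EEM generator
#'
#' Each fluorophore contributes a separable band: a Gaussian excitation
#' profile times a mixture of Gaussian emission peaks (the mixture supports
#' the chlorophyll doublet at 680/720 nm). Its amplitude evolves linearly
#' with oxidation stage: `A(s) = base_amplitude * max(0, 1 +
#' stage_coefficient * s)`, so a negative coefficient models pigment
#' bleaching and a positive one the accumulation of oxidation products.
#'
#' @param name label; the names `"chlorophyll"` and `"oxidation_product"`
#'   are recognised by the label link (see [synthetic_oil_params()]).
#' @param ex_center,ex_width excitation Gaussian centre and SD (nm).
#' @param em_centers,em_widths,em_weights emission mixture centres, SDs (nm)
#'   and non-negative relative weights (recycled to common length).
#' @param base_amplitude fresh-oil peak amplitude in counts.
#' @param stage_coefficient signed per-stage relative amplitude change.
#' @return object of class `fluorophore`.
#' @export
fluorophore <- function(name, ex_center, ex_width, em_centers, em_widths,
                        em_weights = 1, base_amplitude = 100,
                        stage_coefficient = 0) {
  n <- max(length(em_centers), length(em_widths), length(em_weights))
  em_centers <- rep_len(em_centers, n)
  em_widths <- rep_len(em_widths, n)
  em_weights <- rep_len(em_weights, n)
  if (ex_width <= 0 || any(em_widths <= 0)) stopf("band widths must be > 0")
  if (base_amplitude < 0) stopf("base_amplitude must be >= 0")
  if (any(em_centers < 300 | em_centers > 800))
    stopf("emission centers must lie in 300-800 nm")
  structure(list(name = name, ex_center = ex_center, ex_width = ex_width,
                 em_centers = em_centers, em_widths = em_widths,
                 em_weights = em_weights, base_amplitude = base_amplitude,
                 stage_coefficient = stage_coefficient),
            class = "fluorophore")
}

#' Default fluorophores of an extra virgin olive oil EEM
#'
#' Chlorophyll: broad excitation centred near 410 nm, emission doublet with
#' the main peak at 680 nm and a broad secondary peak at 720 nm, declining
#' with oxidation. Oxidation products: excitation 340-390 nm, emission
#' centred near 470 nm, growing with oxidation stage.
#'
#' @return list of [fluorophore] objects.
#' @export
default_fluorophores <- function() {
  list(
    fluorophore("chlorophyll", ex_center = 410, ex_width = 60,
                em_centers = c(680, 720), em_widths = c(12, 25),
                em_weights = c(1, 0.6), base_amplitude = 800,
                stage_coefficient = -0.06),
    fluorophore("oxidation_product", ex_center = 365, ex_width = 30,
                em_centers = 470, em_widths = 40, em_weights = 1,
                base_amplitude = 60, stage_coefficient = 0.35)
  )
}

#' Affine link from latent oxidation state to a quality indicator
#'
#' `K = intercept + ox_slope * u(s) + chl_slope * d(s) + noise`, where
#' `u(s)` is the oxidation-product amplitude at stage `s` divided by the
#' 1000-count full scale and `d(s)` is the chlorophyll amplitude loss since
#' stage 0, also in full-scale units. With all fluorophore amplitudes zero
#' both latents vanish and `K` equals the intercept exactly.
#'
#' @param intercept fresh-oil baseline value.
#' @param ox_slope weight of the oxidation-product latent.
#' @param chl_slope weight of the chlorophyll-decline latent.
#' @param noise_sd SD of the additive label noise (scaled by the oil's
#'   `label_noise_sd` multiplier).
#' @return object of class `label_link`.
#' @export
label_link <- function(intercept, ox_slope = 0, chl_slope = 0, noise_sd = 0) {
  structure(list(intercept = intercept, ox_slope = ox_slope,
                 chl_slope = chl_slope, noise_sd = noise_sd),
            class = "label_link")
}

#' Generative parameters for one synthetic oil
#'
#' Defaults emulate a fresh commercial EVOO: strong chlorophyll emission,
#' a weak but growing oxidation-product band, a Rayleigh scatter ridge on
#' the diagonal, detector noise of a few counts, and K232/K268 driven by
#' the fluorophore amplitudes (K268 by the oxidation-product latent alone,
#' K232 by a mixture of oxidation and chlorophyll decline).
#'
#' @param oil_id label.
#' @param fluorophores list of [fluorophore] objects.
#' @param rayleigh_amplitude ridge intensity in counts.
#' @param rayleigh_half_width half-width of the ridge support in nm; the
#'   ridge covers exactly the cells with `|em - ex| <= half_width`.
#' @param noise_sd additive Gaussian detector noise SD in counts (applied
#'   before clipping to 0-1000).
#' @param k232_link,k268_link [label_link] objects.
#' @param label_noise_sd dimensionless multiplier on both links' noise SDs.
#' @return object of class `synthetic_oil_params`.
#' @export
synthetic_oil_params <- function(oil_id = "oil01",
                                 fluorophores = default_fluorophores(),
                                 rayleigh_amplitude = 400,
                                 rayleigh_half_width = 10,
                                 noise_sd = 5,
                                 k232_link = label_link(1.70, ox_slope = 1.3,
                                                        chl_slope = 1.2,
                                                        noise_sd = 0.02),
                                 k268_link = label_link(0.10, ox_slope = 1.0,
                                                        chl_slope = 0,
                                                        noise_sd = 0.005),
                                 label_noise_sd = 1) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (label_noise_sd < 0) stopf("label_noise_sd must be >= 0")
  if (rayleigh_half_width <= 0) stopf("rayleigh_half_width must be > 0")
  structure(list(oil_id = oil_id, fluorophores = fluorophores,
                 rayleigh_amplitude = rayleigh_amplitude,
                 rayleigh_half_width = rayleigh_half_width,
                 noise_sd = noise_sd, k232_link = k232_link,
                 k268_link = k268_link, label_noise_sd = label_noise_sd),
            class = "synthetic_oil_params")
}

fluoro_amplitude <- function(f, stage) {
  f$base_amplitude * max(0, 1 + f$stage_coefficient * stage)
}

## latent oxidation state in full-scale (1000 count) units
latent_states <- function(params, stage) {
  u <- 0; d <- 0
  for (f in params$fluorophores) {
    if (f$name == "oxidation_product")
      u <- u + fluoro_amplitude(f, stage) / 1000
    if (f$name == "chlorophyll")
      d <- d + (fluoro_amplitude(f, 0) - fluoro_amplitude(f, stage)) / 1000
  }
  list(ox = u, chl_decline = d)
}

synth_eem_matrix <- function(params, stage, excitation, emission, noise = TRUE) {
  m <- matrix(0, length(excitation), length(emission))
  for (f in params$fluorophores) {
    a <- fluoro_amplitude(f, stage)
    if (a == 0) next
    gex <- exp(-(excitation - f$ex_center)^2 / (2 * f$ex_width^2))
    gem <- rep(0, length(emission))
    for (k in seq_along(f$em_centers))
      gem <- gem + f$em_weights[k] *
        exp(-(emission - f$em_centers[k])^2 / (2 * f$em_widths[k]^2))
    m <- m + a * outer(gex, gem)
  }
  if (params$rayleigh_amplitude > 0) {
    ridge <- abs(outer(excitation, emission, function(ex, em) em - ex)) <=
      params$rayleigh_half_width
    m <- m + params$rayleigh_amplitude * ridge
  }
  if (noise && params$noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, params$noise_sd),
                    nrow(m), ncol(m))
  clamp(m, 0, 1000)
}

synth_labels <- function(params, stage, noise = TRUE) {
  lat <- latent_states(params, stage)
  one <- function(link) {
    v <- link$intercept + link$ox_slope * lat$ox + link$chl_slope * lat$chl_decline
    if (noise && link$noise_sd * params$label_noise_sd > 0)
      v <- v + stats::rnorm(1, 0, link$noise_sd * params$label_noise_sd)
    max(v, 0)
  }
  quality_indicators(k232 = one(params$k232_link), k268 = one(params$k268_link))
}

#' Simulate one oil across oxidation stages
#'
#' Each stage's EEM is the sum over fluorophores of separable Gaussian
#' bands with stage-scaled amplitudes, plus a Rayleigh ridge along
#' emission = excitation, plus additive Gaussian noise, clipped to the
#' 0-1000 count range. K232/K268 follow the affine label links (see
#' [label_link()]) with additive label noise. Output is a deterministic
#' function of `(params, n_stages, seed)`.
#'
#' @param params a [synthetic_oil_params].
#' @param n_stages number of stages (>= 1); stage indices run 0..n_stages-1.
#' @param seed integer RNG seed.
#' @return list of records `list(grid, labels)`, one per stage.
#' @export
simulate_oil <- function(params, n_stages = 10, seed = 1) {
  if (!is_scalar_number(n_stages) || n_stages < 1)
    stopf("n_stages must be >= 1")
  ex <- eem_excitation_axis(); em <- eem_emission_axis()
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_stages) - 1L, function(s) {
      m <- synth_eem_matrix(params, s, ex, em)
      list(grid = eem_grid(m, ex, em, oil_id = params$oil_id, stage_index = s),
           labels = synth_labels(params, s))
    })
  })
}

jitter_params <- function(params, heterogeneity, oil_id) {
  h <- heterogeneity
  params$oil_id <- oil_id
  if (h <= 0) return(params)
  params$fluorophores <- lapply(params$fluorophores, function(f) {
    f$base_amplitude <- f$base_amplitude * exp(stats::rnorm(1, 0, 0.3 * h))
    f$ex_center <- clamp(f$ex_center + stats::rnorm(1, 0, 15 * h), 300, 640)
    f$em_centers <- clamp(f$em_centers + stats::rnorm(1, 0, 8 * h), 300, 800)
    f$stage_coefficient <- f$stage_coefficient * exp(stats::rnorm(1, 0, 0.3 * h))
    f
  })
  params$rayleigh_amplitude <- params$rayleigh_amplitude * exp(stats::rnorm(1, 0, 0.3 * h))
  params
}

#' Simulate a dataset of heterogeneous oils
#'
#' Per-oil generative parameters are drawn around the defaults of
#' [synthetic_oil_params()]: log-normal spread (SD `0.3 * heterogeneity`)
#' on amplitudes and stage rates, Gaussian jitter on band centres (SD
#' `15 * heterogeneity` nm excitation, `8 * heterogeneity` nm emission).
#' `heterogeneity = 1` emulates the deliberately diverse commercial oils of
#' a deliberately diverse commercial panel; `0` makes every oil identical up to noise.
#'
#' @param n_oils,n_stages dataset shape; defaults are the full study shape
#'   (24 oils, 10 stages including fresh).
#' @param seed integer RNG seed; determines everything.
#' @param heterogeneity non-negative spread multiplier.
#' @param base_params template [synthetic_oil_params].
#' @return an [oil_dataset] with `n_oils * n_stages` records.
#' @export
simulate_dataset <- function(n_oils = 24, n_stages = 10, seed = 1,
                             heterogeneity = 1,
                             base_params = synthetic_oil_params()) {
  if (!is_scalar_number(n_oils) || n_oils < 1) stopf("n_oils must be >= 1")
  oil_ids <- sprintf("oil%02d", seq_len(n_oils))
  prm <- withr::with_seed(as.integer(seed), {
    oil_seeds <- sample.int(2147483646L, n_oils)
    lapply(seq_len(n_oils), function(i)
      list(p = jitter_params(base_params, heterogeneity, oil_ids[i]),
           seed = oil_seeds[i]))
  })
  records <- do.call(c, lapply(prm, function(x)
    simulate_oil(x$p, n_stages = n_stages, seed = x$seed)))
  oil_dataset(records)
}

#' Named spectral band rectangles
#'
#' `R1` marks the chlorophyll absorption/emission bands (excitation
#' 300-650 nm, emission 650-750 nm); `R2` the oxidation-product bands
#' (excitation 300-400 nm, emission 400-500 nm).
#'
#' @param band `"R1"`, `"R2"`, or a `list(ex = c(lo, hi), em = c(lo, hi))`.
#' @return list with elements `ex` and `em` (nm ranges).
#' @export
band_rect <- function(band) {
  if (is.character(band)) {
    band <- switch(match.arg(band, c("R1", "R2")),
                   R1 = list(ex = c(300, 650), em = c(650, 750)),
                   R2 = list(ex = c(300, 400), em = c(400, 500)))
  }
  if (!is.list(band) || is.null(band$ex) || is.null(band$em))
    stopf("band must be 'R1', 'R2' or list(ex = c(lo, hi), em = c(lo, hi))")
  band
}

#' Ground-truth band mask on the model-input pixel grid
#'
#' Marks the pixels of a wavelength rectangle using the same corner-aligned
#' pixel-centre wavelength maps as [to_model_input()], so generator bands
#' and occlusion heatmaps share one geometry.
#'
#' @param band see [band_rect()].
#' @param size image side in pixels.
#' @param ex_range,em_range full wavelength span of the two image axes (nm).
#' @return `size x size` logical matrix (rows = excitation pixels).
#' @export
ground_truth_band_mask <- function(band, size = 160,
                                   ex_range = c(300, 640),
                                   em_range = c(300, 800)) {
  band <- band_rect(band)
  if (max(band$ex) < ex_range[1] || min(band$ex) > ex_range[2] ||
      max(band$em) < em_range[1] || min(band$em) > em_range[2])
    stopf("band rectangle lies outside the axis ranges")
  ex_wl <- pixel_centre_wavelengths(size, ex_range[1], ex_range[2])
  em_wl <- pixel_centre_wavelengths(size, em_range[1], em_range[2])
  outer(ex_wl >= min(band$ex) & ex_wl <= max(band$ex),
        em_wl >= min(band$em) & em_wl <= max(band$em), `&`)
}
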