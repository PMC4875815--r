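# Built-in illuminant library.
#
# "ideal" is the flat unit illuminant. The three habitat illuminants are
# smooth parametric curves shaped to the qualitative structure of measured
# forest-light spectra: forest shade is UV-poor and peaks in the green-yellow
# (vegetation-filtered light), D65 is broad standard daylight, and blue sky is
# richest at short/UV wavelengths. Each is scaled so its total photon flux
# over 300-700 nm matches published field totals (forest shade 142.71,
# daylight 275.87, blue sky 249.10 umol m^-2 s^-1). Absolute scale cancels
# under von Kries adaptation; the curves are synthetic stand-ins and can be
# replaced by measured CSV curves via read_irradiance_table().

.illuminant_shape <- function(name, wl) {
  switch(name,
    ideal = rep(1, length(wl)),
    forest_shade = {
      # green-yellow dome with suppressed UV tail
      0.04 + exp(-((wl - 560)^2) / (2 * 90^2)) * (1 / (1 + exp(-(wl - 420) / 25)))
    },
    d65 = {
      # broad daylight: gentle rise from UV, near-flat through the visible
      (1 / (1 + exp(-(wl - 350) / 40))) * (1 - 0.25 * (wl - 300) / 400)
    },
    blue_sky = {
      # Rayleigh-like: intensity peaks toward the UV and falls with wavelength
      (wl / 300)^(-3) + 0.15
    },
    stop("unknown illuminant: ", name, call. = FALSE)
  )
}

.illuminant_totals <- c(ideal = NA_real_, forest_shade = 142.71,
                        d65 = 275.87, blue_sky = 249.10)

#' Built-in illuminants
#'
#' @param name One of `"ideal"`, `"forest_shade"`, `"d65"`, `"blue_sky"`.
#'   `"ideal"` is the constant function 1; the other three are smooth
#'   parametric daylight/habitat curves scaled to published total photon
#'   fluxes over 300-700 nm.
#' @param grid Wavelength grid in nm.
#' @return An [irradiance_spectrum()].
#' @export
illuminant <- function(name = c("ideal", "forest_shade", "d65", "blue_sky"),
                       grid = canonical_grid()) {
  name <- match.arg(name)
  grid <- as.numeric(grid)
  y <- .illuminant_shape(name, grid)
  tot <- .illuminant_totals[[name]]
  if (is.finite(tot)) y <- y * tot / trapz(grid, y)
  irradiance_spectrum(grid, y, name = name)
}

#' Illuminant used by a light-level group in the habitat-matched scenario
#'
#' Maps habitat light levels to the illuminant each group experiences:
#' forest shade for the low light group, standard daylight (D65) for the
#' intermediate group, and blue sky for the high light group (its intensity
#' peaks in the UV, like forest-canopy light).
#'
#' @param light_level `"low"`, `"intermediate"`, or `"high"`.
#' @return The illuminant name.
#' @export
scenario_for_group <- function(light_level) {
  map <- c(low = "forest_shade", intermediate = "d65", high = "blue_sky")
  out <- unname(map[light_level])
  if (any(is.na(out))) {
    stop("mapping error: unknown light level(s) ",
         paste(light_level[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

# trapezoid rule on an arbitrary ascending grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
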