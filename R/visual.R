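#' Visual pigment spectral sensitivity (A1 nomogram)
#'
#' Builds the absorbance template of a vitamin-A1 visual pigment from its peak
#' wavelength, using the Govardovskii rhodopsin nomogram, and peak-normalizes
#' it on the requested grid. The default is the alpha band alone, which is
#' unimodal; the short-wavelength beta band (a secondary absorbance bump that
#' in intact eyes is largely masked by ocular media and oil droplets) can be
#' added with `beta = TRUE`.
#'
#' @param lambda_max Peak wavelength in nm (must lie within the grid range).
#' @param grid Wavelength grid in nm.
#' @param beta Include the beta absorbance band.
#' @return Numeric sensitivity curve on `grid`, maximum value 1.
#' @export
pigment_sensitivity <- function(lambda_max, grid = canonical_grid(),
                                beta = FALSE) {
  grid <- as.numeric(grid)
  if (lambda_max < min(grid) || lambda_max > max(grid)) {
    stop("domain error: lambda_max outside the wavelength grid", call. = FALSE)
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((grid - lmb) / bb)^2)
  }
  s / max(s)
}

#' Construct an avian visual system
#'
#' A tetrachromatic (UVS-type) visual system: four single-cone sensitivity
#' curves ordered u < s < m < l by peak wavelength, relative cone densities,
#' and the Weber fraction of the most abundant cone class. Defaults give a
#' generic average avian UV system with blue tit cone densities.
#'
#' @param peaks Named numeric vector of peak wavelengths (nm) for cones
#'   `u, s, m, l`. Ignored when `curves` is supplied.
#' @param densities Relative cone densities (u, s, m, l), all > 0.
#' @param weber Weber fraction of the most abundant cone class, in (0, 1).
#' @param grid Wavelength grid.
#' @param curves Optional 4-column matrix of tabulated sensitivity curves on
#'   `grid` (columns u, s, m, l), overriding the nomogram construction.
#' @param name Label for the system.
#' @return An object of class `visual_system`.
#' @export
visual_system <- function(peaks = c(u = 370, s = 445, m = 508, l = 565),
                          densities = c(u = 0.37, s = 0.70, m = 0.99, l = 1.00),
                          weber = 0.05,
                          grid = canonical_grid(),
                          curves = NULL,
                          name = "avian_uvs") {
  grid <- as.numeric(grid)
  densities <- as.numeric(densities)
  if (length(densities) != 4L || any(densities <= 0)) {
    stop("densities must be four positive values", call. = FALSE)
  }
  if (weber <= 0 || weber >= 1) stop("weber must lie in (0, 1)", call. = FALSE)
  if (is.null(curves)) {
    peaks <- as.numeric(peaks)
    if (length(peaks) != 4L || any(diff(peaks) <= 0)) {
      stop("peaks must be four increasing wavelengths (u < s < m < l)",
           call. = FALSE)
    }
    curves <- vapply(peaks, pigment_sensitivity, numeric(length(grid)),
                     grid = grid)
  } else {
    curves <- as.matrix(curves)
    if (nrow(curves) != length(grid) || ncol(curves) != 4L) {
      stop("curves must be a length(grid) x 4 matrix", call. = FALSE)
    }
    curves <- sweep(curves, 2, apply(curves, 2, max), "/")
    peaks <- grid[apply(curves, 2, which.max)]
  }
  colnames(curves) <- c("u", "s", "m", "l")
  names(densities) <- c("u", "s", "m", "l")
  structure(list(grid = grid, curves = curves, peaks = peaks,
                 densities = densities, weber = weber, name = name),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system> %s: peaks %s nm, densities %s, w = %g\n",
              x$name, paste(round(x$peaks), collapse = "/"),
              paste(format(x$densities), collapse = ":"), x$weber))
  invisible(x)
}

#' Cone quantum catches of a stimulus
#'
#' Integrates reflectance x illuminant x cone sensitivity over the grid
#' (trapezoid rule) for each of the four cone classes.
#'
#' @param s A [reflectance_spectrum()] on the system's grid.
#' @param illum An [irradiance_spectrum()] on the same grid.
#' @param vs A [visual_system()].
#' @return Object of class `quantum_catch` with raw catches `$Q`; the
#'   adapted catches `$q` and log signals `$f` are filled by [von_kries()].
#' @export
quantum_catch <- function(s, illum, vs) {
  .check_grid(s$wavelengths, vs$grid)
  .check_grid(illum$wavelengths, vs$grid)
  prod <- s$reflectance * illum$irradiance
  Q <- vapply(1:4, function(i) trapz(vs$grid, vs$curves[, i] * prod),
              numeric(1))
  names(Q) <- colnames(vs$curves)
  structure(list(Q = Q, q = NULL, f = NULL), class = "quantum_catch")
}

.check_grid <- function(a, b) {
  if (length(a) != length(b) || any(a != b)) {
    stop("grid error: spectrum not on the visual system's wavelength grid",
         call. = FALSE)
  }
}

#' Von Kries chromatic adaptation
#'
#' Normalizes each cone's catch by its catch of the adapting background,
#' giving color constancy; the log of the adapted catch is the receptor
#' signal used by the discrimination model.
#'
#' @param Q A `quantum_catch` for the stimulus.
#' @param Q_bg A `quantum_catch` for the adapting background.
#' @return `Q` with `$q = Q/Q_bg` and `$f = log(q)` filled in.
#' @export
von_kries <- function(Q, Q_bg) {
  if (any(Q_bg$Q <= 0)) {
    stop("degenerate-background error: background catch <= 0 for cone(s) ",
         paste(names(Q_bg$Q)[Q_bg$Q <= 0], collapse = ", "), call. = FALSE)
  }
  q <- Q$Q / Q_bg$Q
  if (any(q <= 0)) {
    stop("log-domain error: adapted catch <= 0 for cone(s) ",
         paste(names(q)[q <= 0], collapse = ", "), call. = FALSE)
  }
  Q$q <- q
  Q$f <- log(q)
  Q
}

#' Receptor noise per cone class
#'
#' Noise-to-signal ratio of each cone channel under the neural-noise
#' convention: `e_c = w * sqrt(n_max / n_c)`, anchored so the most abundant
#' cone class has noise equal to the Weber fraction.
#'
#' @param vs A [visual_system()].
#' @return Named numeric vector `e` over cones u, s, m, l.
#' @export
receptor_noise <- function(vs) {
  n <- vs$densities
  if (any(n <= 0)) stop("domain error: non-positive cone density", call. = FALSE)
  vs$weber * sqrt(max(n) / n)
}

#' Receptor-noise distance from contrast differences
#'
#' The tetrachromatic receptor-noise discrimination distance given the four
#' receptor-contrast differences `df = f(a) - f(b)` and the per-cone noises
#' `e`:
#' \deqn{\Delta S^2 = \frac{(e_1e_2)^2(df_4-df_3)^2 + (e_1e_3)^2(df_4-df_2)^2 +
#'   (e_1e_4)^2(df_3-df_2)^2 + (e_2e_3)^2(df_4-df_1)^2 +
#'   (e_2e_4)^2(df_3-df_1)^2 + (e_3e_4)^2(df_2-df_1)^2}{
#'   (e_1e_2e_3)^2 + (e_1e_2e_4)^2 + (e_1e_3e_4)^2 + (e_2e_3e_4)^2}}
#'
#' @param df Numeric length-4 vector of log-contrast differences.
#' @param e Numeric length-4 vector of positive receptor noises.
#' @return Non-negative distance in just noticeable differences (jnd).
#' @export
receptor_distance <- function(df, e) {
  df <- unname(as.numeric(df))
  e <- unname(as.numeric(e))
  stopifnot(length(df) == 4L, length(e) == 4L, all(e > 0))
  num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
    (e[1] * e[3])^2 * (df[4] - df[2])^2 +
    (e[1] * e[4])^2 * (df[3] - df[2])^2 +
    (e[2] * e[3])^2 * (df[4] - df[1])^2 +
    (e[2] * e[4])^2 * (df[3] - df[1])^2 +
    (e[3] * e[4])^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

#' Chromatic discrimination distance between two stimuli
#'
#' Computes the receptor-noise-limited distance (in jnd) between two
#' reflectance spectra under a given illuminant and visual system. The
#' adapting background is an ideal white reflector under the same illuminant,
#' so absolute illuminant intensity cancels.
#'
#' @param a,b [reflectance_spectrum()] objects on the system grid.
#' @param illum An [irradiance_spectrum()]; default the ideal illuminant.
#' @param vs A [visual_system()].
#' @return ΔS in jnd (non-negative, symmetric in `a`, `b`).
#' @export
delta_S <- function(a, b, illum = illuminant("ideal"), vs = visual_system()) {
  bg <- reflectance_spectrum(vs$grid, rep(1, length(vs$grid)),
                             meta = list(patch = NA))
  Qbg <- quantum_catch(bg, illum, vs)
  fa <- tryCatch(von_kries(quantum_catch(a, illum, vs), Qbg)$f,
                 error = function(e) .annotate_catch_error(e, a))
  fb <- tryCatch(von_kries(quantum_catch(b, illum, vs), Qbg)$f,
                 error = function(e) .annotate_catch_error(e, b))
  receptor_distance(fa - fb, receptor_noise(vs))
}

.annotate_catch_error <- function(e, s) {
  m <- s$meta
  stop(conditionMessage(e), sprintf(" [species=%s sex=%s patch=%s]",
                                    m$species %||% "?", m$sex %||% "?",
                                    m$patch %||% "?"), call. = FALSE)
}
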