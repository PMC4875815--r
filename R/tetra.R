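#' Relative quantum catches
#'
#' Normalizes the four von-Kries-adapted catches to sum to one, so that a
#' spectrally flat stimulus sits at the achromatic center.
#'
#' @param q Positive length-4 vector of adapted catches (u, s, m, l), or a
#'   `quantum_catch` object with `$q` filled in.
#' @return Named numeric usml vector summing to 1.
#' @export
relative_catches <- function(q) {
  if (inherits(q, "quantum_catch")) {
    if (is.null(q$q)) stop("apply von_kries() before relative_catches()",
                           call. = FALSE)
    q <- q$q
  }
  q <- as.numeric(q)
  if (length(q) != 4L) stop("need four cone catches", call. = FALSE)
  if (any(q <= 0)) stop("degenerate-stimulus error: zero cone catch",
                        call. = FALSE)
  out <- q / sum(q)
  names(out) <- c("u", "s", "m", "l")
  out
}

#' Map relative catches into the tetrahedral color space
#'
#' The standard avian tetrahedral color space: the achromatic point
#' (1/4, 1/4, 1/4, 1/4) maps to the origin, each pure-cone stimulus to a
#' vertex at distance 0.75 (the u vertex on the +z axis), and chroma is the
#' Euclidean distance from the origin.
#'
#' @param usml Length-4 non-negative vector summing to 1 (tolerance 1e-6).
#' @param meta Optional metadata list (species, sex, patch).
#' @return Object of class `color_point` with fields `usml`, `xyz`, `r`.
#' @export
tetra_point <- function(usml, meta = list()) {
  usml <- as.numeric(usml)
  if (length(usml) != 4L || any(usml < 0) || abs(sum(usml) - 1) > 1e-6) {
    stop("domain error: usml must be non-negative and sum to 1", call. = FALSE)
  }
  u <- usml[1]; s <- usml[2]; m <- usml[3]
  x <- ((1 - 2 * s - m - u) / 2) * sqrt(3 / 2)
  y <- (-1 + 3 * m + u) / (2 * sqrt(2))
  z <- u - 1 / 4
  xyz <- c(x = x, y = y, z = z)
  structure(list(usml = stats::setNames(usml, c("u", "s", "m", "l")),
                 xyz = xyz, r = sqrt(sum(xyz^2)), meta = as.list(meta)),
            class = "color_point")
}

#' @export
print.color_point <- function(x, ...) {
  cat(sprintf("<color_point> xyz = (%.4f, %.4f, %.4f), chroma r = %.4f\n",
              x$xyz[1], x$xyz[2], x$xyz[3], x$r))
  invisible(x)
}

#' Color point of a reflectance spectrum
#'
#' Convenience wrapper: quantum catches under an illuminant with an ideal
#' white adapting background, von Kries adaptation, relative catches, and the
#' tetrahedral mapping.
#'
#' @param s A [reflectance_spectrum()].
#' @param vs A [visual_system()].
#' @param illum Illuminant (default ideal, the convention for descriptor
#'   computation).
#' @return A `color_point` carrying the spectrum's metadata.
#' @export
spectrum_color_point <- function(s, vs = visual_system(),
                                 illum = illuminant("ideal")) {
  bg <- reflectance_spectrum(vs$grid, rep(1, length(vs$grid)))
  q <- von_kries(quantum_catch(s, illum, vs), quantum_catch(bg, illum, vs))
  tetra_point(relative_catches(q), meta = s$meta)
}

#' Average brightness of a spectrum
#'
#' Arithmetic mean reflectance over the spectral range.
#'
#' @param s A [reflectance_spectrum()].
#' @return Mean reflectance proportion.
#' @export
brightness <- function(s) mean(s$reflectance)

#' Volume of the 3-D convex hull of a point set
#'
#' Exact convex-hull volume by enumeration of supporting planes, suitable for
#' the small point sets of a plumage (a handful of patches). Degenerate sets
#' (fewer than 4 distinct points, or coplanar/collinear points) have volume 0.
#'
#' @param xyz Numeric matrix with 3 columns (or list of `color_point`s).
#' @return Hull volume (color-space units cubed).
#' @export
hull_volume <- function(xyz) {
  if (is.list(xyz) && !is.matrix(xyz) && !is.data.frame(xyz)) {
    xyz <- do.call(rbind, lapply(xyz, function(p) p$xyz))
  }
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  xyz <- unique(xyz)
  n <- nrow(xyz)
  if (n < 4L) return(0)
  scale <- max(abs(sweep(xyz, 2, colMeans(xyz)))) + .Machine$double.eps
  tol <- 1e-10 * scale
  # rank check: all points coplanar -> volume 0
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))$d
  if (sv[3] <= 1e-12 * max(sv[1], 1)) return(0)
  ctr <- colMeans(xyz)
  planes <- list()
  keys <- character(0)
  cmb <- utils::combn(n, 3)
  for (j in seq_len(ncol(cmb))) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]; i3 <- cmb[3, j]
    v1 <- xyz[i2, ] - xyz[i1, ]
    v2 <- xyz[i3, ] - xyz[i1, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nl <- sqrt(sum(nrm^2))
    if (nl <= tol * scale) next
    nrm <- nrm / nl
    d <- sum(nrm * xyz[i1, ])
    side <- xyz %*% nrm - d
    if (all(side <= tol)) {
      # keep normal pointing away from the interior
    } else if (all(side >= -tol)) {
      nrm <- -nrm; d <- -d; side <- -side
    } else next
    keyv <- round(c(nrm, d), 7)
    keyv[abs(keyv) < 5e-8] <- 0
    key <- paste(sprintf("%.7f", keyv), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    planes[[length(planes) + 1L]] <- list(n = nrm, d = d,
                                          pts = which(abs(side) <= tol))
  }
  vol <- 0
  for (pl in planes) {
    pts <- xyz[pl$pts, , drop = FALSE]
    # orthonormal basis of the facet plane
    b1 <- pts[2, ] - pts[1, ]
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(pl$n[2] * b1[3] - pl$n[3] * b1[2],
            pl$n[3] * b1[1] - pl$n[1] * b1[3],
            pl$n[1] * b1[2] - pl$n[2] * b1[1])
    uv <- cbind((pts %*% b1)[, 1], (pts %*% b2)[, 1])
    cuv <- colMeans(uv)
    ord <- order(atan2(uv[, 2] - cuv[2], uv[, 1] - cuv[1]))
    uv <- uv[ord, , drop = FALSE]
    k <- nrow(uv)
    area <- abs(sum(uv[, 1] * uv[c(2:k, 1), 2] -
                      uv[c(2:k, 1), 1] * uv[, 2])) / 2
    h <- pl$d - sum(pl$n * ctr)  # distance from interior point to plane
    vol <- vol + area * abs(h) / 3
  }
  vol
}

#' Six whole-plumage color descriptors
#'
#' Summarizes one plumage (a set of patch color points and the matching
#' sex-mean reflectance spectra) into: average color span (mean pairwise
#' Euclidean distance), its variance (population convention, divide by the
#' number of pairs), convex-hull color volume, average and maximum chroma,
#' and average brightness (mean of per-patch mean reflectance).
#'
#' @param points List of `color_point` objects (>= 2 for span statistics).
#' @param spectra List of the same patches' [reflectance_spectrum()] curves.
#' @return A one-row data.frame with the six descriptors and `n_patches`.
#' @export
plumage_summary <- function(points, spectra) {
  if (length(points) < 2L) {
    stop("span undefined error: need at least 2 patches for span statistics",
         call. = FALSE)
  }
  xyz <- do.call(rbind, lapply(points, function(p) p$xyz))
  dd <- as.numeric(stats::dist(xyz))
  r <- vapply(points, function(p) p$r, numeric(1))
  data.frame(
    n_patches = length(points),
    avg_span = mean(dd),
    var_span = mean((dd - mean(dd))^2),
    volume = hull_volume(xyz),
    avg_chroma = mean(r),
    max_chroma = max(r),
    brightness = mean(vapply(spectra, brightness, numeric(1)))
  )
}

#' Species-level color descriptors for a collection
#'
#' Computes the six descriptors per species. Each sex's patch set is
#' summarized separately on sex-mean spectra (ideal illuminant and ideal
#' white background); the species value is by default the mean of the male
#' and female descriptor values, or the summary of the pooled two-sex point
#' cloud when `combine = "pool"`.
#'
#' @param coll A replicate-level [spectrum_collection()].
#' @param vs A [visual_system()].
#' @param combine `"average"` (default) or `"pool"`.
#' @return Data.frame with one row per species (plus per-sex rows in
#'   attribute `"by_sex"`).
#' @export
species_descriptors <- function(coll, vs = visual_system(),
                                combine = c("average", "pool")) {
  combine <- match.arg(combine)
  sm <- sex_mean_spectra(coll)
  ill <- illuminant("ideal", grid = vs$grid)
  meta <- sm$meta
  by_sex <- list()
  rows <- list()
  for (sp in unique(meta$species)) {
    sexes <- unique(meta$sex[meta$species == sp])
    per_sex <- list()
    for (sx in sexes) {
      idx <- meta$idx[meta$species == sp & meta$sex == sx]
      specs <- sm$records[idx]
      pts <- lapply(specs, spectrum_color_point, vs = vs, illum = ill)
      d <- plumage_summary(pts, specs)
      per_sex[[sx]] <- list(desc = d, pts = pts, specs = specs)
      by_sex[[length(by_sex) + 1L]] <- cbind(
        data.frame(species = sp, sex = sx, stringsAsFactors = FALSE), d)
    }
    if (combine == "average" || length(sexes) == 1L) {
      ds <- do.call(rbind, lapply(per_sex, `[[`, "desc"))
      row <- as.data.frame(as.list(colMeans(ds)))
    } else {
      pts <- unlist(lapply(per_sex, `[[`, "pts"), recursive = FALSE)
      specs <- unlist(lapply(per_sex, `[[`, "specs"), recursive = FALSE)
      row <- plumage_summary(pts, specs)
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(species = sp, stringsAsFactors = FALSE), row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "by_sex") <- do.call(rbind, by_sex)
  out
}
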