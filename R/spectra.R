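#' Canonical wavelength grid
#'
#' The analysis grid used throughout the package: 300 to 700 nm inclusive at a
#' 1-nm step (401 points). Reflectance is measured over this range by typical
#' field spectrometers and all quantum-catch integrals are evaluated on it.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
canonical_grid <- function() 300:700

#' Canonical plumage patch names
#'
#' The patch set used in studies of whole-body plumage color: throat, breast,
#' belly, crown, nape, back, rump, tail, wing coverts, and facial marks when
#' present.
#'
#' @return Character vector of patch names.
#' @export
canonical_patches <- function() {
  c("throat", "breast", "belly", "crown", "nape", "back", "rump", "tail",
    "wing_coverts", "facial_mark")
}

#' Construct a reflectance spectrum
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance Numeric vector of reflectance proportions (nominally
#'   0-1), same length as `wavelengths`.
#' @param meta Named list of metadata (species, sex, specimen, patch,
#'   replicate, ...). Free-form; aggregation functions fill in `n_averaged`
#'   and `level`.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least two points", call. = FALSE)
  }
  if (any(!is.finite(reflectance))) {
    stop("reflectance values must be finite", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(reflectance < 0)) {
    stop("reflectance values must be >= 0", call. = FALSE)
  }
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         meta = as.list(meta)),
    class = "reflectance_spectrum"
  )
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<reflectance_spectrum> %g-%g nm, %d points, mean %.3f\n",
              rng[1], rng[2], length(x$wavelengths), mean(x$reflectance)))
  m <- x$meta
  keys <- intersect(c("species", "sex", "specimen", "patch", "replicate",
                      "level", "n_averaged"), names(m))
  if (length(keys)) {
    cat("  ", paste(sprintf("%s=%s", keys, unlist(m[keys])), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Construct an irradiance spectrum
#'
#' @param wavelengths Numeric nm grid.
#' @param irradiance Non-negative photon-flux values (relative units).
#' @param name Scenario label, e.g. `"ideal"`, `"forest_shade"`, `"d65"`,
#'   `"blue_sky"`, or `"custom"`.
#' @return An object of class `irradiance_spectrum`.
#' @export
irradiance_spectrum <- function(wavelengths, irradiance, name = "custom") {
  wavelengths <- as.numeric(wavelengths)
  irradiance <- as.numeric(irradiance)
  if (length(wavelengths) != length(irradiance)) {
    stop("wavelengths and irradiance must have equal length", call. = FALSE)
  }
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    stop("irradiance must be finite and non-negative", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, irradiance = irradiance,
                 name = name),
            class = "irradiance_spectrum")
}

#' Construct a spectrum collection
#'
#' A validated set of reflectance spectra plus the species-to-light-level map
#' used to resolve habitat-specific illuminants.
#'
#' @param records List of [reflectance_spectrum()] objects.
#' @param group_map Named character vector mapping species to a light level in
#'   `c("low", "intermediate", "high")`, or `NULL` if no comparative analysis
#'   is planned.
#' @return An object of class `spectrum_collection` with a metadata index in
#'   `$meta`.
#' @export
spectrum_collection <- function(records, group_map = NULL) {
  if (!length(records)) stop("empty spectrum collection", call. = FALSE)
  meta <- do.call(rbind, lapply(seq_along(records), function(i) {
    m <- records[[i]]$meta
    data.frame(
      idx = i,
      species = as.character(m$species %||% NA_character_),
      sex = as.character(m$sex %||% NA_character_),
      specimen = as.character(m$specimen %||% NA_character_),
      patch = as.character(m$patch %||% NA_character_),
      replicate = as.character(m$replicate %||% NA_character_),
      level = as.character(m$level %||% "replicate"),
      stringsAsFactors = FALSE
    )
  }))
  bad <- setdiff(unique(meta$patch), c(canonical_patches(), NA_character_))
  if (length(bad)) {
    stop("unknown patch name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(group_map)) {
    lv <- setdiff(unique(as.character(group_map)),
                  c("low", "intermediate", "high"))
    if (length(lv)) {
      stop("unknown light level(s) in group_map: ",
           paste(lv, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(records = records, meta = meta, group_map = group_map),
            class = "spectrum_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spectrum_collection <- function(x, ...) {
  cat(sprintf("<spectrum_collection> %d spectra, %d species\n",
              nrow(x$meta), length(unique(x$meta$species))))
  tab <- table(x$meta$species, x$meta$sex)
  cat(sprintf("  sexes: %s; patches: %d distinct\n",
              paste(colnames(tab), collapse = "/"),
              length(unique(x$meta$patch))))
  invisible(x)
}

#' Read a long-format reflectance table
#'
#' Expects a CSV with columns `species, sex, specimen, patch, replicate,
#' wavelength_nm, reflectance`. Reflectance recorded in percent (curves
#' exceeding 1.5 throughout) is auto-rescaled to proportion with a message.
#'
#' @param path Path to the CSV file.
#' @param group_map Optional named vector species -> light level, attached to
#'   the collection.
#' @param exclude_patches Optional character vector of patch names to drop
#'   (e.g. patches rejected in the field as barred or mottled).
#' @return A [spectrum_collection()].
#' @export
read_spectra_table <- function(path, group_map = NULL, exclude_patches = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: no spectra rows in ", path, call. = FALSE)
  need <- c("species", "sex", "specimen", "patch", "replicate",
            "wavelength_nm", "reflectance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$reflectance)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$reflectance))))[1]
    stop("parse error: non-numeric reflectance at data row ", bad,
         call. = FALSE)
  }
  if (!is.null(exclude_patches)) {
    df <- df[!(df$patch %in% exclude_patches), , drop = FALSE]
    if (nrow(df) == 0L) stop("empty input after patch exclusion", call. = FALSE)
  }
  key <- interaction(df$species, df$sex, df$specimen, df$patch, df$replicate,
                     drop = TRUE)
  records <- lapply(split(df, key), function(d) {
    d <- d[order(d$wavelength_nm), , drop = FALSE]
    refl <- d$reflectance
    # percent-scaled curves: rescale when the whole curve sits above 1.5
    if (all(refl > 1.5)) {
      message("rescaling percent reflectance to proportion for ",
              d$species[1], "/", d$patch[1])
      refl <- refl / 100
    }
    reflectance_spectrum(d$wavelength_nm, refl, meta = list(
      species = d$species[1], sex = d$sex[1], specimen = d$specimen[1],
      patch = d$patch[1], replicate = d$replicate[1], level = "replicate"
    ))
  })
  names(records) <- NULL
  spectrum_collection(records, group_map = group_map)
}

#' Write a collection to a long-format reflectance CSV
#'
#' Inverse of [read_spectra_table()]; round-trips values at full precision.
#'
#' @param coll A [spectrum_collection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(coll, path) {
  stopifnot(inherits(coll, "spectrum_collection"))
  rows <- lapply(coll$records, function(s) {
    m <- s$meta
    data.frame(species = m$species, sex = m$sex, specimen = m$specimen,
               patch = m$patch, replicate = m$replicate,
               wavelength_nm = s$wavelengths, reflectance = s$reflectance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an irradiance table
#'
#' CSV with columns `wavelength_nm, irradiance` and optionally `name`.
#'
#' @param path CSV path.
#' @param name Scenario label override.
#' @return An [irradiance_spectrum()].
#' @export
read_irradiance_table <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "irradiance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  irradiance_spectrum(df$wavelength_nm, df$irradiance,
                      name = name %||% (df$name[1] %||% "custom"))
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; never extrapolates.
#'
#' @param s A [reflectance_spectrum()] or [irradiance_spectrum()].
#' @param grid Target nm grid (default the canonical 300-700 nm grid).
#' @return A spectrum of the same class on `grid`.
#' @export
resample_spectrum <- function(s, grid = canonical_grid()) {
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelengths) || max(grid) > max(s$wavelengths)) {
    stop(sprintf(
      "coverage error: requested %g-%g nm but spectrum covers %g-%g nm",
      min(grid), max(grid), min(s$wavelengths), max(s$wavelengths)),
      call. = FALSE)
  }
  if (inherits(s, "irradiance_spectrum")) {
    vals <- stats::approx(s$wavelengths, s$irradiance, xout = grid)$y
    return(irradiance_spectrum(grid, vals, name = s$name))
  }
  vals <- stats::approx(s$wavelengths, s$reflectance, xout = grid)$y
  reflectance_spectrum(grid, vals, meta = s$meta)
}

#' Average a list of reflectance spectra pointwise
#'
#' Used at both aggregation levels of a specimen study: three replicate scans
#' are averaged into a specimen curve, and specimen curves into a sex mean.
#'
#' @param spectra Nonempty list of [reflectance_spectrum()] objects on
#'   identical grids.
#' @param level Aggregation label recorded in the result's metadata.
#' @return A [reflectance_spectrum()]; `meta$n_averaged` records the count.
#' @export
average_spectra <- function(spectra, level = "specimen") {
  if (!length(spectra)) stop("empty input: nothing to average", call. = FALSE)
  wl <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(wl) || any(s$wavelengths != wl)) {
      stop("grid error: spectra are not on identical wavelength grids",
           call. = FALSE)
    }
  }
  mat <- vapply(spectra, function(s) s$reflectance, numeric(length(wl)))
  mat <- matrix(mat, nrow = length(wl))
  meta <- spectra[[1]]$meta
  meta$n_averaged <- length(spectra)
  meta$level <- level
  reflectance_spectrum(wl, rowMeans(mat), meta = meta)
}

#' Aggregate a collection to sex-mean spectra
#'
#' Replicate scans are averaged within specimen, then specimen curves within
#' sex, giving one curve per species x sex x patch. Between-sex color
#' distances are computed on these sex means.
#'
#' @param coll A [spectrum_collection()] of replicate-level records.
#' @return A [spectrum_collection()] of sex-mean records (one per
#'   species/sex/patch), inheriting the group map.
#' @export
sex_mean_spectra <- function(coll) {
  stopifnot(inherits(coll, "spectrum_collection"))
  meta <- coll$meta
  out <- list()
  for (sp in unique(meta$species)) {
    for (sx in unique(meta$sex[meta$species == sp])) {
      sel <- meta$species == sp & meta$sex == sx
      for (p in unique(meta$patch[sel])) {
        psel <- sel & meta$patch == p
        spec_means <- lapply(unique(meta$specimen[psel]), function(id) {
          reps <- coll$records[meta$idx[psel & meta$specimen == id]]
          average_spectra(reps, level = "specimen")
        })
        m <- average_spectra(spec_means, level = "sex")
        m$meta$specimen <- NA_character_
        m$meta$replicate <- NA_character_
        out[[length(out) + 1L]] <- m
      }
    }
  }
  spectrum_collection(out, group_map = coll$group_map)
}

#' Count records per species, sex, and patch
#'
#' A validation report used to check study design balance.
#'
#' @param coll A [spectrum_collection()].
#' @return A data.frame with one row per species/sex/patch and an `n` count.
#' @export
collection_report <- function(coll) {
  stopifnot(inherits(coll, "spectrum_collection"))
  agg <- stats::aggregate(idx ~ species + sex + patch, data = coll$meta,
                          FUN = length)
  names(agg)[names(agg) == "idx"] <- "n"
  agg[order(agg$species, agg$sex, agg$patch), , drop = FALSE]
}
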