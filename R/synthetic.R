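# Synthetic reflectance study generator.
#
# Museum reflectance datasets of drab Neotropical passerines are rarely
# deposited, so the generator builds a study with the same statistical
# structure: smooth brown reflectance curves (low baseline rising through the
# red), several patches per species with patch-level shape offsets, multiple
# specimens per sex with specimen-level intensity/tilt noise, three replicate
# scans per patch, a species-to-light-level map, a Yule phylogeny, and
# descriptor traits simulated under known evolutionary models.

# run code with a deterministic seed without clobbering the caller's RNG
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# fold a string key into a 31-bit sub-seed so every unit (species, patch,
# specimen, replicate) gets an independent reproducible stream
subseed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Species template for the drab-spectrum generator
#'
#' Parameters of the smooth reflectance family used for brown plumage: a
#' baseline reflectance plus a sigmoid long-wavelength ramp and an optional
#' UV bump, with per-patch shape offsets, a sex-difference specification
#' (chromatic ramp-inflection shift in nm and/or a pure intensity scale
#' factor applied to females), and specimen/replicate noise levels.
#'
#' @param species Species label.
#' @param base Baseline reflectance proportion.
#' @param amp Ramp amplitude (long-wavelength reflectance gain).
#' @param inflection Ramp inflection wavelength (nm).
#' @param width Ramp width (nm).
#' @param uv_amp,uv_width UV bump amplitude and width (bump centered 360 nm).
#' @param patches Character vector of patch names (canonical set).
#' @param patch_offsets Optional data.frame (patch, base_mul, amp_mul,
#'   infl_shift); generated deterministically from `seed` when `NULL`.
#' @param sex_shift_nm Chromatic dimorphism: ramp-inflection shift applied to
#'   females, per patch (recycled).
#' @param sex_scale Intensity dimorphism: multiplicative factor applied to
#'   female curves (1 = none; pure scaling is invisible to the chromatic
#'   discrimination distance).
#' @param specimen_scale_sd SD of the specimen-level log intensity factor.
#' @param specimen_tilt_sd SD of the specimen-level spectral tilt.
#' @param replicate_sd SD of replicate-level instrument noise.
#' @param seed Seed for the deterministic patch offsets.
#' @return Object of class `species_template`.
#' @export
species_template <- function(species = "sp",
                             base = 0.06, amp = 0.30,
                             inflection = 590, width = 45,
                             uv_amp = 0.02, uv_width = 30,
                             patches = c("throat", "breast", "belly", "crown",
                                         "nape", "back", "rump"),
                             patch_offsets = NULL,
                             sex_shift_nm = 0, sex_scale = 1,
                             specimen_scale_sd = 0.05,
                             specimen_tilt_sd = 0.008,
                             replicate_sd = 0.002,
                             seed = 1L) {
  stopifnot(base > 0, amp >= 0, width > 0, uv_width > 0, sex_scale > 0)
  if (is.null(patch_offsets)) {
    patch_offsets <- with_seed(subseed(seed, paste0(species, ":offsets")), {
      data.frame(
        patch = patches,
        base_mul = stats::runif(length(patches), 0.8, 1.5),
        amp_mul = stats::runif(length(patches), 0.7, 1.4),
        infl_shift = stats::runif(length(patches), -25, 25),
        uv_mul = stats::runif(length(patches), 0.2, 1.8),
        stringsAsFactors = FALSE
      )
    })
  }
  shift <- rep_len(sex_shift_nm, length(patches))
  names(shift) <- patches
  structure(list(species = species, base = base, amp = amp,
                 inflection = inflection, width = width,
                 uv_amp = uv_amp, uv_width = uv_width,
                 patches = patches, patch_offsets = patch_offsets,
                 sex_shift_nm = shift, sex_scale = sex_scale,
                 specimen_scale_sd = specimen_scale_sd,
                 specimen_tilt_sd = specimen_tilt_sd,
                 replicate_sd = replicate_sd, seed = seed),
            class = "species_template")
}

# noiseless patch curve for one sex
.template_curve <- function(tpl, patch, sex, grid) {
  po <- tpl$patch_offsets
  row <- po[po$patch == patch, , drop = FALSE]
  if (!nrow(row)) stop("patch not in template: ", patch, call. = FALSE)
  infl <- tpl$inflection + row$infl_shift
  shift <- if (sex == "F") tpl$sex_shift_nm[[patch]] else 0
  uv_mul <- if ("uv_mul" %in% names(row)) row$uv_mul else 1
  y <- tpl$base * row$base_mul +
    tpl$amp * row$amp_mul / (1 + exp(-(grid - (infl + shift)) / tpl$width)) +
    tpl$uv_amp * uv_mul * exp(-((grid - 360) / tpl$uv_width)^2)
  if (sex == "F") y <- y * tpl$sex_scale
  y
}

#' Generate one synthetic reflectance scan
#'
#' Builds the template's noiseless curve for the given patch and sex, applies
#' a specimen-level intensity factor and spectral tilt (shared by all of that
#' specimen's replicates), adds small replicate-level instrument noise, and
#' clips to \[0.001, 1\]. Fully deterministic given `seed` and the identifiers.
#'
#' @param template A [species_template()].
#' @param patch Patch name.
#' @param sex `"M"` or `"F"`.
#' @param specimen Specimen identifier (string or number).
#' @param replicate Replicate number.
#' @param seed Study-level seed.
#' @param grid Wavelength grid.
#' @return A [reflectance_spectrum()] with full metadata.
#' @export
make_drab_spectrum <- function(template, patch, sex, specimen, replicate,
                               seed = 1L, grid = canonical_grid()) {
  grid <- as.numeric(grid)
  y <- .template_curve(template, patch, sex, grid)
  if (any(!is.finite(y))) stop("domain error: template produced non-finite values",
                               call. = FALSE)
  spec_key <- paste(template$species, sex, specimen, sep = ":")
  sp_noise <- with_seed(subseed(seed, spec_key), {
    c(scale = exp(stats::rnorm(1, 0, template$specimen_scale_sd)),
      tilt = stats::rnorm(1, 0, template$specimen_tilt_sd))
  })
  y <- y * sp_noise["scale"] * (1 + sp_noise["tilt"] * (grid - 500) / 200)
  rep_key <- paste(spec_key, patch, replicate, sep = ":")
  y <- y + with_seed(subseed(seed, rep_key),
                     stats::rnorm(length(grid), 0, template$replicate_sd))
  y <- pmin(pmax(y, 0.001), 1)
  reflectance_spectrum(grid, y, meta = list(
    species = template$species, sex = sex, specimen = as.character(specimen),
    patch = patch, replicate = as.character(replicate), level = "replicate"))
}

#' Calibrate the chromatic sex shift to a target discrimination distance
#'
#' Bisection on the female ramp-inflection shift until the ideal-illuminant
#' ΔS between the noiseless male and female curves of a patch is within 2%
#' of the target (exactly 0 for target 0).
#'
#' @param template A [species_template()].
#' @param target_deltaS Target ΔS in jnd (>= 0).
#' @param vs A [visual_system()].
#' @param patch Patch whose curves are compared (default the first).
#' @param max_shift Physical bound on the shift (nm).
#' @return Shift magnitude in nm.
#' @export
calibrate_sex_shift <- function(template, target_deltaS,
                                vs = visual_system(),
                                patch = template$patches[1],
                                max_shift = 120) {
  stopifnot(target_deltaS >= 0)
  if (target_deltaS == 0) return(0)
  grid <- vs$grid
  ill <- illuminant("ideal", grid = grid)
  m <- reflectance_spectrum(grid, .template_curve(template, patch, "M", grid))
  ds_at <- function(shift) {
    tpl <- template
    tpl$sex_shift_nm[[patch]] <- shift
    f <- reflectance_spectrum(grid, .template_curve(tpl, patch, "F", grid))
    delta_S(m, f, ill, vs)
  }
  hi <- max_shift
  if (ds_at(hi) < target_deltaS) {
    stop("calibration error: target ", target_deltaS,
         " jnd unreachable within ", max_shift, " nm shift", call. = FALSE)
  }
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- ds_at(mid)
    if (abs(v - target_deltaS) <= 0.02 * target_deltaS) return(mid)
    if (v < target_deltaS) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with the requested number of tips, depth rescaled to 1.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @param tip_labels Optional tip labels (default `t1..tn` from the
#'   simulator).
#' @return An ultrametric `ape::phylo` tree of depth 1.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L,
                               tip_labels = NULL) {
  if (n_tips < 2) stop("domain error: need at least 2 tips", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$edge.length <- tree$edge.length / max(tip_depths(tree))
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tree$tip.label <- tip_labels
  }
  tree
}

#' Specification of a synthetic reflectance study
#'
#' Defaults emulate the design of a 33-species museum study: group sizes
#' 4 low / 18 intermediate / 11 high, 5-10 patches per species, 3-5
#' specimens per sex, 3 replicate scans, and descriptor traits evolving
#' under known models (brightness under a three-regime OU with optima
#' 0.15 / 0.19 / 0.22, attraction about 4 and rate about 0.005 on a depth-1
#' tree; the other descriptors under the BM or single-optimum OU settings
#' of the same scale).
#'
#' @param n_species Named integer vector of species counts per light level.
#' @param patch_range Range of patches per species.
#' @param specimen_range Range of specimens per sex.
#' @param replicates Replicate scans per patch.
#' @param seed Study seed (separate sub-seeds drive spectra, tree, traits).
#' @param birth_rate Yule speciation rate for the tree.
#' @param deltaS_targets Pool of per-patch target ΔS values (jnd) assigned
#'   to dichromatic patches; chosen away from the 1.0/1.5/2.0 thresholds so
#'   calibration tolerance cannot flip a classification.
#' @param prop_monochromatic Fraction of species with no dichromatic patch.
#' @param trait_models Named list of per-descriptor trait-evolution settings
#'   (`model`, `params`).
#' @return Object of class `study_fixture_spec`.
#' @export
study_fixture_spec <- function(n_species = c(low = 4, intermediate = 18,
                                             high = 11),
                               patch_range = c(5, 10),
                               specimen_range = c(3, 5),
                               replicates = 3,
                               seed = 1L,
                               birth_rate = 1,
                               deltaS_targets = c(0.6, 1.25, 1.75, 2.4),
                               prop_monochromatic = 0.18,
                               trait_models = NULL) {
  if (is.null(trait_models)) {
    trait_models <- list(
      avg_span = list(model = "BM", params = list(sigma2 = 6.1e-6, z0 = 0.029)),
      var_span = list(model = "OU1", params = list(alpha = 3.71,
                                                   sigma2 = 7.1e-7,
                                                   theta = 3.0e-4)),
      volume = list(model = "BM", params = list(sigma2 = 1.8e-13, z0 = 2.0e-6)),
      avg_chroma = list(model = "BM", params = list(sigma2 = 7.4e-5,
                                                    z0 = 0.32)),
      max_chroma = list(model = "OU1", params = list(alpha = 4.61,
                                                     sigma2 = 0.02,
                                                     theta = 0.41)),
      brightness = list(model = "OU_regimes",
                        params = list(alpha = 4.17, sigma2 = 0.005,
                                      theta_low = 0.15,
                                      theta_intermediate = 0.19,
                                      theta_high = 0.22))
    )
  }
  structure(list(n_species = n_species, patch_range = patch_range,
                 specimen_range = specimen_range, replicates = replicates,
                 seed = as.integer(seed), birth_rate = birth_rate,
                 deltaS_targets = deltaS_targets,
                 prop_monochromatic = prop_monochromatic,
                 trait_models = trait_models),
            class = "study_fixture_spec")
}

#' Generate a full synthetic study with known ground truth
#'
#' Builds the whole input set for the pipeline: a replicate-level spectrum
#' collection whose per-patch chromatic dimorphism is calibrated to known
#' target ΔS values, a Yule phylogeny over the species, the light-level map,
#' and descriptor traits simulated under known evolutionary parameters.
#'
#' @param spec A [study_fixture_spec()].
#' @param vs Visual system used for ΔS calibration.
#' @return List with `collection`, `tree`, `group_map`, `truth` (per-patch
#'   ΔS targets, per-descriptor trait model truth, simulated trait matrix),
#'   and `spec`.
#' @export
make_study_fixture <- function(spec = study_fixture_spec(),
                               vs = visual_system()) {
  stopifnot(inherits(spec, "study_fixture_spec"))
  seed <- spec$seed
  lvls <- names(spec$n_species)
  n_tot <- sum(spec$n_species)
  species <- sprintf("species_%02d", seq_len(n_tot))
  group_map <- stats::setNames(rep(lvls, spec$n_species), species)

  n_mono <- max(0L, round(spec$prop_monochromatic * n_tot))
  mono <- with_seed(subseed(seed, "mono"),
                    sort(sample(species, n_mono)))

  records <- list()
  target_rows <- list()
  for (sp in species) {
    sp_seed <- subseed(seed, paste0(sp, ":design"))
    des <- with_seed(sp_seed, {
      n_pat <- sample(spec$patch_range[1]:spec$patch_range[2], 1)
      n_spec <- sample(spec$specimen_range[1]:spec$specimen_range[2], 1)
      patches <- c(setdiff(canonical_patches(), "facial_mark")[
        sample.int(9, min(n_pat, 9))])
      if (n_pat > 9) patches <- c(patches, "facial_mark")
      list(n_pat = n_pat, n_spec = n_spec, patches = patches,
           base = stats::runif(1, 0.04, 0.08),
           amp = stats::runif(1, 0.22, 0.40),
           infl = stats::runif(1, 550, 630),
           width = stats::runif(1, 30, 60),
           uv = stats::runif(1, 0.005, 0.045))
    })
    # assign per-patch ΔS targets: monochromatic species get all zeros;
    # others get 1-3 dichromatic patches with targets from the pool
    targets <- stats::setNames(rep(0, length(des$patches)), des$patches)
    if (!(sp %in% mono)) {
      targets[] <- with_seed(subseed(seed, paste0(sp, ":targets")), {
        t <- rep(0, length(des$patches))
        nd <- sample(1:3, 1)
        t[sample.int(length(t), nd)] <-
          sample(spec$deltaS_targets, nd, replace = TRUE)
        t
      })
    }
    tpl <- species_template(
      species = sp, base = des$base, amp = des$amp, inflection = des$infl,
      width = des$width, uv_amp = des$uv, patches = des$patches,
      seed = subseed(seed, paste0(sp, ":offsets")))
    for (p in des$patches) {
      if (targets[[p]] > 0) {
        tpl$sex_shift_nm[[p]] <- calibrate_sex_shift(tpl, targets[[p]], vs,
                                                     patch = p)
      }
      target_rows[[length(target_rows) + 1L]] <- data.frame(
        species = sp, patch = p, target_deltaS = targets[[p]],
        stringsAsFactors = FALSE)
    }
    for (sx in c("M", "F")) {
      for (id in seq_len(des$n_spec)) {
        for (p in des$patches) {
          for (r in seq_len(spec$replicates)) {
            records[[length(records) + 1L]] <-
              make_drab_spectrum(tpl, p, sx, id, r, seed = seed)
          }
        }
      }
    }
  }
  coll <- spectrum_collection(records, group_map = group_map)

  tree <- simulate_yule_tree(n_tot, spec$birth_rate,
                             seed = subseed(seed, "tree"),
                             tip_labels = species)
  painting <- paint_regimes(tree, group_map)
  traits <- sapply(names(spec$trait_models), function(d) {
    tm <- spec$trait_models[[d]]
    drop(simulate_traits(tree, tm$model, tm$params,
                         seed = subseed(seed, paste0("trait:", d)),
                         painting = if (tm$model == "OU_regimes") painting))
  })
  rownames(traits) <- tree$tip.label

  list(collection = coll, tree = tree, group_map = group_map,
       truth = list(deltaS_targets = do.call(rbind, target_rows),
                    monochromatic = mono,
                    trait_models = spec$trait_models,
                    traits = traits),
       spec = spec)
}

#' Write a fixture's input files to a directory
#'
#' Writes the long-format spectra CSV, the Newick tree, the tip-to-regime
#' TSV, and a ground-truth JSON.
#'
#' @param fixture Result of [make_study_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             tree = file.path(dir, "tree.nwk"),
             regimes = file.path(dir, "regimes.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_spectra_table(fixture$collection, paths["spectra"])
  ape::write.tree(fixture$tree, paths["tree"])
  utils::write.table(
    data.frame(species = names(fixture$group_map),
               regime = unname(fixture$group_map)),
    paths["regimes"], sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(
    list(deltaS_targets = fixture$truth$deltaS_targets,
         monochromatic = fixture$truth$monochromatic,
         trait_models = fixture$truth$trait_models,
         traits = as.data.frame(fixture$truth$traits)),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
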