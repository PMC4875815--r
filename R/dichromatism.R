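#' Per-patch male-female discrimination table
#'
#' Computes ΔS (jnd) between the male and female sex-mean curve of every
#' homologous patch, under each requested illuminant scenario. `"ideal"` uses
#' the flat unit illuminant; `"real"` resolves each species' habitat
#' illuminant from the collection's group map (forest shade / D65 / blue
#' sky); a named illuminant applies that illuminant to every species.
#'
#' @param coll A replicate-level [spectrum_collection()]; its `group_map`
#'   must cover every species when a `"real"` scenario is requested.
#' @param vs A [visual_system()].
#' @param scenarios Character vector from
#'   `c("ideal", "real", "forest_shade", "d65", "blue_sky")`.
#' @return Data.frame with columns species, light_level, patch and one
#'   `deltaS_<scenario>` column per scenario. Patches present in one sex only
#'   are skipped with a warning; species missing a sex are skipped entirely.
#' @export
patch_deltaS_table <- function(coll, vs = visual_system(),
                               scenarios = c("ideal", "real")) {
  stopifnot(inherits(coll, "spectrum_collection"))
  known <- c("ideal", "real", "forest_shade", "d65", "blue_sky")
  bad <- setdiff(scenarios, known)
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  gm <- coll$group_map
  if ("real" %in% scenarios && is.null(gm)) {
    stop("mapping error: 'real' scenario requires a species -> light level map",
         call. = FALSE)
  }
  sm <- sex_mean_spectra(coll)
  meta <- sm$meta
  ills <- lapply(stats::setNames(nm = c("ideal", "forest_shade", "d65",
                                        "blue_sky")),
                 illuminant, grid = vs$grid)
  rows <- list()
  for (sp in unique(meta$species)) {
    sexes <- unique(meta$sex[meta$species == sp])
    if (!all(c("M", "F") %in% sexes)) {
      warning("skipping species ", sp, ": missing one sex", call. = FALSE)
      next
    }
    lvl <- if (!is.null(gm)) unname(gm[sp]) else NA_character_
    if ("real" %in% scenarios && (is.na(lvl) || !nzchar(lvl))) {
      stop("mapping error: species ", sp, " has no light level", call. = FALSE)
    }
    patches_m <- meta$patch[meta$species == sp & meta$sex == "M"]
    patches_f <- meta$patch[meta$species == sp & meta$sex == "F"]
    only <- c(setdiff(patches_m, patches_f), setdiff(patches_f, patches_m))
    if (length(only)) {
      warning("species ", sp, ": patch(es) present in one sex only skipped: ",
              paste(only, collapse = ", "), call. = FALSE)
    }
    for (p in intersect(patches_m, patches_f)) {
      a <- sm$records[[meta$idx[meta$species == sp & meta$sex == "M" &
                                  meta$patch == p]]]
      b <- sm$records[[meta$idx[meta$species == sp & meta$sex == "F" &
                                  meta$patch == p]]]
      row <- data.frame(species = sp, light_level = lvl, patch = p,
                        stringsAsFactors = FALSE)
      for (sc in scenarios) {
        illname <- if (sc == "real") scenario_for_group(lvl) else sc
        row[[paste0("deltaS_", sc)]] <- delta_S(a, b, ills[[illname]], vs)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species dichromatic-patch counts at discrimination thresholds
#'
#' A patch is dichromatic when its ΔS meets or exceeds the threshold
#' (inclusive comparison); a species is dichromatic when at least one of its
#' patches is.
#'
#' @param records Output of [patch_deltaS_table()].
#' @param thresholds Ascending jnd thresholds (default 1.0, 1.5, 2.0).
#' @return Data.frame with one row per species: `n_patches_measured`, then
#'   for each scenario and threshold a count column `n_<scenario>_<thr>` and
#'   a logical flag `dichromatic_<scenario>_<thr>`.
#' @export
threshold_summary <- function(records, thresholds = c(1.0, 1.5, 2.0)) {
  if (!nrow(records)) stop("empty records", call. = FALSE)
  sc_cols <- grep("^deltaS_", names(records), value = TRUE)
  scen <- sub("^deltaS_", "", sc_cols)
  rows <- lapply(split(records, records$species), function(d) {
    row <- data.frame(species = d$species[1],
                      light_level = d$light_level[1],
                      n_patches_measured = nrow(d),
                      stringsAsFactors = FALSE)
    for (i in seq_along(scen)) {
      for (th in thresholds) {
        n <- sum(d[[sc_cols[i]]] >= th)
        row[[sprintf("n_%s_%s", scen[i], format(th))]] <- n
        row[[sprintf("dichromatic_%s_%s", scen[i], format(th))]] <- n >= 1L
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[match(unique(records$species), out$species), , drop = FALSE]
}

#' Aggregate printed-style per-species counts
#'
#' Operates on a counts table (one row per species with
#' `n_patches_measured` and `n_<scenario>_<threshold>` columns, i.e. the
#' output of [threshold_summary()] or a transcription of a published summary
#' table) and reports, per scenario and threshold, the number and percentage
#' of dichromatic species and the totals row.
#'
#' @param counts Counts data.frame as above.
#' @param thresholds Thresholds matching the count columns.
#' @return List with `species_totals` (per scenario x threshold: n and pct of
#'   dichromatic species) and `n_species`.
#' @export
species_dichromatism_totals <- function(counts, thresholds = c(1.0, 1.5, 2.0)) {
  cols <- grep("^n_(?!patches)", names(counts), value = TRUE, perl = TRUE)
  scen <- unique(sub("^n_([^_]+)_.*$", "\\1", cols))
  out <- list()
  for (sc in scen) {
    for (th in thresholds) {
      cn <- sprintf("n_%s_%s", sc, format(th))
      if (!cn %in% names(counts)) next
      n_dich <- sum(counts[[cn]] >= 1L)
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, threshold = th, n_dichromatic_species = n_dich,
        pct_dichromatic_species = round(100 * n_dich / nrow(counts), 1),
        stringsAsFactors = FALSE)
    }
  }
  list(species_totals = do.call(rbind, out), n_species = nrow(counts))
}

#' Group-level patch and species summaries
#'
#' For each light-level group: number of species, patches measured, the
#' percentage of patches dichromatic at ΔS >= 1.0 (per scenario), the
#' percentage of dichromatic species at each threshold, and — when raw ΔS
#' records are supplied — the mean and SD of the per-patch ΔS values.
#'
#' @param counts Per-species counts (see [species_dichromatism_totals()])
#'   with a `light_level` column.
#' @param records Optional raw output of [patch_deltaS_table()] for the
#'   mean/SD columns.
#' @param thresholds Thresholds matching the count columns.
#' @param mean_scenario Scenario whose per-patch ΔS values feed the mean/SD
#'   (all patches, not only dichromatic ones).
#' @return Data.frame with one row per light level (ordered low,
#'   intermediate, high) per scenario.
#' @export
group_patch_summary <- function(counts, records = NULL,
                                thresholds = c(1.0, 1.5, 2.0),
                                mean_scenario = "ideal") {
  if (any(is.na(counts$light_level))) {
    stop("mapping error: species without a light level", call. = FALSE)
  }
  lvls <- intersect(c("low", "intermediate", "high"),
                    unique(counts$light_level))
  cols <- grep("^n_(?!patches)", names(counts), value = TRUE, perl = TRUE)
  scen <- unique(sub("^n_([^_]+)_.*$", "\\1", cols))
  rows <- list()
  for (sc in scen) {
    for (lv in lvls) {
      d <- counts[counts$light_level == lv, , drop = FALSE]
      npat <- sum(d$n_patches_measured)
      c10 <- sprintf("n_%s_%s", sc, format(thresholds[1]))
      row <- data.frame(
        scenario = sc, light_level = lv, n_species = nrow(d),
        n_patches = npat,
        pct_dichromatic_patches = round(100 * sum(d[[c10]]) / npat, 1),
        stringsAsFactors = FALSE)
      for (th in thresholds) {
        cn <- sprintf("n_%s_%s", sc, format(th))
        row[[sprintf("pct_species_%s", format(th))]] <-
          round(100 * sum(d[[cn]] >= 1L) / nrow(d), 1)
      }
      if (!is.null(records)) {
        vcol <- paste0("deltaS_", mean_scenario)
        v <- records[[vcol]][records$light_level == lv]
        row$mean_jnd <- mean(v)
        row$sd_jnd <- stats::sd(v)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-way blocked ANOVA with Tukey post hoc comparisons
#'
#' Additive two-factor analysis of variance (factor of interest + blocking
#' factor, no interaction) with Type-II sums of squares, followed by Tukey
#' HSD comparisons of the factor means and a compact letter display.
#'
#' @param values Numeric response (e.g. per-patch ΔS in jnd).
#' @param factor_ Factor of interest (e.g. light-level group or patch).
#' @param block Optional blocking factor; `NULL` gives a one-way ANOVA.
#' @param level Significance level for letters (default 0.05).
#' @return List with `F`, `p` (for the factor of interest), the full `anova`
#'   table, the `tukey` comparison table, and `letters` (groups sharing a
#'   letter are not significantly different).
#' @export
blocked_anova_tukey <- function(values, factor_, block = NULL, level = 0.05) {
  f <- factor(factor_)
  if (nlevels(f) < 2L) stop("need >= 2 factor levels", call. = FALSE)
  if (any(table(f) < 2L)) {
    stop("insufficient-data error: a factor level has < 2 observations",
         call. = FALSE)
  }
  dat <- data.frame(y = as.numeric(values), f = f)
  if (!is.null(block)) {
    dat$b <- factor(block)
    fit <- stats::aov(y ~ f + b, data = dat)
  } else {
    fit <- stats::aov(y ~ f, data = dat)
  }
  # drop1 gives each term adjusted for the other: Type-II SS for the
  # additive model
  d1 <- stats::drop1(fit, test = "F")
  Fv <- d1["f", "F value"]
  pv <- d1["f", "Pr(>F)"]
  tk <- stats::TukeyHSD(fit, which = "f")$f
  letters <- tukey_letters(tk, levels(f), level = level)
  list(F = Fv, p = pv, anova = d1, tukey = as.data.frame(tk),
       letters = letters)
}

# Compact letter display via insert-and-absorb on the Tukey p-value matrix.
tukey_letters <- function(tukey_tab, lev, level = 0.05) {
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (cmp in rownames(tukey_tab)) {
    pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    if (length(pair) != 2L) next
    if (tukey_tab[cmp, "p adj"] < level) {
      sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- TRUE
    }
  }
  groups <- list(lev)  # candidate letter groups
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (g in seq_along(groups)) {
        if (all(c(lev[i], lev[j]) %in% groups[[g]])) {
          groups <- c(groups, list(setdiff(groups[[g]], lev[i])),
                      list(setdiff(groups[[g]], lev[j])))
          groups[g] <- NULL
          break
        }
      }
    }
  }
  # absorb subsets
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (a != b && keep[a] && all(groups[[a]] %in% groups[[b]]) &&
          length(groups[[a]]) < length(groups[[b]])) keep[a] <- FALSE
    }
  }
  groups <- unique(groups[keep])
  groups <- groups[order(vapply(groups, function(g) min(match(g, lev)),
                                numeric(1)))]
  out <- stats::setNames(rep("", k), lev)
  for (g in seq_along(groups)) {
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  }
  out
}

#' Cross-illuminant audit of dichromatism classifications
#'
#' Reruns the threshold classification under every habitat illuminant and
#' flags species whose dichromatic/monochromatic status (>= 1 patch at
#' ΔS >= 1.0) changes across illuminants — the check that von Kries color
#' constancy makes illuminant choice immaterial.
#'
#' @param records Output of [patch_deltaS_table()] computed with scenarios
#'   including `forest_shade`, `d65`, and `blue_sky`.
#' @param threshold Classification threshold (default 1.0 jnd).
#' @return Data.frame per species: dichromatic patch count under each
#'   illuminant and a `status_changes` flag.
#' @export
cross_illuminant_audit <- function(records, threshold = 1.0) {
  sc_cols <- grep("^deltaS_", names(records), value = TRUE)
  rows <- lapply(split(records, records$species), function(d) {
    counts <- vapply(sc_cols, function(cn) sum(d[[cn]] >= threshold),
                     integer(1))
    names(counts) <- paste0("n_", sub("^deltaS_", "", sc_cols))
    status <- counts >= 1L
    cbind(data.frame(species = d$species[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(status_changes = length(unique(status)) > 1L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Patch-frequency breakdown by body region
#'
#' Proportion of dichromatic patches and mean jnd of dichromatic patches per
#' patch type. Facial marks are excluded here (they are not homologous body
#' regions across species) but remain in all species-level counts.
#'
#' @param records Output of [patch_deltaS_table()].
#' @param scenario Scenario column to use.
#' @param threshold Dichromatism threshold.
#' @return Data.frame per patch type.
#' @export
patch_frequency_summary <- function(records, scenario = "ideal",
                                    threshold = 1.0) {
  vcol <- paste0("deltaS_", scenario)
  d <- records[records$patch != "facial_mark", , drop = FALSE]
  rows <- lapply(split(d, d$patch), function(x) {
    dich <- x[[vcol]] >= threshold
    data.frame(patch = x$patch[1], n = nrow(x),
               pct_dichromatic = round(100 * mean(dich), 1),
               mean_jnd_dichromatic = if (any(dich)) mean(x[[vcol]][dich])
                                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
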