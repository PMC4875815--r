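#' Build a run configuration
#'
#' A single configuration drives the whole analysis. Paths may be omitted
#' when the corresponding stage is skipped (e.g. no `tree` when no
#' evolutionary models are requested).
#'
#' @param spectra Path to the long-format reflectance CSV.
#' @param regimes Path to the tip-to-light-level TSV.
#' @param tree Path to the Newick phylogeny (required when `models` given).
#' @param illuminants Optional named list of CSV paths overriding built-in
#'   illuminants.
#' @param visual Optional list overriding [visual_system()] arguments
#'   (`peaks`, `densities`, `weber`).
#' @param scenarios Illuminant scenarios for the ΔS tables.
#' @param thresholds Ascending dichromatism thresholds (jnd).
#' @param descriptors Descriptor columns to model.
#' @param models Evolutionary models to fit (empty to skip).
#' @param bootstrap_reps Bootstrap replicates for the selected models.
#' @param seed Run seed.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spectra, regimes, tree = NULL, illuminants = NULL,
                       visual = list(),
                       scenarios = c("ideal", "real", "forest_shade", "d65",
                                     "blue_sky"),
                       thresholds = c(1.0, 1.5, 2.0),
                       descriptors = c("avg_span", "var_span", "volume",
                                       "avg_chroma", "max_chroma",
                                       "brightness"),
                       models = c("BM", "OU1", "OU_regimes"),
                       bootstrap_reps = 10000L,
                       seed = 1L,
                       out_dir = "plumalight_out") {
  cfg <- list(spectra = spectra, regimes = regimes, tree = tree,
              illuminants = illuminants, visual = visual,
              scenarios = scenarios, thresholds = sort(thresholds),
              descriptors = descriptors, models = models,
              bootstrap_reps = as.integer(bootstrap_reps),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

validate_run_config <- function(cfg) {
  for (field in c("spectra", "regimes")) {
    if (is.null(cfg[[field]])) {
      stop("configuration error: missing required field '", field, "'",
           call. = FALSE)
    }
    if (!file.exists(cfg[[field]])) {
      stop("configuration error: '", field, "' file not found: ",
           cfg[[field]], call. = FALSE)
    }
  }
  if (length(cfg$models) && is.null(cfg$tree)) {
    stop("configuration error: field 'tree' required when models requested",
         call. = FALSE)
  }
  if (!is.null(cfg$tree) && !file.exists(cfg$tree)) {
    stop("configuration error: 'tree' file not found: ", cfg$tree,
         call. = FALSE)
  }
  if (is.unsorted(cfg$thresholds)) {
    stop("configuration error: thresholds must be ascending", call. = FALSE)
  }
  invisible(cfg)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis
#'
#' Sequences every stage from one configuration: read and aggregate spectra,
#' per-patch ΔS tables under all requested scenarios, threshold and group
#' summaries, the cross-illuminant audit, the blocked ANOVA, species color
#' descriptors, and (when a tree is configured) BM/OU model fits with AICc
#' selection and parametric-bootstrap intervals for the selected models.
#' All tables are written as TSV, plus a `run.log` recording the seed and
#' every setting in force. On any stage failure, partial outputs are removed
#' and the error is re-raised with the stage name.
#'
#' @param config A `run_config`, or a path to a YAML config file.
#' @return Invisible list of the result tables.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- c(sprintf("plumalight %s",
                         as.character(utils::packageVersion("plumalight"))),
                 sprintf("R %s", R.version.string),
                 sprintf("seed: %d", config$seed),
                 sprintf("scenarios: %s", paste(config$scenarios,
                                                collapse = ",")),
                 sprintf("thresholds: %s", paste(config$thresholds,
                                                 collapse = ",")),
                 sprintf("models: %s", paste(config$models, collapse = ",")),
                 sprintf("bootstrap_reps: %d", config$bootstrap_reps),
                 "conventions: sex-mean spectra; inclusive thresholds (>=);",
                 "  ideal illuminant+background for descriptors; sexes",
                 "  combined by averaging descriptor values; population",
                 "  variance for var_span; group mean jnd over all patches")
  stage <- "setup"
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  out <- tryCatch({
    stage <- "spectra_io"
    gm <- read_regime_map(config$regimes)
    coll <- read_spectra_table(config$spectra, group_map = gm)
    vs <- do.call(visual_system, config$visual)
    for (f in c("spectra", "regimes", "tree")) {
      if (!is.null(config[[f]])) {
        log_lines <- c(log_lines, sprintf(
          "%s: %s (md5 %s)", f, config[[f]],
          tools::md5sum(config[[f]])[[1]]))
      }
    }

    stage <- "dichromatism"
    records <- patch_deltaS_table(coll, vs, scenarios = config$scenarios)
    counts <- threshold_summary(records, thresholds = config$thresholds)
    totals <- species_dichromatism_totals(counts, config$thresholds)
    groups <- group_patch_summary(counts, records, config$thresholds)
    audit_cols <- intersect(config$scenarios,
                            c("forest_shade", "d65", "blue_sky"))
    audit <- if (length(audit_cols) >= 2) cross_illuminant_audit(records)
    patch_freq <- patch_frequency_summary(records)
    vcol <- paste0("deltaS_", intersect(c("ideal", config$scenarios),
                                        config$scenarios)[1])
    anova_groups <- blocked_anova_tukey(records[[vcol]],
                                        records$light_level,
                                        block = records$patch)
    anova_patches <- blocked_anova_tukey(
      records[[vcol]][records$patch != "facial_mark"],
      records$patch[records$patch != "facial_mark"],
      block = records$light_level[records$patch != "facial_mark"])

    written <- c(written, .write_tsv(counts,
                                     file.path(config$out_dir, "table1.tsv")))
    written <- c(written, .write_tsv(groups,
                                     file.path(config$out_dir, "table2.tsv")))
    written <- c(written, .write_tsv(patch_freq,
                                     file.path(config$out_dir, "tableS1.tsv")))
    if (!is.null(audit)) {
      written <- c(written, .write_tsv(audit,
                                       file.path(config$out_dir,
                                                 "tableS2.tsv")))
    }
    anova_df <- data.frame(
      analysis = c("groups_blocked_by_patch", "patches_blocked_by_group"),
      F = c(anova_groups$F, anova_patches$F),
      p = c(anova_groups$p, anova_patches$p),
      letters = c(paste(names(anova_groups$letters), anova_groups$letters,
                        sep = "=", collapse = ";"),
                  paste(names(anova_patches$letters), anova_patches$letters,
                        sep = "=", collapse = ";")))
    written <- c(written, .write_tsv(anova_df,
                                     file.path(config$out_dir, "anova.tsv")))

    stage <- "descriptors"
    desc <- species_descriptors(coll, vs)
    desc_out <- desc[, c("species", "avg_span", "var_span", "volume",
                         "avg_chroma", "max_chroma", "brightness")]
    written <- c(written, .write_tsv(desc_out,
                                     file.path(config$out_dir,
                                               "descriptors.tsv")))

    fits_out <- NULL
    params_out <- NULL
    if (length(config$models) && !is.null(config$tree)) {
      stage <- "phylo_comparative"
      tree <- read_newick(config$tree)
      painting <- paint_regimes(tree, gm)
      comp_rows <- list()
      par_rows <- list()
      for (d in intersect(config$descriptors, names(desc_out))) {
        tr <- stats::setNames(desc_out[[d]], desc_out$species)
        fits <- list()
        if ("BM" %in% config$models) fits$BM <- fit_evol(tree, tr, "BM")
        if ("OU1" %in% config$models) fits$OU1 <- fit_evol(tree, tr, "OU1")
        if ("OU_regimes" %in% config$models) {
          fits$OU_regimes <- fit_evol(tree, tr, "OU_regimes",
                                      painting = painting)
        }
        sel <- select_model(fits)
        comp_rows[[d]] <- cbind(
          data.frame(descriptor = d, stringsAsFactors = FALSE),
          as.data.frame(as.list(round(sel$delta_aicc, 2))),
          data.frame(selected = sel$selected))
        bt <- parametric_bootstrap(fits[[sel$selected]],
                                   reps = config$bootstrap_reps,
                                   seed = config$seed)
        ci <- bt$ci
        par_rows[[d]] <- data.frame(
          descriptor = d, model = sel$selected,
          parameter = colnames(ci),
          estimate = ci["estimate", ], lower = ci["lower", ],
          upper = ci["upper", ], row.names = NULL)
      }
      fits_out <- do.call(rbind, comp_rows)
      params_out <- do.call(rbind, par_rows)
      rownames(fits_out) <- rownames(params_out) <- NULL
      written <- c(written,
                   .write_tsv(fits_out, file.path(config$out_dir,
                                                  "model_comparison.tsv")),
                   .write_tsv(params_out, file.path(config$out_dir,
                                                    "parameters.tsv")))
    }

    stage <- "log"
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    list(counts = counts, totals = totals, groups = groups,
         patch_freq = patch_freq, audit = audit,
         anova = anova_df, descriptors = desc_out,
         model_comparison = fits_out, parameters = params_out,
         records = records)
  }, error = on_fail)
  invisible(out)
}
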