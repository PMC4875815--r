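# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

vs_default <- function() memo("vs", function() visual_system())

# small 6-species study (2 per light level) for fast pipeline/unit tests
tiny_spec <- function(seed = 11) {
  study_fixture_spec(
    n_species = c(low = 2, intermediate = 2, high = 2),
    patch_range = c(5, 6), specimen_range = c(3, 3),
    seed = seed)
}

tiny_fixture <- function() memo("tiny_fx", function() {
  make_study_fixture(tiny_spec())
})

# the full 33-species default fixture (the emulated study design)
fixture33 <- function() memo("fx33", function() {
  make_study_fixture(study_fixture_spec(seed = 1))
})

# a smooth brown test spectrum distinct from the generator path
ramp_spectrum <- function(base = 0.1, amp = 0.2, infl = 600, width = 40,
                          grid = canonical_grid()) {
  reflectance_spectrum(grid, base + amp / (1 + exp(-(grid - infl) / width)))
}

# independent evaluation of the receptor-noise distance: minimize the
# noise-scaled distance over the achromatic offset (projection route,
# no use of the six-term closed form)
rnl_distance_oracle <- function(df, e) {
  sqrt(stats::optimize(function(cc) sum((df - cc)^2 / e^2),
                       interval = range(df) + c(-1, 1),
                       tol = 1e-12)$objective)
}

# noiseless template for exact-arithmetic dichromatism cases
noiseless_template <- function(..., seed = 1) {
  species_template(..., specimen_scale_sd = 0, specimen_tilt_sd = 0,
                   replicate_sd = 0, seed = seed)
}

# build a replicate-level collection directly from templates
collection_from_templates <- function(templates, group_map = NULL,
                                      n_specimens = 2, replicates = 2,
                                      seed = 1) {
  records <- list()
  for (tpl in templates) {
    for (sx in c("M", "F")) {
      for (id in seq_len(n_specimens)) {
        for (p in tpl$patches) {
          for (r in seq_len(replicates)) {
            records[[length(records) + 1L]] <-
              make_drab_spectrum(tpl, p, sx, id, r, seed = seed)
          }
        }
      }
    }
  }
  spectrum_collection(records, group_map = group_map)
}
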