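test_that("identical sexes give zero distances in every scenario", {
  tpl <- noiseless_template(species = "mono", patches = c("throat", "back"))
  coll <- collection_from_templates(list(tpl),
                                    group_map = c(mono = "low"),
                                    n_specimens = 2, replicates = 2)
  rec <- patch_deltaS_table(coll, vs_default(),
                            scenarios = c("ideal", "real", "d65"))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$deltaS_ideal, c(0, 0))
  expect_equal(rec$deltaS_real, c(0, 0))
  expect_equal(rec$deltaS_d65, c(0, 0))
})

test_that("an injected chromatic contrast is recovered near its target", {
  vs <- vs_default()
  tpl <- noiseless_template(species = "dich", patches = c("throat", "back"))
  shift <- calibrate_sex_shift(tpl, 1.5, vs, patch = "throat")
  tpl$sex_shift_nm[["throat"]] <- shift
  coll <- collection_from_templates(list(tpl), group_map = c(dich = "high"))
  rec <- patch_deltaS_table(coll, vs, scenarios = "ideal")
  expect_equal(names(rec)[grep("deltaS", names(rec))], "deltaS_ideal")
  got <- rec$deltaS_ideal[rec$patch == "throat"]
  expect_lt(abs(got - 1.5) / 1.5, 0.05)
  expect_equal(rec$deltaS_ideal[rec$patch == "back"], 0)
})

test_that("species missing a sex are skipped with a warning", {
  tpl <- noiseless_template(species = "solo", patches = c("throat", "back"))
  g <- canonical_grid()
  males_only <- lapply(tpl$patches, function(p)
    make_drab_spectrum(tpl, p, "M", 1, 1, seed = 1))
  tpl2 <- noiseless_template(species = "ok", patches = c("throat", "back"))
  both <- collection_from_templates(list(tpl2))$records
  coll <- spectrum_collection(c(males_only, both),
                              group_map = c(solo = "low", ok = "low"))
  expect_warning(rec <- patch_deltaS_table(coll, vs_default(), "ideal"),
                 "missing one sex")
  expect_equal(unique(rec$species), "ok")
})

test_that("threshold counts use inclusive comparison and stay monotone", {
  rec <- data.frame(species = rep("sp", 4), light_level = "low",
                    patch = c("throat", "back", "rump", "tail"),
                    deltaS_ideal = c(0.99, 1.0, 1.5, 2.3))
  cnt <- threshold_summary(rec)
  expect_equal(cnt$n_patches_measured, 4L)
  expect_equal(cnt$n_ideal_1, 3L)     # 0.99 excluded, 1.0 included
  expect_equal(cnt$n_ideal_1.5, 2L)
  expect_equal(cnt$n_ideal_2, 1L)
  expect_true(cnt$dichromatic_ideal_2)

  all_sub <- rec
  all_sub$deltaS_ideal <- rep(0.99, 4)
  cnt0 <- threshold_summary(all_sub)
  expect_equal(cnt0$n_ideal_1 + cnt0$n_ideal_1.5 + cnt0$n_ideal_2, 0L)
  expect_false(cnt0$dichromatic_ideal_1)
})

test_that("counts on the fixture are monotone in threshold and sum by group", {
  fx <- tiny_fixture()
  rec <- patch_deltaS_table(fx$collection, vs_default(),
                            scenarios = c("ideal", "real"))
  cnt <- threshold_summary(rec)
  for (sc in c("ideal", "real")) {
    n1 <- cnt[[paste0("n_", sc, "_1")]]
    n15 <- cnt[[paste0("n_", sc, "_1.5")]]
    n2 <- cnt[[paste0("n_", sc, "_2")]]
    expect_true(all(n1 >= n15 & n15 >= n2))
    expect_true(all(n1 <= cnt$n_patches_measured))
  }
  gp <- group_patch_summary(cnt, rec)
  # group patch totals add up to the collection-wide patch count
  expect_equal(sum(gp$n_patches[gp$scenario == "ideal"]), nrow(rec))
  expect_equal(sum(gp$n_species[gp$scenario == "ideal"]),
               length(unique(rec$species)))
})

test_that("published per-species counts aggregate to the reported totals", {
  cnt <- furnariides_reference("patch_counts")
  tot <- species_dichromatism_totals(cnt)$species_totals
  get <- function(sc, th, col) tot[tot$scenario == sc & tot$threshold == th,
                                   col]
  expect_equal(get("real", 1.0, "n_dichromatic_species"), 27)
  expect_equal(get("real", 1.0, "pct_dichromatic_species"), 81.8)
  expect_equal(get("real", 1.5, "n_dichromatic_species"), 16)
  expect_equal(get("real", 2.0, "n_dichromatic_species"), 9)
  expect_equal(get("ideal", 1.0, "n_dichromatic_species"), 27)
  expect_equal(get("ideal", 1.5, "n_dichromatic_species"), 18)
  expect_equal(get("ideal", 2.0, "n_dichromatic_species"), 10)

  gp <- group_patch_summary(cnt)
  real <- gp[gp$scenario == "real", ]
  expect_equal(real$n_species, c(4, 18, 11))
  expect_equal(real$n_patches, c(37, 144, 91))
  expect_equal(real$pct_dichromatic_patches, c(37.8, 20.1, 52.7))
  expect_equal(real$pct_species_1, c(100, 77.8, 81.8))
  expect_equal(real$pct_species_1.5, c(75, 22.2, 81.8))
  expect_equal(real$pct_species_2, c(25, 11.1, 54.5))
})

test_that("blocked ANOVA matches hand computation and letters separate shifts", {
  # equal means, spread within groups: no factor effect
  set.seed(2)
  y <- c(rnorm(10, 5, 1), rnorm(10, 5, 1))
  f <- rep(c("a", "b"), each = 10)
  res <- blocked_anova_tukey(y, f)
  expect_gt(res$p, 0.3)
  expect_equal(unname(res$letters["a"]), unname(res$letters["b"]))

  # textbook one-way case {1,2,3} vs {4,5,6}: F = 13.5
  res2 <- blocked_anova_tukey(c(1, 2, 3, 4, 5, 6),
                              rep(c("a", "b"), each = 3))
  expect_equal(unname(res2$F), 13.5)
  expect_equal(unname(res2$p), pf(13.5, 1, 4, lower.tail = FALSE))

  # a clearly shifted third group earns its own letter
  set.seed(9)
  y3 <- c(rnorm(12, 0, 1), rnorm(12, 0.3, 1), rnorm(12, 10, 1))
  f3 <- rep(c("a", "b", "c"), each = 12)
  b3 <- rep(rep(c("x", "y"), 6), 3)
  res3 <- blocked_anova_tukey(y3, f3, block = b3)
  expect_lt(res3$p, 1e-6)
  expect_equal(unname(res3$letters["a"]), unname(res3$letters["b"]))
  expect_false(res3$letters[["c"]] %in% res3$letters[c("a", "b")])

  expect_error(blocked_anova_tukey(1:3, c("a", "a", "b")),
               "insufficient-data")
})

test_that("cross-illuminant audit is stable under von Kries constancy", {
  # identical sexes: zeros everywhere, no flags
  tpl <- noiseless_template(species = "mono", patches = c("throat", "back"))
  coll <- collection_from_templates(list(tpl), group_map = c(mono = "low"))
  rec <- patch_deltaS_table(coll, vs_default(),
                            scenarios = c("forest_shade", "d65", "blue_sky"))
  aud <- cross_illuminant_audit(rec)
  expect_equal(aud$n_forest_shade + aud$n_d65 + aud$n_blue_sky, 0L)
  expect_false(any(aud$status_changes))

  # pure intensity dimorphism (female = k x male) is invisible everywhere
  tpl2 <- noiseless_template(species = "scl", patches = c("throat", "back"),
                             sex_scale = 1.3)
  coll2 <- collection_from_templates(list(tpl2), group_map = c(scl = "high"))
  rec2 <- patch_deltaS_table(coll2, vs_default(),
                             scenarios = c("ideal", "forest_shade", "d65",
                                           "blue_sky"))
  expect_true(all(abs(as.matrix(rec2[grep("deltaS", names(rec2))])) < 1e-9))

  # moderate chromatic dimorphism: classification identical across illuminants
  fx <- tiny_fixture()
  rec3 <- patch_deltaS_table(fx$collection, vs_default(),
                             scenarios = c("forest_shade", "d65", "blue_sky"))
  aud3 <- cross_illuminant_audit(rec3)
  expect_lte(sum(aud3$status_changes), 1L)
})

test_that("facial marks are excluded from the body-region breakdown only", {
  rec <- data.frame(
    species = rep(c("s1", "s2"), each = 3), light_level = "low",
    patch = rep(c("throat", "back", "facial_mark"), 2),
    deltaS_ideal = c(1.2, 0.4, 2.0, 1.6, 0.2, 3.0))
  pf <- patch_frequency_summary(rec)
  expect_false("facial_mark" %in% pf$patch)
  expect_equal(pf$pct_dichromatic[pf$patch == "throat"], 100)
  expect_equal(pf$pct_dichromatic[pf$patch == "back"], 0)
  # but facial marks still count toward the species-level summary
  cnt <- threshold_summary(rec)
  expect_equal(cnt$n_patches_measured, c(3L, 3L))
  expect_equal(cnt$n_ideal_2, c(1L, 1L))
})
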