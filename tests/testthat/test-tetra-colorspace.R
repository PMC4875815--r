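test_that("relative catches normalize and reject degenerate stimuli", {
  expect_equal(unname(relative_catches(c(1, 1, 1, 1))), rep(0.25, 4))
  expect_equal(unname(relative_catches(c(2, 2, 2, 2))), rep(0.25, 4))
  set.seed(3)
  for (i in 1:20) {
    q <- runif(4, 0.01, 5)
    expect_equal(sum(relative_catches(q)), 1)
  }
  expect_error(relative_catches(c(0, 1, 1, 1)), "degenerate-stimulus")
})

test_that("tetrahedral mapping places the achromatic point and vertices", {
  origin <- tetra_point(rep(0.25, 4))
  expect_equal(unname(origin$xyz), c(0, 0, 0))
  expect_equal(origin$r, 0)

  # substitution oracle for each pure-cone vertex
  s6 <- sqrt(3 / 2) / 2
  s8 <- 1 / (2 * sqrt(2))
  verts <- list(
    u = list(usml = c(1, 0, 0, 0), xyz = c(0, 0, 0.75)),
    s = list(usml = c(0, 1, 0, 0), xyz = c(-s6, -s8, -0.25)),
    m = list(usml = c(0, 0, 1, 0), xyz = c(0, 2 * s8, -0.25)),
    l = list(usml = c(0, 0, 0, 1), xyz = c(s6, -s8, -0.25)))
  for (v in verts) {
    p <- tetra_point(v$usml)
    expect_equal(unname(p$xyz), v$xyz, tolerance = 1e-12)
    expect_equal(p$r, 0.75, tolerance = 1e-12)
  }
  expect_error(tetra_point(c(0.5, 0.5, 0.5, 0.5)), "domain error")
})

test_that("every valid point stays inside the tetrahedron with chroma <= 0.75", {
  verts <- do.call(rbind, lapply(list(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                      c(0, 0, 1, 0), c(0, 0, 0, 1)),
                                 function(v) tetra_point(v)$xyz))
  v_full <- hull_volume(verts)
  set.seed(8)
  for (i in 1:50) {
    w <- rexp(4)
    p <- tetra_point(w / sum(w))
    expect_lte(p$r, 0.75 + 1e-9)
    # adding an interior point must not enlarge the vertex hull
    expect_equal(hull_volume(rbind(verts, p$xyz)), v_full, tolerance = 1e-9)
  }
})

test_that("brightness is the arithmetic mean reflectance", {
  g <- canonical_grid()
  expect_equal(brightness(reflectance_spectrum(g, rep(0.2, 401))), 0.2)
  expect_equal(brightness(reflectance_spectrum(g, (0:400) / 400)), 0.5)
  set.seed(4)
  y <- runif(401, 0, 1)
  expect_equal(brightness(reflectance_spectrum(g, y)), sum(y) / 401)
})

test_that("hull volume matches closed forms and handles degeneracy", {
  expect_equal(hull_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))), 0)
  # unit-edge regular tetrahedron: a^3 / (6 sqrt(2))
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(hull_volume(tet), 1 / (6 * sqrt(2)), tolerance = 1e-9)
  # color-space vertex set (circumradius 0.75): a = 0.75 sqrt(8/3)
  verts <- do.call(rbind, lapply(list(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                      c(0, 0, 1, 0), c(0, 0, 0, 1)),
                                 function(v) tetra_point(v)$xyz))
  a <- 0.75 * sqrt(8 / 3)
  expect_equal(hull_volume(verts), a^3 / (6 * sqrt(2)), tolerance = 1e-9)
  # coplanar quad and duplicated vertices are degenerate / neutral
  expect_equal(hull_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(1, 1, 0))), 0)
  expect_equal(hull_volume(rbind(tet, tet[1, , drop = FALSE])),
               1 / (6 * sqrt(2)), tolerance = 1e-9)
  # a quad-faced solid: the unit cube
  expect_equal(hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1))), 1,
               tolerance = 1e-9)
})

test_that("plumage summary reproduces hand-computed span statistics", {
  g <- canonical_grid()
  flat <- reflectance_spectrum(g, rep(0.2, 401))
  p0 <- tetra_point(rep(0.25, 4))
  expect_error(plumage_summary(list(p0), list(flat)), "span undefined")

  two_same <- plumage_summary(list(p0, p0), list(flat, flat))
  expect_equal(two_same$avg_span, 0)
  expect_equal(two_same$var_span, 0)

  # three synthetic points with pairwise distances {3, 4, 5}
  fake_point <- function(xyz) {
    structure(list(usml = rep(0.25, 4), xyz = xyz, r = sqrt(sum(xyz^2)),
                   meta = list()), class = "color_point")
  }
  tri <- list(fake_point(c(0, 0, 0)), fake_point(c(3, 0, 0)),
              fake_point(c(0, 4, 0)))
  s <- plumage_summary(tri, list(flat, flat, flat))
  expect_equal(s$avg_span, 4)
  expect_equal(s$var_span, 2 / 3)  # population variance
  expect_gte(s$max_chroma, s$avg_chroma)
  expect_equal(s$brightness, 0.2)
})

test_that("descriptors are patch-order invariant and in drab magnitudes", {
  fx <- tiny_fixture()
  d <- species_descriptors(fx$collection, vs_default())
  expect_equal(nrow(d), 6L)
  expect_true(all(d$max_chroma >= d$avg_chroma))
  # magnitude envelope of drab plumages (sanity band, not equality)
  expect_true(all(d$avg_span > 0.005 & d$avg_span < 0.12))
  expect_true(all(d$volume > 1e-9 & d$volume < 1e-4))
  expect_true(all(d$brightness > 0.08 & d$brightness < 0.30))

  # reversing record order changes nothing
  coll <- fx$collection
  rev_coll <- spectrum_collection(rev(coll$records), coll$group_map)
  d2 <- species_descriptors(rev_coll, vs_default())
  d2 <- d2[match(d$species, d2$species), ]
  expect_equal(d$avg_span, d2$avg_span)
  expect_equal(d$volume, d2$volume)
})

test_that("pooling sexes is available and differs from descriptor averaging", {
  fx <- tiny_fixture()
  d_avg <- species_descriptors(fx$collection, vs_default(), combine = "average")
  d_pool <- species_descriptors(fx$collection, vs_default(), combine = "pool")
  expect_equal(d_avg$species, d_pool$species)
  # pooled cloud spans at least each sex's own hull
  by_sex <- attr(d_pool, "by_sex")
  for (i in seq_len(nrow(d_pool))) {
    expect_gte(d_pool$volume[i] + 1e-12,
               max(by_sex$volume[by_sex$species == d_pool$species[i]]))
  }
})
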