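test_that("Newick reading validates structure and round-trips", {
  t1 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(attr(t1, "depth"), 2)
  expect_true(attr(t1, "ultrametric"))

  t2 <- read_newick("((A:1,B:2):1,C:2);")
  expect_false(attr(t2, "ultrametric"))

  expect_error(read_newick("((A:1,B:1):1,A:2);"), "duplicate tip")
  expect_error(read_newick("((A,B),C);"), "branch lengths")

  tr <- simulate_yule_tree(12, seed = 6)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
})

test_that("parsimony painting follows Fitch with documented tie-breaks", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  # all tips low: every branch low
  p_all <- paint_regimes(tr, c(A = "low", B = "low", C = "low"))
  expect_true(all(p_all$edge_regime == "low"))

  # cherry (A,B)=low sister to C=high: cherry stem painted low
  p <- paint_regimes(tr, c(A = "low", B = "low", C = "high"))
  cherry_mrca <- ape::getMRCA(tr, c("A", "B"))
  stem_edge <- which(tr$edge[, 2] == cherry_mrca)
  expect_equal(p$edge_regime[stem_edge], "low")
  # root set {low, high} resolves to "low" by the fixed order
  expect_equal(p$root_state, "low")

  two <- read_newick("(A:1,B:1);")
  p2 <- paint_regimes(two, c(A = "low", B = "high"))
  expect_equal(p2$root_state, "low")

  expect_error(paint_regimes(tr, c(A = "low", B = "low")), "unmapped tip")
})

test_that("BM fit matches iid closed forms on a star tree", {
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:15), collapse = ","), ");"))
  set.seed(12)
  y <- setNames(rnorm(15, 3, 1.5), star$tip.label)
  f <- fit_evol(star, y, "BM")
  expect_equal(f$params$z0, mean(y))
  expect_equal(f$params$sigma2, mean((y - mean(y))^2))
  expect_equal(f$lnL, sum(dnorm(y, mean(y), sqrt(mean((y - mean(y))^2)),
                                log = TRUE)))
  expect_equal(f$k, 2L)
  expect_equal(f$AICc, aicc(f$lnL, 2, 15))

  # constant traits: boundary fit reported, not a crash
  f0 <- fit_evol(star, setNames(rep(1, 15), star$tip.label), "BM")
  expect_true(f0$boundary)
  expect_lt(f0$params$sigma2, 1e-12)
})

test_that("two-tip BM likelihood equals the direct bivariate-normal density", {
  tr <- read_newick("(A:1.5,B:1.5);")
  y <- c(A = 0.3, B = 1.1)
  f <- fit_evol(tr, y, "BM")
  C <- f$params$sigma2 * ape::vcv(tr)
  d <- y - f$params$z0
  lnL_direct <- -0.5 * (2 * log(2 * pi) + determinant(C)$modulus[1] +
                          drop(d %*% solve(C, d)))
  expect_equal(f$lnL, lnL_direct, tolerance = 1e-9)
})

test_that("OU collapses to BM as alpha -> 0 and to OU1 with equal optima", {
  tr <- simulate_yule_tree(16, seed = 3)
  y <- setNames(drop(simulate_traits(tr, "BM", list(sigma2 = 0.4, z0 = 1),
                                     seed = 5)), tr$tip.label)
  bm <- fit_evol(tr, y, "BM")

  # evaluate the OU1 likelihood at near-zero alpha via the model moments
  lnL_at <- function(model, params, painting = NULL) {
    fit <- structure(list(model = model, params = params, tree = tr,
                          n = 16L, painting = painting), class = "evo_fit")
    mo <- evo_moments(fit)
    d <- y - mo$mean
    drop(-0.5 * (16 * log(2 * pi) + determinant(mo$V)$modulus[1] +
                   d %*% solve(mo$V, d)))
  }
  lnL_ou_small <- lnL_at("OU1", list(alpha = 1e-8, sigma2 = bm$params$sigma2,
                                     theta = bm$params$z0))
  expect_equal(lnL_ou_small, bm$lnL, tolerance = 1e-3)

  # equal-theta regime model has identical likelihood to OU1
  gm <- setNames(rep(c("low", "intermediate", "high"), length.out = 16),
                 tr$tip.label)
  pt <- paint_regimes(tr, gm)
  prm1 <- list(alpha = 2.5, sigma2 = 0.3, theta = 0.8)
  prmR <- list(alpha = 2.5, sigma2 = 0.3, theta_low = 0.8,
               theta_intermediate = 0.8, theta_high = 0.8)
  expect_equal(lnL_at("OU_regimes", prmR, pt), lnL_at("OU1", prm1),
               tolerance = 1e-6)

  # a painting with every branch in one regime reproduces the OU1 fit
  pt_one <- paint_regimes(tr, setNames(rep("low", 16), tr$tip.label))
  ou1 <- fit_evol(tr, y, "OU1")
  ouR <- fit_evol(tr, y, "OU_regimes", painting = pt_one)
  expect_equal(ouR$lnL, ou1$lnL, tolerance = 1e-6)

  expect_error(fit_evol(read_newick("((A:1,B:2):1,C:2);"),
                        c(A = 1, B = 2, C = 3), "OU1"),
               "ultrametric")
})

test_that("Hansen weights sum to one and covariance is SPD for any alpha", {
  tr <- simulate_yule_tree(20, seed = 13)
  gm <- setNames(sample(c("low", "intermediate", "high"), 20, replace = TRUE,
                        prob = c(0.3, 0.4, 0.3)),
                 tr$tip.label)
  pt <- paint_regimes(tr, gm)
  set.seed(21)
  for (a in c(1e-4, 0.1, 1, 4, 30, exp(runif(3, -6, 4)))) {
    W <- hansen_weights(tr, pt, a)
    expect_equal(unname(rowSums(W)), rep(1, 20), tolerance = 1e-12)
    V0 <- plumalight:::.ou_V0(plumalight:::.tree_geometry(tr), a)
    expect_silent(chol(V0))
  }
})

test_that("AICc arithmetic and domain are correct", {
  expect_equal(aicc(0, 2, 33), 4.4)
  expect_equal(aicc(0, 5, 33), 10 + 60 / 27)
  for (k in 2:5) expect_gt(aicc(-10, k, 20), -2 * (-10) + 2 * k)
  expect_error(aicc(0, 5, 6), "domain error")
})

test_that("the AICc ladder reproduces all published model selections", {
  tab <- furnariides_reference("delta_aicc")
  expected <- c("BM", "OU1", "BM", "BM", "OU1", "OU_regimes")
  for (i in seq_len(nrow(tab))) {
    d <- c(BM = tab$BM[i], OU1 = tab$OU1[i], OU_regimes = tab$OU_regimes[i])
    sel <- select_model_from_table(d, c(BM = tab$lrt_rejects_simpler[i]))
    expect_equal(sel$selected, expected[i], label = tab$descriptor[i])
    expect_equal(min(sel$delta_aicc), 0)
  }
})

test_that("fit-based selection picks the generating model at strong effects", {
  tr <- simulate_yule_tree(64, seed = 31)
  gm <- setNames(rep(c("low", "intermediate", "high"), length.out = 64),
                 tr$tip.label)
  pt <- paint_regimes(tr, gm)
  truth <- list(alpha = 4, sigma2 = 0.005, theta_low = 0.15,
                theta_intermediate = 0.19, theta_high = 0.22)
  y <- setNames(drop(simulate_traits(tr, "OU_regimes", truth, seed = 77,
                                     painting = pt)), tr$tip.label)
  fits <- list(BM = fit_evol(tr, y, "BM"),
               OU1 = fit_evol(tr, y, "OU1"),
               OU_regimes = fit_evol(tr, y, "OU_regimes", painting = pt))
  sel <- select_model(fits)
  expect_equal(sel$selected, "OU_regimes")

  # fits on different data are rejected
  y2 <- y + 1
  fits$BM <- fit_evol(tr, y2, "BM")
  expect_error(select_model(fits), "consistency error")
})

test_that("trait simulation honours parameters, seeds, and the OU stationary law", {
  tr <- simulate_yule_tree(10, seed = 2)
  z <- simulate_traits(tr, "BM", list(sigma2 = 0, z0 = 0.7), seed = 1)
  expect_equal(unname(drop(z)), rep(0.7, 10))

  s1 <- simulate_traits(tr, "BM", list(sigma2 = 0.2, z0 = 0), seed = 42)
  s2 <- simulate_traits(tr, "BM", list(sigma2 = 0.2, z0 = 0), seed = 42)
  expect_identical(s1, s2)

  # large alpha: tips fluctuate around regime optima with sd sqrt(s2/2a)
  gm <- setNames(rep(c("low", "high"), each = 5), tr$tip.label)
  pt <- paint_regimes(tr, gm, levels = c("low", "high"))
  prm <- list(alpha = 50, sigma2 = 0.5, theta_low = 0, theta_high = 1)
  draws <- simulate_traits(tr, "OU_regimes", prm, seed = 3, nsim = 1000,
                           painting = pt)
  sd_theory <- sqrt(prm$sigma2 / (2 * prm$alpha))
  low_tips <- names(gm)[gm == "low"]
  expect_equal(mean(draws[low_tips, ]), 0, tolerance = 0.01)
  expect_equal(sd(draws[low_tips[1], ]), sd_theory, tolerance = 0.06)
  expect_equal(mean(draws[setdiff(rownames(draws), low_tips), ]), 1,
               tolerance = 0.01)

  expect_error(simulate_traits(tr, "OU1",
                               list(alpha = -1, sigma2 = 1, theta = 0)),
               "domain error")
})

test_that("parametric bootstrap is seed-reproducible and brackets estimates", {
  tr <- simulate_yule_tree(24, seed = 8)
  y <- setNames(drop(simulate_traits(tr, "OU1",
                                     list(alpha = 4, sigma2 = 0.005,
                                          theta = 0.2), seed = 19)),
                tr$tip.label)
  f <- fit_evol(tr, y, "OU1")
  b1 <- parametric_bootstrap(f, reps = 200, seed = 5)
  b2 <- parametric_bootstrap(f, reps = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_lte(b1$failed, 10)
  inside <- b1$ci["lower", ] <= b1$ci["estimate", ] &
    b1$ci["estimate", ] <= b1$ci["upper", ]
  expect_gte(mean(inside), 2 / 3)
  expect_true(inside[["theta"]])
})

test_that("regime-optimum bootstrap intervals bracket the simulation truth", {
  tr <- simulate_yule_tree(64, seed = 42)
  gm <- setNames(rep(c("low", "intermediate", "high"), length.out = 64),
                 tr$tip.label)
  pt <- paint_regimes(tr, gm)
  truth <- list(alpha = 4, sigma2 = 0.005, theta_low = 0.15,
                theta_intermediate = 0.19, theta_high = 0.22)
  covered <- 0L
  for (r in 1:3) {
    y <- setNames(drop(simulate_traits(tr, "OU_regimes", truth,
                                       seed = 600 + r, painting = pt)),
                  tr$tip.label)
    f <- fit_evol(tr, y, "OU_regimes", painting = pt)
    bt <- parametric_bootstrap(f, reps = 100, seed = 700 + r)
    for (th in c("theta_low", "theta_intermediate", "theta_high")) {
      if (bt$ci["lower", th] <= truth[[th]] &&
          truth[[th]] <= bt$ci["upper", th]) covered <- covered + 1L
    }
  }
  # at least 2 of 3 optima covered per replicate on average
  expect_gte(covered, 6L)
})
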