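#' Read and validate a Newick phylogeny
#'
#' Parses a Newick file, requires branch lengths and unique tip labels, and
#' reports tree depth and ultrametricity (relative tolerance 1e-6).
#'
#' @param path Path to a Newick file, or a Newick string.
#' @return An `ape::phylo` tree with attributes `depth` and `ultrametric`.
#' @export
read_newick <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path) else
    ape::read.tree(text = path)
  if (is.null(tree)) stop("format error: could not parse Newick", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("format error: tree is missing branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("format error: duplicate tip labels", call. = FALSE)
  }
  depths <- tip_depths(tree)
  attr(tree, "depth") <- max(depths)
  attr(tree, "ultrametric") <- is_ultrametric(tree)
  tree
}

#' Tip depths (root-to-tip path lengths)
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Named numeric vector over tips.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  stats::setNames(d, tree$tip.label)
}

#' Ultrametricity check at relative tolerance
#' @param tree An `ape::phylo` tree.
#' @param tol Relative tolerance on tip-depth spread (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(d)
}

#' Paint selective regimes onto a phylogeny by parsimony
#'
#' Assigns a regime to every branch from tip regimes using Fitch parsimony
#' (generalized to multifurcations: intersection of child state sets when
#' nonempty, else union). On the up-pass, ambiguous nodes take the parent's
#' state when possible; remaining ties, including at the root, resolve to the
#' earliest state in `levels`. Each branch takes its child node's state.
#'
#' @param tree An `ape::phylo` tree.
#' @param tip_regimes Named character vector (or data.frame with columns
#'   `species`, `regime`) mapping every tip to a regime.
#' @param levels Regime labels in tie-break order (default
#'   low < intermediate < high).
#' @return Object of class `regime_painting`: `$edge_regime` (per edge of
#'   `tree$edge`), `$node_state`, `$root_state`, `$levels`, `$tip_regimes`.
#' @export
paint_regimes <- function(tree, tip_regimes,
                          levels = c("low", "intermediate", "high")) {
  if (is.data.frame(tip_regimes)) {
    tip_regimes <- stats::setNames(as.character(tip_regimes$regime),
                                   tip_regimes$species)
  }
  miss <- setdiff(tree$tip.label, names(tip_regimes))
  if (length(miss)) {
    stop("mapping error: unmapped tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tipst <- tip_regimes[tree$tip.label]
  bad <- setdiff(unique(tipst), levels)
  if (length(bad)) stop("unknown regime(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tipst[i]
  po <- unique(edge[ape::postorder(tree), 1])  # internal nodes, children-first
  children <- split(edge[, 2], edge[, 1])
  for (nd in po) {
    kid_sets <- lapply(children[[as.character(nd)]], function(k) sets[[k]])
    inter <- Reduce(intersect, kid_sets)
    sets[[nd]] <- if (length(inter)) inter else unique(unlist(kid_sets))
  }
  state <- character(ntip + nnode)
  state[seq_len(ntip)] <- tipst
  pick <- function(set, prefer = NULL) {
    if (!is.null(prefer) && prefer %in% set) return(prefer)
    levels[min(match(set, levels))]
  }
  state[root] <- pick(sets[[root]])
  # preorder up-pass
  for (nd in rev(po)) {
    if (nd == root) next
    parent <- edge[edge[, 2] == nd, 1]
    state[nd] <- pick(sets[[nd]], prefer = state[parent])
  }
  structure(list(edge_regime = state[edge[, 2]],
                 node_state = state, root_state = state[root],
                 levels = levels, tip_regimes = tipst),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("<regime_painting>", length(x$edge_regime), "branches; root =",
      x$root_state, "\n  ")
  print(table(x$edge_regime))
  invisible(x)
}

# -- covariance and design machinery ----------------------------------------

# Shared-depth matrix t_ij (vcv with unit rate) and tip depths.
.tree_geometry <- function(tree) {
  Ct <- ape::vcv(tree)
  depths <- diag(Ct)
  list(Ct = Ct, depths = depths, T = max(depths))
}

# OU correlation-scale covariance for sigma2 = 1:
#  V0_ij = 1/(2a) * exp(-a d_ij) * (1 - exp(-2a t_ij))
.ou_V0 <- function(geom, alpha) {
  t_ij <- geom$Ct
  d_ij <- outer(geom$depths, geom$depths, "+") - 2 * t_ij
  V0 <- exp(-alpha * d_ij) * (1 - exp(-2 * alpha * t_ij)) / (2 * alpha)
  (V0 + t(V0)) / 2
}

# Root-to-tip path segments per tip: list of matrices (t_begin, t_end, regime)
.tip_segments <- function(tree, painting) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  node_depth <- ape::node.depth.edgelength(tree)
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  edge_of <- integer(max(edge))
  edge_of[edge[, 2]] <- seq_len(nrow(edge))
  root <- ntip + 1L
  lapply(seq_len(ntip), function(tip) {
    segs <- NULL
    nd <- tip
    while (nd != root) {
      e <- edge_of[nd]
      segs <- rbind(segs, c(node_depth[parent_of[nd]], node_depth[nd],
                            match(painting$edge_regime[e], painting$levels)))
      nd <- parent_of[nd]
    }
    segs
  })
}

#' Hansen regime weights
#'
#' The expected trait value of tip i under a multi-optimum OU model is a
#' weighted sum of the regime optima; the weight of regime k accumulates
#' `exp(-a(T - t_end)) - exp(-a(T - t_begin))` over the root-to-tip branch
#' segments lying in regime k, and the root weight `exp(-a T)` goes to the
#' root regime. Weights sum to 1 for every tip and every a.
#'
#' @param tree An ultrametric `ape::phylo` tree.
#' @param painting A [paint_regimes()] result.
#' @param alpha Strength of attraction (> 0).
#' @return n_tips x n_regimes weight matrix (columns in `painting$levels`).
#' @export
hansen_weights <- function(tree, painting, alpha) {
  geom <- .tree_geometry(tree)
  segs <- .tip_segments(tree, painting)
  k <- length(painting$levels)
  Tdep <- geom$T
  W <- matrix(0, length(segs), k,
              dimnames = list(tree$tip.label, painting$levels))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    w <- exp(-alpha * (Tdep - s[, 2])) - exp(-alpha * (Tdep - s[, 1]))
    for (j in seq_len(nrow(s))) W[i, s[j, 3]] <- W[i, s[j, 3]] + w[j]
  }
  rootk <- match(painting$root_state, painting$levels)
  W[, rootk] <- W[, rootk] + exp(-alpha * Tdep)
  W
}

# GLS profile likelihood for mean design X and correlation-scale covariance
# V0: profiles out theta (GLS) and sigma2 (ML, divide by n).
.gls_profile <- function(y, X, V0) {
  n <- length(y)
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdet <- 2 * sum(log(diag(R)))
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  theta <- tryCatch(solve(XtX, crossprod(Xs, ys)),
                    error = function(e) NULL)
  if (is.null(theta)) return(NULL)
  r <- ys - Xs %*% theta
  s2 <- sum(r^2) / n
  lnL <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(theta = drop(theta), sigma2 = s2, lnL = lnL)
}

# -- model fitting -----------------------------------------------------------

#' Fit a model of continuous trait evolution on a phylogeny
#'
#' Maximum-likelihood fits of three models of trait evolution:
#' * `"BM"` — Brownian motion; parameters root state `z0` and rate `sigma2`
#'   (closed-form GLS estimates; k = 2).
#' * `"OU1"` — Ornstein-Uhlenbeck with a single optimum `theta`; parameters
#'   `alpha`, `sigma2`, `theta` (k = 3).
#' * `"OU_regimes"` — OU with one optimum per selective regime painted on
#'   the branches; parameters `alpha`, `sigma2`, and one `theta` per regime
#'   (k = 2 + number of regimes).
#'
#' OU models require an ultrametric tree; the root state is the root
#' regime's optimum (no free root parameter). Optimization is over ln(alpha)
#' only — the optima and sigma2 are profiled out by generalized least
#' squares — with box constraints ln(alpha) in \[-10, 5\] after rescaling
#' tree depth to 1, and multiple fixed starting points.
#'
#' @param tree An `ape::phylo` tree with branch lengths (ultrametric for OU).
#' @param traits Named numeric vector of tip trait values.
#' @param model `"BM"`, `"OU1"`, or `"OU_regimes"`.
#' @param painting A [paint_regimes()] result (required for
#'   `"OU_regimes"`).
#' @param n_starts Number of ln(alpha) starting points (default 5).
#' @return Object of class `evo_fit`: parameters, `lnL`, `k`, `n`, `AICc`,
#'   convergence diagnostics, and the inputs needed to simulate.
#' @export
fit_evol <- function(tree, traits, model = c("BM", "OU1", "OU_regimes"),
                     painting = NULL, n_starts = 5L) {
  model <- match.arg(model)
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss)) stop("traits missing for tip(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  y <- as.numeric(traits[tree$tip.label])
  if (any(!is.finite(y))) stop("non-finite trait values", call. = FALSE)
  n <- length(y)
  geom <- .tree_geometry(tree)

  if (model == "BM") {
    C <- geom$Ct
    g <- .gls_profile(y, matrix(1, n, 1), C)
    if (is.null(g)) {
      stop("numerical error: singular phylogenetic covariance; check for ",
           "zero-length branches collapsing tips", call. = FALSE)
    }
    params <- list(sigma2 = g$sigma2, z0 = unname(g$theta))
    fit <- list(model = model, params = params, lnL = g$lnL, k = 2L, n = n,
                AICc = if (n > 3L) aicc(g$lnL, 2L, n) else NA_real_,
                convergence = list(ok = TRUE),
                boundary = g$sigma2 < 1e-12,
                tree = tree, traits = stats::setNames(y, tree$tip.label),
                painting = NULL)
    return(structure(fit, class = "evo_fit"))
  }

  if (!is_ultrametric(tree)) {
    stop("precondition error: OU fitting requires an ultrametric tree",
         call. = FALSE)
  }
  if (model == "OU_regimes") {
    if (is.null(painting)) stop("OU_regimes requires a regime painting",
                                call. = FALSE)
    # regimes absent from the painting carry no weight: drop them so the
    # design stays full rank (a one-regime painting is the single-optimum
    # model)
    used <- intersect(painting$levels,
                      unique(c(painting$edge_regime, painting$root_state)))
    if (length(used) < length(painting$levels)) {
      painting$levels <- used
    }
    k_par <- 2L + length(painting$levels)
  } else {
    k_par <- 3L
  }

  # work on a depth-1 rescaled tree; alpha' = alpha*T, sigma2' = sigma2*T
  Tdep <- geom$T
  stree <- tree
  stree$edge.length <- tree$edge.length / Tdep
  sgeom <- .tree_geometry(stree)
  W_fun <- if (model == "OU_regimes") {
    segs_painting <- painting
    function(a) hansen_weights(stree, segs_painting, a)
  } else {
    function(a) matrix(1, n, 1)
  }
  negll <- function(lna) {
    a <- exp(lna)
    g <- .gls_profile(y, W_fun(a), .ou_V0(sgeom, a))
    if (is.null(g) || !is.finite(g$lnL)) return(1e10)
    -g$lnL
  }
  starts <- seq(-6, 4, length.out = max(1L, n_starts))
  best <- NULL
  conv <- integer(0)
  for (s0 in starts) {
    o <- tryCatch(
      stats::optim(s0, negll, method = "L-BFGS-B", lower = -10, upper = 5,
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(o)) next
    conv <- c(conv, o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("diagnostic error: OU optimization failed to converge from any start",
         call. = FALSE)
  }
  a_s <- exp(best$par)
  g <- .gls_profile(y, W_fun(a_s), .ou_V0(sgeom, a_s))
  alpha <- a_s / Tdep
  sigma2 <- g$sigma2 / Tdep
  params <- if (model == "OU1") {
    list(alpha = alpha, sigma2 = sigma2, theta = unname(g$theta))
  } else {
    th <- stats::setNames(as.list(g$theta),
                          paste0("theta_", painting$levels))
    c(list(alpha = alpha, sigma2 = sigma2), th)
  }
  fit <- list(model = model, params = params, lnL = g$lnL, k = k_par, n = n,
              AICc = if (n > k_par + 1L) aicc(g$lnL, k_par, n) else NA_real_,
              convergence = list(ok = any(conv == 0), codes = conv,
                                 at_bound = abs(best$par) >= 10 - 1e-6 ||
                                   best$par >= 5 - 1e-6),
              boundary = FALSE,
              tree = tree, traits = stats::setNames(y, tree$tip.label),
              painting = if (model == "OU_regimes") painting else NULL)
  structure(fit, class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("<evo_fit> %s: lnL = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$model, x$lnL, x$k, x$n, x$AICc))
  p <- unlist(x$params)
  cat("  ", paste(sprintf("%s = %.6g", names(p), p), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.evo_fit <- function(object, ...) unlist(object$params)

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.evo_fit <- function(object, ...) {
  cat(sprintf("Model of trait evolution: %s (n = %d tips)\n",
              object$model, object$n))
  print(data.frame(estimate = unlist(object$params)))
  cat(sprintf("lnL = %.4f  k = %d  AICc = %.4f\n",
              object$lnL, object$k, object$AICc))
  if (!is.null(object$convergence$at_bound) && object$convergence$at_bound) {
    cat("note: alpha estimate at optimization bound\n")
  }
  invisible(object)
}

#' Model-implied trait mean and covariance
#' @param fit An `evo_fit`.
#' @return List with `mean` vector and covariance `V` over tips.
#' @export
evo_moments <- function(fit) {
  tree <- fit$tree
  geom <- .tree_geometry(tree)
  if (fit$model == "BM") {
    list(mean = rep(fit$params$z0, fit$n), V = fit$params$sigma2 * geom$Ct)
  } else {
    a <- fit$params$alpha
    V <- fit$params$sigma2 * .ou_V0(geom, a)
    mu <- if (fit$model == "OU1") {
      rep(fit$params$theta, fit$n)
    } else {
      th <- unlist(fit$params[paste0("theta_", fit$painting$levels)])
      drop(hansen_weights(tree, fit$painting, a) %*% th)
    }
    list(mean = mu, V = V)
  }
}

#' Simulate trait vectors under a fitted or specified model
#'
#' Draws from the model-implied multivariate normal over the tips.
#'
#' @param tree An `ape::phylo` tree.
#' @param model `"BM"`, `"OU1"`, or `"OU_regimes"`.
#' @param params Named list of parameters (as in the matching `evo_fit`).
#' @param seed Integer seed (draws are reproducible).
#' @param nsim Number of draws.
#' @param painting Regime painting for `"OU_regimes"`.
#' @return n_tips x nsim matrix of trait values (rownames = tip labels).
#' @export
simulate_traits <- function(tree, model, params, seed = NULL, nsim = 1L,
                            painting = NULL) {
  fit <- list(model = model, params = params, tree = tree,
              n = length(tree$tip.label), painting = painting)
  class(fit) <- "evo_fit"
  if (model != "BM" && (is.null(params$alpha) || params$alpha <= 0)) {
    stop("domain error: OU simulation needs alpha > 0", call. = FALSE)
  }
  if (params$sigma2 < 0) stop("domain error: sigma2 must be >= 0",
                              call. = FALSE)
  mo <- evo_moments(fit)
  n <- fit$n
  if (!is.null(seed)) set.seed(seed)
  if (params$sigma2 == 0) {
    out <- matrix(rep(mo$mean, nsim), n, nsim)
  } else {
    L <- t(chol(mo$V + diag(1e-12 * mean(diag(mo$V)), n)))
    z <- matrix(stats::rnorm(n * nsim), n, nsim)
    out <- mo$mean + L %*% z
  }
  rownames(out) <- tree$tip.label
  out
}

#' @export
simulate.evo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_traits(object$tree, object$model, object$params, seed = seed,
                  nsim = nsim, painting = object$painting)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("domain error: AICc requires n > k + 1", call. = FALSE)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# complexity order used by the selection rule
.model_order <- c(BM = 1L, OU1 = 2L, OU_regimes = 3L)
.model_df <- c(BM = 2L, OU1 = 3L, OU_regimes = 5L)

#' Select among BM / OU1 / OU-regime fits
#'
#' Implements the AICc ladder with likelihood-ratio fallback: models within
#' ΔAICc < 2 of the best do not differ meaningfully, so the simplest such
#' model is chosen; otherwise, when a more complex model leads and a nested
#' simpler model sits within ΔAICc < 4, a likelihood ratio test (chi-square,
#' df = difference in parameter count, alpha = 0.05) decides whether the
#' simpler model can be rejected. No test is performed when the simpler
#' model already has the lower AICc.
#'
#' @param fits Named list of `evo_fit` objects (names among `"BM"`,
#'   `"OU1"`, `"OU_regimes"`), all fitted to the same trait vector.
#' @return Object of class `evo_model_sel`: `$delta_aicc`, `$selected`,
#'   `$lrt` table, `$trace` of rule applications.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2L, !is.null(names(fits)))
  y0 <- fits[[1]]$traits
  for (f in fits[-1]) {
    if (length(f$traits) != length(y0) || any(f$traits != y0)) {
      stop("consistency error: fits are not on identical trait vectors",
           call. = FALSE)
    }
  }
  aic <- vapply(fits, `[[`, numeric(1), "AICc")
  if (anyNA(aic)) {
    # AICc undefined (n <= k + 1): the model cannot enter the ladder
    fits <- fits[!is.na(aic)]
    aic <- aic[!is.na(aic)]
    if (!length(aic)) stop("AICc undefined for every fit", call. = FALSE)
  }
  delta <- aic - min(aic)
  lnl <- vapply(fits, `[[`, numeric(1), "lnL")
  kk <- vapply(fits, `[[`, integer(1), "k")
  best <- names(which.min(aic))
  lrt_fun <- function(simple, complex) {
    stat <- 2 * (lnl[complex] - lnl[simple])
    df <- kk[complex] - kk[simple]
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    c(stat = stat, df = df, p = p)
  }
  .apply_selection_rule(delta, best, lrt_fun)
}

#' Selection rule on a precomputed ΔAICc table
#'
#' Applies the same AICc-ladder rule as [select_model()] when only published
#' ΔAICc values (and the reported significance of the likelihood ratio tests
#' against simpler models) are available.
#'
#' @param delta_aicc Named numeric vector of ΔAICc for `BM`, `OU1`,
#'   `OU_regimes` (minimum 0).
#' @param lrt_significant Named logical vector: for each simpler model that
#'   required a likelihood ratio test, whether the test rejected it.
#' @return An `evo_model_sel` object.
#' @export
select_model_from_table <- function(delta_aicc, lrt_significant = c()) {
  delta <- delta_aicc - min(delta_aicc)
  best <- names(which.min(delta))
  lrt_fun <- function(simple, complex) {
    sig <- isTRUE(lrt_significant[[simple]])
    c(stat = NA_real_, df = NA_real_, p = if (sig) 0 else 1)
  }
  .apply_selection_rule(delta, best, lrt_fun)
}

.apply_selection_rule <- function(delta, best, lrt_fun) {
  models <- names(delta)[order(.model_order[names(delta)])]
  trace <- character(0)
  lrt_rows <- list()
  selected <- NULL
  for (m in models) {
    if (delta[m] < 2) {
      trace <- c(trace, sprintf(
        "%s: dAICc %.2f < 2 -> simplest adequate model, selected", m,
        delta[m]))
      selected <- m
      break
    }
    nested_in_best <- .model_order[m] < .model_order[best]
    if (delta[m] < 4 && nested_in_best) {
      lr <- lrt_fun(m, best)
      lrt_rows[[m]] <- data.frame(simple = m, complex = best,
                                  stat = lr["stat"], df = lr["df"],
                                  p = lr["p"], row.names = NULL)
      if (lr["p"] >= 0.05) {
        trace <- c(trace, sprintf(
          "%s: dAICc %.2f < 4, LRT vs %s p = %.3g >= 0.05 -> simpler model kept",
          m, delta[m], best, lr["p"]))
        selected <- m
        break
      }
      trace <- c(trace, sprintf(
        "%s: dAICc %.2f < 4 but LRT vs %s p = %.3g < 0.05 -> rejected",
        m, delta[m], best, lr["p"]))
    } else {
      trace <- c(trace, sprintf("%s: dAICc %.2f -> not competitive", m,
                                delta[m]))
    }
  }
  if (is.null(selected)) {
    selected <- best
    trace <- c(trace, sprintf("%s: best by AICc, selected", best))
  }
  structure(list(delta_aicc = delta, selected = selected,
                 lrt = if (length(lrt_rows)) do.call(rbind, lrt_rows) else NULL,
                 trace = trace),
            class = "evo_model_sel")
}

#' @export
print.evo_model_sel <- function(x, ...) {
  cat("<evo_model_sel> selected:", x$selected, "\n")
  print(round(x$delta_aicc, 2))
  for (t in x$trace) cat("  -", t, "\n")
  invisible(x)
}

#' Parametric bootstrap confidence intervals for a fitted model
#'
#' Simulates trait vectors from the fitted model on its tree, refits the
#' same model to each replicate, and reports percentile 2.5%/97.5% intervals
#' for every parameter. Replicates whose refit fails are dropped (an error is
#' raised if more than 20% fail).
#'
#' @param fit A converged `evo_fit`.
#' @param reps Number of bootstrap replicates.
#' @param seed Integer seed; results are reproducible.
#' @param n_starts Optimization starts per refit (default 2; the parent
#'   fit's alpha seeds the refits through the standard start grid).
#' @return Object of class `evo_boot`: `$ci` (matrix with rows lower,
#'   estimate, upper), `$reps_used`, `$failed`, `$draws`.
#' @export
parametric_bootstrap <- function(fit, reps = 10000L, seed = 1L,
                                 n_starts = 2L) {
  sims <- simulate_traits(fit$tree, fit$model, fit$params, seed = seed,
                          nsim = reps, painting = fit$painting)
  est <- unlist(fit$params)
  draws <- matrix(NA_real_, reps, length(est),
                  dimnames = list(NULL, names(est)))
  failed <- 0L
  for (r in seq_len(reps)) {
    tr <- stats::setNames(sims[, r], rownames(sims))
    rf <- tryCatch(
      fit_evol(fit$tree, tr, model = fit$model, painting = fit$painting,
               n_starts = n_starts),
      error = function(e) NULL)
    if (is.null(rf)) failed <- failed + 1L else draws[r, ] <- unlist(rf$params)
  }
  if (failed > 0.2 * reps) {
    stop("reliability error: ", failed, " of ", reps,
         " bootstrap refits failed", call. = FALSE)
  }
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  ci <- rbind(lower = qs[1, ], estimate = est, upper = qs[2, ])
  structure(list(ci = ci, reps_used = sum(ok), failed = failed,
                 draws = draws[ok, , drop = FALSE]),
            class = "evo_boot")
}

#' @export
print.evo_boot <- function(x, ...) {
  cat(sprintf("<evo_boot> %d replicates used (%d failed)\n",
              x$reps_used, x$failed))
  print(t(signif(x$ci, 4)))
  invisible(x)
}

#' Read a tip -> regime TSV
#'
#' Two tab-separated columns: species and regime, no header required (a
#' header line `species  regime` is accepted and skipped).
#'
#' @param path TSV path.
#' @return Named character vector species -> regime.
#' @export
read_regime_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("species", "regime"))
  if (identical(tolower(df$species[1]), "species")) df <- df[-1, , drop = FALSE]
  stats::setNames(df$regime, df$species)
}
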