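---
title: "Quantifying plumage color and its evolution across light environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plumage color and its evolution across light environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumalight)
```

## The problem

The light environment hypothesis proposes that the ambient light of a
habitat shapes the evolution of visual signals: forest-floor birds live in
dim, green-shifted light, canopy and edge species in bright, UV-rich light,
and plumage color should track those differences. Testing this in drab,
"monochromatic" birds requires (i) measuring color the way a bird sees it,
because tetrachromatic vision with UV sensitivity resolves differences
invisible to humans; and (ii) comparative models that ask whether color
descriptors evolve toward light-regime-specific optima. `plumalight`
implements that full chain: reflectance-spectra handling, the
receptor-noise model of chromatic discrimination, the tetrahedral color
space and its whole-plumage descriptors, and maximum-likelihood
Brownian-motion / Ornstein–Uhlenbeck model selection on a phylogeny, plus a
synthetic-study generator with known ground truth so every stage is
testable without instrument data.

## Spectra and their aggregation

Reflectance is handled as a proportion on a canonical 1-nm grid from 300 to
700 nm (401 points). The range is the standard avian-visible measurement
window; the 1-nm step matches spectrometer exports and keeps trapezoid
integrals stable, and instrument grids are placed onto it by linear
interpolation (never extrapolation). Readers auto-detect percent-scaled
curves (whole curve above 1.5) and rescale with a message.

Aggregation follows the replicate design of a museum study: three replicate
scans average into a specimen curve, specimen curves average into a sex
mean, and all between-sex distances are computed on the two sex-mean
curves. Whether a published analysis compared sex-mean spectra or averaged
pairwise specimen distances is usually unstated; the sex-mean convention is
this package's documented default because it matches the replicate-averaging
language of field protocols and is invariant to specimen count. Patch
exclusion for barred or mottled plumage is a data-collection rule, so the
reader accepts an exclusion list but performs no pattern detection.

## The receptor-noise model of discrimination

For cone class $i$ with spectral sensitivity $R_i(\lambda)$, stimulus
reflectance $S(\lambda)$ and illuminant $I(\lambda)$, the quantum catch is

$$Q_i = \int_{300}^{700} R_i(\lambda)\, S(\lambda)\, I(\lambda)\,
  d\lambda ,$$

evaluated by the trapezoid rule. Von Kries adaptation divides each catch by
the catch of the adapting background — here an ideal white reflector under
the same illuminant — giving color constancy: the absolute intensity and,
to first order, the spectral shape of the illuminant cancel. The receptor
signal is $f_i = \ln q_i$, and the discriminability of two stimuli with
contrast differences $\Delta f_i$ is the receptor-noise-limited distance

$$\Delta S^2 = \frac{\sum_{i<j,\; \{k,l\} = \text{rest}}
  (e_i e_j)^2 (\Delta f_k - \Delta f_l)^2}
  {\sum_{\text{triples}} (e_i e_j e_k)^2},$$

the tetrachromatic form with per-cone noise $e_i = w \sqrt{n_{\max}/n_i}$,
anchored so the most abundant cone class has noise equal to the Weber
fraction $w$. Defaults are $w = 0.05$ and blue tit relative cone densities
$0.37 : 0.70 : 0.99 : 1.00$ (u : s : m : l). $\Delta S$ is expressed in
just noticeable differences (jnd); 1 jnd is the conventional
discriminability threshold.

Useful exact identities, all enforced by the test suite at tight
tolerances: $\Delta S(a,a) = 0$; symmetry; invariance to scaling either
stimulus or the illuminant by any positive constant; and the equal-noise
reduction $\Delta S = \delta\sqrt{3}/(2e)$ when only one contrast channel
is nonzero. The six-term form is also checked against an independent
computation — minimizing the noise-scaled distance over the achromatic
offset — on a thousand random inputs per run.

Cone sensitivities default to a generic average avian UV-type system with
peaks at 370, 445, 508, 565 nm built from the A1 visual-pigment nomogram.
The alpha band alone is used by default, which keeps each curve unimodal;
the secondary beta absorbance band can be enabled per call, and tabulated
sensitivity curves can be supplied to replace the nomogram entirely.
Oil-droplet filtering and ocular media are not modeled, so absolute jnd
values under any substituted curve set will differ slightly from values
computed with other published sensitivity tables; the thresholded
classifications are far less sensitive than the raw distances.

## Illuminant scenarios

Two scenarios drive the dichromatism tables. The *ideal* scenario uses a
flat unit illuminant. The *real* scenario assigns each species the
irradiance of its light-level group: forest shade (low), standard daylight
D65 (intermediate), and blue sky (high — chosen over D65 for bright
habitats because its intensity peaks toward the UV, like canopy light).
The bundled curves are smooth parametric stand-ins shaped to the
qualitative structure of measured forest-light spectra and scaled to
published total photon fluxes (142.71, 275.87 and 249.10 µmol·m⁻²·s⁻¹ over
300–700 nm); any of them can be replaced by a measured CSV. Because von
Kries adaptation cancels most illuminant structure, classifications are
nearly illuminant-independent — the cross-illuminant audit re-runs every
species under all three habitat illuminants and flags any species whose
dichromatic status changes.

## Thresholds and summaries

A patch is dichromatic when $\Delta S \ge$ threshold (inclusive — the
boundary case 1.0 counts, matching the convention "at least one just
noticeable difference"), and a species when at least one patch is.
Thresholds 1.0, 1.5 and 2.0 jnd are tabulated. Group summaries report the
percentage of dichromatic patches and species per light level, plus the
mean ± SD of $\Delta S$ over *all* patches in the group (not only
dichromatic ones); that convention is configurable because published
"mean discrimination" columns rarely state it. One published table this
package mirrors captions its percentages as ideal-model values while the
numbers match the real-model counts; the group summary therefore reports
both scenarios side by side. Facial marks are excluded from the body-region
frequency breakdown (they are not homologous across species) but included
in all species-level counts. Group and patch effects on $\Delta S$ are
tested by an additive two-way ANOVA (factor + block, no interaction,
Type-II sums of squares) with Tukey HSD comparisons and a compact letter
display.

## Tetrahedral color space and the six descriptors

Relative catches $\{u,s,m,l\}$ (von-Kries-normalized, summing to 1) map to

$$x = \frac{1 - 2s - m - u}{2}\sqrt{\tfrac{3}{2}}, \quad
  y = \frac{-1 + 3m + u}{2\sqrt{2}}, \quad
  z = u - \tfrac{1}{4},$$

placing the achromatic point at the origin and each pure-cone stimulus at a
vertex 0.75 from it; chroma is the distance $r$ from the origin. Descriptor
computation uses the ideal illuminant and background. Six whole-plumage
descriptors summarize each species: average color span (mean pairwise
distance between patch points) and its variance (population convention,
divide by the number of pairs — stated so tests can be exact), convex-hull
color volume, average and maximum chroma, and average brightness (mean
reflectance, averaged over patches). Sexes are summarized separately and
the species value is the mean of the two sexes' descriptor values; pooling
both sexes' points into one cloud is available behind a flag (pooling can
only enlarge the hull, averaging cannot — the choice matters for volume and
is therefore explicit).

Hull volumes are computed exactly by enumerating supporting planes, which
is robust and fast for the ≤ ~20 points of a plumage; degenerate
(coplanar or < 4 point) sets get volume 0 rather than an error, since a
plumage of collinear colors is a legitimate observation.

## Evolutionary models and selection

Three models are fitted to each descriptor on an ultrametric phylogeny
(tolerance $10^{-6}$ relative on tip-depth spread):

* **BM** — Brownian motion, parameters $z_0, \sigma^2$, closed-form GLS
  estimates, $k = 2$;
* **OU1** — single-optimum Ornstein–Uhlenbeck, parameters
  $\alpha, \sigma^2, \theta$, $k = 3$;
* **OU-regimes** — one optimum per light regime painted on the branches,
  $k = 5$ for three regimes.

The OU covariance between tips $i, j$ is
$V_{ij} = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2\alpha t_{ij}})$ with $d_{ij}$ the patristic distance and
$t_{ij}$ the depth of the most recent common ancestor, and the expectation
of tip $i$ is a weighted mixture of the regime optima, with weights
accumulated as $e^{-\alpha(T - t_{\text{end}})} -
e^{-\alpha(T - t_{\text{begin}})}$ over the root-to-tip branch segments in
each regime; the root weight $e^{-\alpha T}$ goes to the root regime's
optimum. The root is the root-regime optimum rather than a free ancestral
state, keeping the parameter counts at 2/3/5; a free root is a
straightforward extension but changes the AICc bookkeeping.

Internal branches are painted from the tip regimes by Fitch parsimony
(generalized to multifurcations), with ambiguity resolved toward the
parent's state and residual ties — including at the root — broken by the
fixed order low < intermediate < high. A user-supplied painting can
replace the parsimony one.

Optimization is deliberately one-dimensional: given $\alpha$, the optima
and $\sigma^2$ are profiled out by GLS, so the likelihood is maximized
over $\ln\alpha \in [-10, 5]$ (after rescaling tree depth to 1, so the
bounds are in units of tree depth) by bounded quasi-Newton from five fixed
starts. Fits report convergence codes and whether $\hat\alpha$ sits on a
bound. Degenerate cases behave predictably: constant traits give a
boundary $\sigma^2 \to 0$ BM fit, a painting whose branches all carry one
regime reproduces the single-optimum fit, and equal optima give
likelihoods identical to OU1.

Model choice follows the AICc ladder: models within $\Delta\mathrm{AICc} <
2$ of the best are equivalent and the simplest of them wins (complexity
order BM < OU1 < OU-regimes); otherwise, a nested simpler model within
$\Delta\mathrm{AICc} < 4$ of a leading complex model triggers a likelihood
ratio test ($\chi^2$, df = parameter difference, $\alpha = 0.05$) that
decides; no test is run when the simpler model already leads. BM is
treated as the $\alpha \to 0$ boundary of OU1 (df = 1), and OU1 as nested
in OU-regimes (df = 2); the boundary effect on the $\chi^2$ null is known
to make that test slightly conservative, and the plain $\chi^2$ is used.
When AICc is undefined for a model ($n \le k + 1$), that model simply
cannot enter the ladder. The same rule applied to published
$\Delta\mathrm{AICc}$ tables (with reported LRT outcomes) is exposed
separately, so printed model-comparison tables can be re-decided without
raw data.

Confidence intervals come from a parametric bootstrap: simulate trait
vectors from the fitted model on the tree, refit the same model, take
percentile 2.5/97.5 limits. The bootstrap type (parametric versus
nonparametric) is rarely stated in the literature; parametric is the
natural choice for a fully specified Gaussian process model. Refits seed
their start grid near the parent fit's $\hat\alpha$ (2 starts), failures
are dropped with a count, and more than 20% failures is an error rather
than a silent answer. Default 10,000 replicates; tests use 200.

## The synthetic study generator

The generator emulates the statistical structure of a museum reflectance
study of drab Furnariides: 33 species split 4 / 18 / 11 across low,
intermediate and high light; 5–10 patches per species; 3–5 specimens per
sex; 3 replicate scans. Each species' reflectance family is a low baseline
plus a sigmoid long-wavelength ramp and a small UV bump — the shape of
light-brown to reddish-brown plumage — with per-patch offsets in baseline,
ramp amplitude, ramp position and UV strength. Specimen noise is an
intensity factor (log-normal, SD 0.05) plus a slight spectral tilt;
replicate noise is small white instrument noise (SD 0.002). Parameter
ranges were set so species-level descriptors land in the magnitudes
reported for drab furnariid plumages (average span of order 0.01–0.08,
hull volume of order $10^{-7}$–$10^{-5}$, brightness 0.10–0.21).

Sexual dichromatism is injected chromatically — the female ramp inflection
is shifted in wavelength — and the shift is *calibrated by bisection* until
the ideal-illuminant $\Delta S$ between the noiseless sex curves hits a
target within 2%. Default targets (0.6, 1.25, 1.75, 2.4 jnd) deliberately
avoid the 1.0/1.5/2.0 thresholds so that calibration tolerance and
specimen noise cannot flip a classification; roughly 18% of species get no
shifted patch at all. A pure intensity dimorphism (female = $k$ × male) is
also available and is, by construction, invisible to the chromatic
distance — a useful negative control. Every stream (patch offsets,
specimen noise, replicates, tree, traits) draws from its own deterministic
sub-seed, so fixtures are bitwise reproducible and stages can be varied
independently.

Descriptor traits for the comparative stage are simulated directly on the
Yule tree (depth rescaled to 1) under known models — by default brightness
under a three-regime OU with optima 0.15 / 0.19 / 0.22, $\alpha = 4.17$,
$\sigma^2 = 0.005$, and the other descriptors under BM or single-optimum
OU at matching scales. What the generator does *not* emulate: feather
microstructure and iridescence, plumage patterning (bars, streaks),
phylogenetic signal in the spectral shapes themselves (only the trait
layer evolves on the tree), oil-droplet filtering, and measurement
geometry effects. Passing tests therefore demonstrate that the pipeline's
mathematics and bookkeeping are correct under the study's design — not
that any particular empirical claim about real furnariids would replicate.

## Problem sizes and numerical settings used by the checks

The test suite and the acceptance script keep simulation sizes at the
scale where each check is statistically meaningful but quick: the
regime-recovery study uses 20 replicate simulations on a 128-tip Yule tree
(≥ 80% correct selection expected at the strong-effect scale above);
bootstrap coverage uses 50 simulate–fit–bootstrap rounds at 200 replicates
(≥ 40/50 nominal-95% coverage expected); the end-to-end fixture runs the
full 33-species design twice at 50 bootstrap replicates and demands
byte-identical output tables. Key tolerances: exact identities of the
discrimination model at $10^{-9}$ relative; hull closed forms at
$10^{-9}$; the $\alpha \to 0$ OU/BM likelihood limit at $10^{-3}$;
equal-optimum model equivalence at $10^{-6}$.

## Known limitations

Achromatic (double-cone) contrast is not modeled, so brightness-only
dimorphism registers as zero $\Delta S$ by design. Absolute jnd values
depend on the sensitivity curves chosen. The OU machinery requires
ultrametric trees and a single $\alpha$ and $\sigma^2$ across regimes.
Descriptor models are univariate; joint evolution across descriptors and
phylogenetic uncertainty (tree posterior samples) are out of scope.
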