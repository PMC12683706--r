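---
title: "Energetic landscapes and movement responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetic landscapes and movement responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trophscape links three layers of inference that are usually run in
separate toolchains: (i) a Bayesian stable-isotope mixing model that
estimates what fraction of a forage fish's energy comes from each basal
resource; (ii) an energetic-landscape ("E-scape") construction that
projects those fractions onto a map as a habitat resource index (HRI);
and (iii) two movement models — an integrated step-selection function
(iSSF) and a covariate-transition hidden Markov model (HMM) — that
quantify how a central-place-foraging predator responds to HRI. This
vignette documents the models, the tunable parameters, the synthetic
data generators used for validation, and the numerical choices.

## The mixing model

Consumer tissue carries two tracers, delta-13C and delta-34S (per mil).
Three basal sources — phytoplankton, benthic microalgae, marsh grass —
have known signatures (mean, SD per tracer) and elemental
concentrations. For a proportion vector $p$ on the 3-simplex, the
consumer-space mean of tracer $t$ is the concentration-weighted mixture

$$\mu_t(p) = \frac{\sum_i p_i C_{it}\,(\delta_{it} + \mathrm{TEF}_t)}
                   {\sum_i p_i C_{it}},$$

with trophic enrichment factors (defaults 1.00 ± 0.63 for carbon, 0.50
± 0.20 for sulfur) shifting sources into consumer space. The likelihood
is Gaussian per tracer with variance combining source SD and TEF SD
propagated through the (normalized) mixture weights plus a residual
term. The prior is Dirichlet(1,1,1) on $p$ and half-Cauchy (scale 5 per
mil) on each residual SD.

Sampling is random-walk Metropolis on the additive-log-ratio transform
of $p$ plus log residual SDs. Proposal scales adapt toward ~30%
acceptance during burn-in only, so retained draws come from a fixed
kernel; chains are reproducible given a seed. Split-R-hat is reported
per proportion and a flag is raised above 1.1. Desk-scale defaults are
3 chains x 20,000 iterations (burn 10,000, thin 10); these are
arguments, so the field-scale settings (3 x 1,000,000, burn 500,000,
thin 500) are one call away. Because the likelihood only needs the
per-tracer sufficient statistics (n, sum, sum of squares), iteration
cost is independent of sample size.

Concentrations default to equal, in which case the mixture reduces to a
plain weighted mean and results are invariant to uniformly rescaling
all concentrations (tested). With two tracers and three sources the
simplex is exactly identified when the source triangle is
non-degenerate; the bundled `synthetic_sources()` triangle is synthetic
(field source signatures must come from the user's own data) but has
realistic geometry: phytoplankton 13C-depleted/34S-enriched, C4 marsh
grass 13C-enriched, benthic microalgae intermediate.

## E-scape construction

Habitat rasters are planar-metric grids with three classes (marsh,
water, other). Three derived layers locate the production of each basal
source:

* **marsh cover** — marsh-grass production;
* **edge area** — benthic-microalgae production: each 4-neighbour
  (rook) marsh-water cell adjacency is a piece of linear boundary,
  converted to area as boundary length x a 10 m strip width and
  accumulated on the water side (configurable). Rook adjacency is used
  because the quantity being measured is the linear marsh-water
  boundary; diagonal contacts have zero shared boundary.
* **chlorophyll-weighted water** — phytoplankton production: water
  cover times relative chlorophyll (multi-year mean scaled by its
  maximum, so values lie in [0, 1]).

The index of energetic importance for source $i$ is
$\mathrm{IEI}_i = f^{\mathrm{source}}_i / f^{\mathrm{habitat}}_i$:
posterior-median diet fraction over areal availability in a 500 m
buffer (the predator's foraging scale). Availability is measured at
random calibration points (default 1000); points whose buffer lacks
habitat $i$ are dropped for source $i$ and counted, rather than
producing infinite ratios. Buffer membership is decided by the
cell-center-in-circle rule; at 10 m cells against a 500 m radius the
discretization error is below 0.1% of buffer area, which is why the
exact cell-circle intersection was not implemented.

The habitat resource index of landscape unit $x$ (default 1 km x 1 km,
anchored at the raster origin, half-open cell intervals) is

$$\mathrm{HRI}_x = \sum_i \widetilde{\mathrm{IEI}}_i \,
  f^{\mathrm{habitat}}_{i,x}.$$

HRI = 1 means landscape-average resource production: if a unit's
fractions equal the calibration-wide availability, the ratios cancel
and the sum telescopes to $\sum_i f^{\mathrm{source}}_i = 1$. The test
suite checks this identity to 1e-9 on a homogeneous landscape, and
checks linearity (doubling one source's median doubles its additive
contribution) and whole-cell translation invariance.

Downstream models use log(HRI). Units with HRI = 0 or off the mapped
landscape yield a *missing* covariate, never $-\infty$ or a silent 0:
the iSSF drops affected strata entirely (with a count), while the HMM —
which cannot drop single steps without breaking the chain — imputes the
landscape-average value log(1) = 0 and counts the imputations.

## Trajectory preparation

GPS fixes are segmented into *complete trips*: maximal runs outside a
colony radius (default 500 m, the scale of a small barrier-island
colony; configurable), extended to the bounding on-colony fixes, and
kept only when the whole trip falls on one calendar day (timezone
configurable). Trips are rediscretized to even 15-min intervals by
linear interpolation in time; gaps above 60 min split the trip rather
than bridge it. Steps are Euclidean lengths; turns are signed heading
changes wrapped to $(-\pi, \pi]$, counter-clockwise positive; a
zero-length step has no heading, so its own and the following turn are
missing. When a trip's duration is a whole number of intervals the
interpolated endpoints coincide with the recorded ones; otherwise the
even-interval grid wins and the final partial interval is not emitted.

## Integrated step selection

Movement kernels are fitted to the observed steps: maximum-likelihood
gamma on positive lengths (via `fitdistrplus`) and closed-form von
Mises on turns. For each observed step with a defined previous heading,
K = 50 control steps are drawn from those kernels and log(HRI) is
attached at every endpoint. The estimator maximizes the stratified
conditional multinomial log-likelihood

$$\ell(\beta) = \sum_{\mathrm{strata}} \left[ \eta_{\mathrm{case}}
  - \log \sum_{\mathrm{choices}} e^{\eta} \right],\qquad
  \eta = \beta_1\,\mathrm{sl} + \beta_2 \log \mathrm{sl}
  + \beta_3 \cos(\mathrm{turn}) + \beta_4 \log(\mathrm{HRI}),$$

which is exactly the partial likelihood of the constant-event-time Cox
construction used in the field (the agreement with `survival::clogit`
is a test, not the implementation). Standard errors come from the
observed information. The covariate is evaluated at the step endpoint,
the usual iSSF convention. Step length enters the optimizer in km for
conditioning and is rescaled on output.

A population-level smooth with random smooth deviations (the
penalized-GAM-in-Cox design) is represented here as a linear log(HRI)
effect plus
ridge-penalized per-individual and per-year slope deviations — the
fitted smooths in this system are near-linear, and the ridge-penalized
linear deviation captures the same "who differs from the population"
question with far less machinery; the design keeps the basis hook open.
The penalty is chosen by a Laplace-approximate marginal likelihood over
a log-spaced grid (the ridge read as a normal prior with precision
lambda), or fixed by the user. Pooling decisions across groups are left
to the user: the report carries the shrunken deviation magnitudes.

The relative selection strength for a contrast $\Delta$ in log(HRI) is
$e^{\beta_4 \Delta}$, multiplicative in $\Delta$.

## The covariate-transition HMM

Three behavioral states — stationary, foraging, traveling, labeled in
ascending order of fitted mean step length — emit gamma step lengths
(parameterized by mean and SD, as states are reported in the field) and
von Mises turns. The transition matrix at a step with covariate $g$ =
log(HRI) uses a multinomial-logit link: off-diagonal working values
$\eta_{ij} = \alpha_{ij} + \beta_{ij} g$ with the diagonal as softmax
reference. Each track initializes at the stationary distribution of the
transition matrix evaluated at its first step's covariate; the
covariate for the transition into step $t$ is taken at the start of
step $t$: start-of-step is the natural reading of "conditions where
the bird is deciding", and the alternative (endpoint) differs only by a
one-step covariate lag.

The forward recursion is scaled, runs in compiled code (this likelihood
is evaluated thousands of times across restarts), and shifts emission
log-densities by their per-step maximum so that extreme parameter
values during line searches underflow gracefully instead of
catastrophically. log I0(kappa) switches to its asymptotic expansion
above kappa = 50, where the Bessel routine's running time grows with
its argument. Missing turns (first step of a track, or after a
zero-length step) contribute the length-only emission.

Fitting draws starting values per restart from the stated uniform
ranges — 1-2000 m for mean and SD step length, 0-2 rad for mean and SD
turning angle, the SD mapped to a concentration via the circular-SD
relation — and runs a Nelder-Mead phase followed by BFGS on
log/identity-transformed parameters; the best restart is polished with
a longer BFGS budget and states are relabeled by mean step length. Two
numerical guards matter:

* the gamma likelihood is unbounded along a "spike at zero" ridge
  (shape to 0 with one state's mean collapsing onto the smallest step);
  the working-scale transform caps SD at 3x the mean (shape >= 1/9),
  which excludes the ridge while leaving realistic movement states
  (shape 0.7-3 here) far inside;
* the likelihood surface is genuinely multimodal under uniform random
  starts: distinct local optima correspond to different assignments of
  the step-length clusters to states, and no local polish escapes them.
  That is precisely why the 50-restart protocol exists. On the
  synthetic study-scale data roughly 1 restart in 8 lands in the global
  basin, so 50 restarts find it with overwhelming probability; the fit
  object keeps the full restart table so this can be inspected.

Viterbi decoding breaks ties toward the lower state index. Transition
curves along a covariate grid carry delta-method intervals from the
observed information (probabilities clipped to [0, 1]); per-transition
slopes are reported with Wald intervals. Foraging segregation between
colonies is the Jaccard overlap of the 1-km units containing decoded
foraging locations.

## Synthetic data: what it emulates, and what it does not

The generators define the validation conditions:

* `make_landscape()` thresholds a smoothed Gaussian field by rank, so
  class fractions are hit exactly and patch size is controlled by the
  smoothing scale; water cells carry a west-east relative-chlorophyll
  gradient plus smooth noise. Real cover maps have channels, shoreline
  structure and anisotropy that this field does not.
* `simulate_isotopes()` draws consumers around the analytic mixture
  mean — the model's own likelihood, so mixing tests are
  well-specified parameter recovery, not robustness checks.
* `simulate_hmm_steps()` runs the covariate HMM forward over the
  E-scape (states from the transition matrix at the local covariate,
  then gamma/von Mises emissions), storing the true state sequence so
  Viterbi accuracy is measurable. A soft homing rule turns headings
  back toward the arena center beyond a range limit; homing headings
  carry von Mises noise because an exact homeward heading would place a
  point mass at turn = 0 that no continuous turn model has.
* `simulate_ssf_steps()` draws observed steps *exactly* from density
  proportional to kernel x exp(beta log HRI) by rejection sampling, so
  iSSF recovery has no finite-candidate approximation bias.
* `simulate_tracks()` adds the colony day structure (start at the
  colony, 12 h of 15-min fixes, forced traveling-speed return near day
  end) to exercise trip segmentation end to end. Day length is a free
  parameter, and 12 h is a plausible subtropical daylight window.

Scales used in the checks: IEI/edge/buffer algebra runs on 10 m cells
(the field map resolution); movement arenas use 100-200 m cells over
40-60 km so that ~5 km traveling steps fit inside the mapped area. The
IEI/HRI algebra is resolution-independent, but numerical IEI magnitudes
are not comparable across cell sizes (edge density scales with
resolution). Passing tests demonstrate correct inference under the
generators' assumptions (planar coordinates, exact kernels, no
observation error); they do not certify behavior on real tracking data
with location error, irregular sampling or tidal structure.

## Problem sizes and defaults

| stage | default | note |
|---|---|---|
| buffer radius | 500 m | predator foraging scale |
| landscape unit | 1000 m | matches the buffer scale |
| calibration points | 1000 | medians stable to well under IQR/4 |
| controls per step | K = 50 | |
| MCMC | 3 x 20,000 | desk scale; field scale via arguments |
| HMM restarts | 50 | U(1, 2000) m, U(0, 2) rad starts |
| recovery checks | 5000 strata; 30 tracks x 200 steps | |

## Known limitations

* No geographic CRS handling: all coordinates are planar meters, and
  raster I/O is the plain-text ASCII grid. Reprojection belongs
  upstream.
* The HMM assumes one shared parameter set across birds (tracks enter
  as independent chains with per-track initial distributions); per-bird
  transition heterogeneity is not modeled.
* Zero step lengths are treated as missing-emission steps rather than
  through an explicit zero-inflation mass; rediscretized synthetic data
  contain none.
* The iSSF deviations are linear in log(HRI); genuinely nonlinear
  individual responses would need the spline basis the design leaves
  open.
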