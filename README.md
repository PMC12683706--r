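# trophscape

Energetic resource landscapes ("E-scapes") and predator movement
responses, in one tested R package.

Coastal restoration reshapes where a forage fish's food is produced.
For a planktivorous fish like Gulf menhaden, the energy in its tissue
comes from a few basal resources — phytoplankton, benthic microalgae,
marsh grass — each produced by a mappable habitat: open water weighted
by chlorophyll, the marsh-water edge, and marsh cover. trophscape is
for movement and trophic ecologists who want to go from raw inputs
(habitat cover raster, chlorophyll rasters, consumer/source isotope
tables, GPS tracks of a predator such as the brown pelican) to an
answer to the question *do predators put their foraging effort where
their prey's energy is produced?*

The chain has three links:

1. **Isotope mixing** — a concentration-dependent Bayesian mixing model
   (two tracers: δ13C, δ34S; three sources; Dirichlet(1,1,1) prior;
   TEFs 1.00 ± 0.63 ‰ C, 0.50 ± 0.20 ‰ S by default) estimates the
   diet fractions `fsource_i`.
2. **E-scape** — each source's index of energetic importance is the
   ratio of use to availability, `IEI_i = fsource_i / fhabitat_i`,
   calibrated over 500 m buffers at random points; the habitat resource
   index of each 1 km landscape unit is
   `HRI_x = Σ_i median(IEI_i) · fhabitat_{i,x}`. HRI = 1 is
   landscape-average resource production.
3. **Movement** — GPS tracks are segmented into same-day colony round
   trips, rediscretized to 15-min steps, and modeled two ways: an
   integrated step-selection function (50 kernel-sampled controls per
   step, stratified conditional likelihood, selection coefficient on
   log HRI) and a 3-state hidden Markov model (gamma step lengths, von
   Mises turns) whose state-transition probabilities depend on log HRI,
   fitted with 50 random restarts and decoded with Viterbi.

Every stage has a synthetic twin with known ground truth
(`make_landscape()`, `simulate_isotopes()`, `simulate_ssf_steps()`,
`simulate_hmm_steps()`, `simulate_tracks()`), so the whole pipeline is
testable without any field data.

## Worked example

```r
library(trophscape)

# synthetic landscape + E-scape calibrated from a fitted mixing model
cfg  <- landscape_config(width = 300, height = 300, cell_size = 200,
                         patch_scale = 5, marsh_fraction = 0.3, seed = 2)
land <- make_landscape(cfg)
edge <- edge_area(land$habitat)
chl  <- relative_chl(list(land$chl))

src  <- synthetic_sources()
cons <- simulate_isotopes(c(0.68, 0.23, 0.09), src, tef_defaults(),
                          n = 200, seed = 5)
post <- fit_mixing(cons, src, tef_defaults(), seed = 7)
summarize_mixing(post)
#>          source       mean          sd     median      lower     upper
#> 1 phytoplankton 0.67439027 0.004536114 0.67433165 0.66565177 0.6837154
#> 2       benthic 0.22597104 0.007086420 0.22590009 0.21242011 0.2401752
#> 3         marsh 0.09963869 0.009517167 0.09983569 0.08114906 0.1174738

fs  <- summarize_mixing(post)$median
iei <- compute_iei(land$habitat, chl, edge, fs / sum(fs),
                   n_points = 1000, seed = 3)
esc <- compute_hri(land$habitat, chl, edge, iei, unit = 1000)

# steps simulated with a known unit selection coefficient, then refit
kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
obs  <- simulate_ssf_steps(esc, kern, beta = 1, n = 5000, seed = 9)
ctrl <- make_controls(obs, kern, K = 50, escape = esc, seed = 10)
fit_issf(ctrl)
#> <ssf_fit> 5000 strata, loglik -19075.37
#>                   coef           se          z             p
#> sl        1.445243e-05 2.610433e-05  0.5536413  5.798244e-01
#> log_sl   -1.933658e-02 3.763196e-02 -0.5138339  6.073681e-01
#> cos_turn  2.308821e-02 2.299190e-02  1.0041893  3.152874e-01
#> log_hri   9.789351e-01 3.376589e-02 28.9918316 8.340319e-185
```

The kernel terms hover at zero (they only absorb the sampling design)
while the selection coefficient recovers the simulated truth of 1:
each unit of log(HRI) multiplies the likelihood of taking a step by
`exp(0.98) ≈ 2.7` (`rss(fit, 1)`).

The HMM side works the same way: `simulate_hmm_steps()` generates
tracks whose state switching responds to log(HRI) with the study-scale
state parameters (stationary 5.41 ± 5.05 m, foraging 1176 ± 1353 m,
traveling 5203 ± 2903 m; traveling→foraging slope 1.02), `fit_hmm()`
recovers them from 50 uniform random restarts, and `viterbi()` decodes
states that can be checked against the stored truth.

`run_pipeline(pipeline_config(seed = 1))` chains everything —
landscape, mixing, IEI/HRI, track simulation, trip segmentation, iSSF,
HMM — writes all artifacts (ASCII grids, CSVs, JSON reports) and
returns a manifest with MD5 checksums; identical configs reproduce
identical checksums.

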