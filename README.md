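# quantalmap

Quantal imaging and photoconversion analysis of synaptic release sites at
the *Drosophila* larval neuromuscular junction (NMJ).

Individual presynaptic active zones (AZs) differ enormously in strength:
the probability **Pr** that an AZ releases a vesicle per action potential
spans more than an order of magnitude within one terminal, and a
subpopulation of AZs supports only spontaneous ("mini") fusion. Optical
quantal imaging resolves this heterogeneity site by site: a
membrane-tethered postsynaptic GCaMP reports each vesicle fusion as a
local fluorescence flash, so a movie recorded at 8 Hz during 1 Hz nerve
stimulation yields per-AZ event counts. Combining this with
photoconvertible labels — green→red switching of mMaple/mEosEM-tagged
glutamate receptors or AZ scaffolds by 405 nm light — time-stamps each
synapse's age and each protein pool's delivery date, linking release
strength to synapse maturation and protein turnover.

`quantalmap` is an R package for the full analysis chain, aimed at
synaptic physiologists processing this class of data:

* **Puncta**: max projection, thresholded 8-connected object detection
  (centroids in µm, areas in µm², sum/mean intensities), pairwise
  colocalization, AZ–PSD opposition pairing, densities per 10 µm².
* **Quantal imaging**: ΔF event detection (rolling-percentile baseline,
  spatial smoothing, robust per-pixel noise), nearest-ROI assignment with
  a 0.8 µm cutoff, evoked/spontaneous separation by the ≥3-coincidence
  rule, and per-ROI release maps — `Pr = evoked events / stimulations`,
  spontaneous rate in events/min.
* **Synapse age**: old/new PSD classification from two-colour
  photoconverted receptor signal, per-NMJ intensity normalisation (max
  = 1.0), age–output correlation, bouton-position fractions.
* **Turnover**: remaining-fraction and half-life estimation
  (`T½ = dt·ln2 / ln(S0/S1)` under first-order decay, with initial-rate
  and linear alternatives), new-protein accumulation over AZ masks,
  fold-change statistics.
* **Synthetic data**: a generator that renders ground-truth NMJ geometry,
  puncta Z-stacks, stimulation movies (Bernoulli evoked + Poisson
  spontaneous release) and photoconversion time series, so every
  estimator is validated by parameter recovery.

A thin command-line front end (`inst/scripts/quantalmap`) exposes the
pipeline as `simulate`, `detect`, `map-pr`, `timestamp`, `turnover` and
`report` subcommands.

## Worked example

Simulate an NMJ with known per-AZ Pr, record a 5-minute movie under 1 Hz
stimulation, and recover the release map:

```r
library(quantalmap)

gt <- make_geometry(n_boutons = 3, az_per_bouton = 8,
                    pr_distribution = dist_spec("uniform", min = 0.02, max = 0.5),
                    cac_negative_fraction = 0.1, seed = 42)
gt
#> <nmj_ground_truth> 24 AZs in 3 boutons | field 120x120 px (0.133 um/px)
#>   Pr: 0.000-0.498 | spont: 0.12-2.53 /min | 2 Cac- | NMJ area 60.6 um^2

sim  <- simulate_quantal_movie(gt, movie_spec(duration = 300), seed = 43)
rois <- roi_set(gt$synapses$az_id, gt$synapses$x_um, gt$synapses$y_um)
res  <- map_release(sim, rois)
head(res$map, 5)
#>   roi_id evoked_count        pr spont_count spont_per_min pr_flagged
#> 1      1           85 0.2833333           1           0.2      FALSE
#> 2      2          129 0.4300000           5           1.0      FALSE
#> 3      3           68 0.2266667           1           0.2      FALSE
#> 4      4            0 0.0000000           1           0.2      FALSE
#> 5      5           87 0.2900000           7           1.4      FALSE
```

ROI 2 released on 129 of 300 stimulations (Pr = 0.43); ROI 4 is one of the
Cac-negative sites — no evoked release, spontaneous only. Estimated Pr
tracks the simulated truth closely:

```r
pearson_r(gt$synapses$true_pr,
          res$map$pr[match(gt$synapses$az_id, res$map$roi_id)])
#> [1] 0.994
```

Photoconversion pulse-chase turnover, from rendered image stacks:

```r
pc <- simulate_photoconversion_series(gt, half_life_days = 2.56,
                                      timepoints = c(0, 1), seed = 44)
estimate_turnover(pc$stacks$t0$red, pc$stacks$t1$red, dt_days = 1,
                  pixel_size = gt$pixel_size)
#> <turnover_result> 75.4% remaining after 1 d -> T1/2 = 2.45 d (exponential, 20 puncta)
```

And the desk arithmetic the turnover module is built on — e.g. an NMJ
whose photoconverted scaffold sum drops from 121,279 to 88,464 over 24 h
retains 72.94% of its old protein, a single-interval half-life of 2.56
days under the initial-rate convention:

```r
remaining_fraction(121279, 88464)          #> 72.94
half_life(72.94, 1, "initial-rate")        #> 2.56
```

See the methods vignette (`vignettes/quantalmap-methods.Rmd`) for the
models, defaults and numerical choices, and `?quantalmap` for the module
index.

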