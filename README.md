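# coapore

Single-molecule quantification of cyclic oligoadenylate (cOA)
stoichiometry from protein-nanopore recordings.

Cyclic oligoadenylates — rings of 3 to 6 AMP units (cA₃–cA₆) — are the
second messengers of type III CRISPR-Cas immunity: Cas10 synthesizes them
upon target recognition, and they activate downstream CARF effector
nucleases. A single cOA passing through an α-hemolysin pore produces a
resistive pulse with blockade ΔI and dwell time Δt; dwell times scale with
ring size, which makes the stoichiometry of each individual molecule
readable from its event. `coapore` implements the full analysis workflow:

- **Signal** — zero-phase 4-pole Bessel low-pass filtering,
  median-conserving decimation (500 kHz → 80 kHz), open-pore estimation and
  event detection at 65% of the open-pore current; log-normal dwell and
  normal blockade fits; survival bootstrap (1000 resamples, shifted
  single-exponential) for dwell time constants.
- **Classification** — a 1D CNN over fixed-length event tensors (event +
  47-point flanks, normalized, zero-padded to 250 points + a duration
  feature): two conv layers (10 filters, width 25, ReLU) with batch
  normalization and 20% dropout, max-pooling (10), dense softmax; Adam,
  100 epochs, oversampling, 5 restarts; trace-grouped 10-fold
  cross-validation and a KNN (k = 3) baseline on
  (relative blockade, log dwell).
- **Quantification** — event-rate correction factors CF (events s⁻¹ µM⁻¹)
  convert class counts to abundance fractions; 95% prediction intervals
  over cross-validation folds; absolute yield per enzyme complex,
  molecules = r_e · cA_x%/CF_x · d / [complex]; LC-MS peak-area
  concentration and ratio estimators.
- **Statistics** — Welch difference tests and TOST equivalence tests
  between inferred compositions (default margin δ = 15 percentage points,
  the method's resolution limit).
- **Simulation** — a seeded statistical simulator (Poisson arrivals at
  CF × concentration, log-normal dwells, normal blockades, Gaussian
  baseline noise, acquisition low-pass shaping) with ground-truth
  annotations, so the entire pipeline is testable without experimental
  data.

## Worked example

Simulate a monodisperse cA₆ recording at 50 µM, extract events, and fit the
calibration statistics:

```r
library(coapore)

cfg <- simulation_config(duration = 5,
                         classes = default_classes(c(0, 0, 50)),
                         seed = 42)
sim <- simulate_trace(cfg)
nrow(sim$annotations)
#> [1] 37

ex <- extract_events(sim$trace)   # filter -> decimate -> 65% threshold
nrow(ex$events); round(ex$open_pore)
#> [1] 36
#> [1] 1000

fd <- fit_duration_lognormal(ex$events$duration_s)
fb <- fit_blockade_normal(ex$events$deltaI_pA)
```

This prints `dwell: 302 +/- 63 us, blockade: 404 +/- 23 pA` — the 36
detected events recover the configured cA₆ calibration (dwell 315 ± 26 µs,
blockade 400 ± 30 pA) within the sampling error of so few events; the
dwell SD additionally carries detector quantization at 12.5 µs per sample.

Converting an enzymatic measurement into absolute yield — event rate
0.47 s⁻¹, inferred composition 89:8:3 (cA3/4 : cA5 : cA6), dilution 21,
complex concentration 62.5 nM:

```r
cfs <- c(cA34 = 0.17, cA5 = 0.62, cA6 = 0.12)   # events / s / uM
absolute_yield(0.47, c(cA34 = .89, cA5 = .08, cA6 = .03), cfs,
               d = 21, complex_conc_uM = 0.0625)
#> <absolute_yield>
#>   class flowcell_uM reaction_uM molecules_per_complex sd
#> 1  cA34      2.4606       51.67                 826.8  0
#> 2   cA5      0.0606        1.27                  20.4  0
#> 3   cA6      0.1175        2.47                  39.5  0
#>   total: 887 +/- 0 molecules per complex
```

About 890 cOA molecules per type III-A complex, dominated by cA₃/₄.
Passing the published input uncertainties (`r_e_sd`, `cf_sd`,
`fractions_sd`) propagates them to the totals.

A thin command-line front end over the same functions lives at
`inst/cli/coapore.R` (subcommands `simulate`, `detect`, `fitdist`,
`quantify`, `yield`, `lcms`, `compare`, `demo`), and `run_pipeline()`
orchestrates simulate → detect → train → classify → quantify runs with a
JSON provenance manifest.

See the methods vignette (`vignettes/coapore-methods.Rmd`) for the model,
parameter choices, detector bias analysis and known limitations.

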