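# dcvtrace

Quantification of single dense-core-vesicle (DCV) exocytosis from
multi-channel fluorescence time-lapse movies of neurons.

## The scientific problem

Dense-core vesicles release neuropeptides and neurotrophins, but they
fuse rarely and asynchronously, so their exocytosis must be measured
one vesicle at a time. The standard assay images a DCV cargo fused to
superecliptic pHluorin at 2 Hz while the neuron is field-stimulated
(16 bursts of 50 action potentials at 50 Hz): the reporter is quenched
inside the acidic vesicle and unquenches in a single frame when the
fusion pore opens, so each fusion event is a sudden localized
fluorescence step. A pH-insensitive red cargo complements this — it is
visible before fusion, which permits tracking of axonal transport, and
complete cargo release appears as the disappearance of a punctum. An
NH₄Cl superfusion at the end of the recording unquenches every vesicle
and reveals the total labeled pool.

Extracting biology from such movies requires a chain of estimators,
each with failure modes that are hard to audit on real data: fusion
detection must not count a vesicle that *moved into* the measurement
ROI; disappearance must be separated from photobleaching; pool counts
fight diffraction-limited merging; kymograph slopes are only meaningful
on reversal-free, crossing-free streaks; and the final group statistics
need a defensible test-selection policy. `dcvtrace` implements the
whole chain, plus a seeded synthetic movie generator with complete
ground truth (trajectories, event times and modes, synapse positions,
neurite paths), so every estimator is validated end-to-end against
scenes where the answer is known.

The methods vignette (`vignettes/dcv-exocytosis-methods.Rmd`) documents
the model, every default, and the reasoning behind the numerical
choices.

## Worked example

Simulate one cell under the study protocol, detect fusion events,
count the pool, and summarize:

```r
library(dcvtrace)

prot <- build_protocol(nh4_start_s = 80, nh4_duration_s = 10)
sim  <- simulate_scene(scene_config(rng_seed = 1), prot)

ev <- detect_fusion_events(sim$movie, prot, soma_roi = sim$truth$soma_roi)
head(ev[, c("y_px", "x_px", "onset_frame", "peak_dff", "mode")])
#>       y_px     x_px onset_frame  peak_dff       mode
#> 1 45.97256 75.13561          63  9.219987  transient
#> 2 76.94565 31.04815          77  9.706610  transient
#> 3 50.09906 82.96710          85  9.269514  transient
#> 4 65.10569 13.06870          86 10.060338  transient
#> 5 76.11921 36.04326          86 10.446735 persistent
#> 6 41.98683 38.08598          90  9.174676  transient

nrow(ev)                              # detected events
#> [1] 15
sum(!sim$truth$events$somatic)        # ground truth
#> [1] 15

pool <- count_pool_nh4(sim$movie, prot)
ann  <- annotate_events(ev, sim$truth$synapses, protocol = prot)
cell_summary(ann, prot, cell_id = "demo", pool_count = pool$count)
#>   cell_id label n_events n_events_first4bursts fraction_synaptic
#> 1    demo             15                     1        0.06666667
#>   fraction_stationary_prior_to_fusion fusion_rate_stim pool_count non_secreting
#> 1                                  NA            0.625         24         FALSE
```

All 15 true fusion events are recovered at their exact onset frames;
the NH₄⁺ pool count (24) is below the 30 simulated vesicles because
vesicles closer than the diffraction limit merge into single puncta
(see the vignette's pool-counting section).

## The analysis workflow

The study itself lives in `analysis/`, as numbered scripts that write
everything under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | generates the fixture recordings (6 pHluorin cells, 3 red-cargo cells) with full ground truth on disk |
| `analysis/02_detect_events.R` | fusion-event detection, synaptic assignment, pool counting, per-cell summaries |
| `analysis/03_motility.R` | tracking, motility classification, velocities, kymographs, co-trafficking control |
| `analysis/04_dispersion_coloc.R` | activity-triggered dispersion of a synaptic protein; cargo–synapse colocalization |
| `analysis/05_report.R` | aggregate report tables and group statistics |

Headline numbers from running the workflow (seeds are fixed in the
scripts, so a rerun reproduces them exactly):

- **Secretion** (6 cells): 12.3 events per cell, fusion rate 0.514
  vesicles/s during stimulation, 19% of events in the first 4 bursts,
  7% synaptic, 18 persistent / 56 transient, 52% of the labeled pool
  released. Peak ΔF/F₀ synaptic (10.86, n = 5) vs extra-synaptic
  (10.03, n = 69): Mann–Whitney, p = 0.132.
- **Transport** (3 red cells, 149 tracks): 61% mobile; mean pre-stimulus
  speed of mobile tracks 160 nm/s; kymograph ridge speeds on the
  clearest crossing-free streaks 164/131/204 nm/s against track-based
  speeds of 173/174/236 nm/s on the same runs (the track estimator
  includes localization jitter; the ridge measures net drift).
  Co-trafficking control: 0 of 1340 distinct-vesicle pairs.
- **Dispersion** (4 cells): at 160 s, synaptic ΔF/F₀ −0.187 ± 0.003 vs
  shaft +0.221 ± 0.018 (Welch t-test, p = 2.4 × 10⁻²⁴) — activity moves
  the protein out of synapses into the shaft.
- **Colocalization** (6 cells, cargo vs synapse marker): Pearson 0.29,
  Manders M1 0.16 / M2 0.07, object-based fraction within 400 nm 0.12.

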