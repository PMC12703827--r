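# dyadsync

Analysis of interpersonal neural synchronization from dyadic EEG
hyperscanning: two people are recorded simultaneously and the question is
how strongly, and through which channel or region pairs, their band-limited
neural oscillations couple across brains under different interaction
conditions.

The package implements the full analysis chain as tested, reusable R
functions:

* **Preprocessing** — downsampling to 250 Hz, zero-phase 50 Hz notch,
  common-average reference, event-based trial extraction, and zero-phase
  band-pass into the canonical delta (1–3 Hz), theta (4–7 Hz),
  alpha (8–12 Hz) and beta (13–30 Hz) bands.
* **Intersubject correlation (ISC)** — correlated component analysis with a
  single projection `w` shared by both subjects, solving
  `(R_AB + R_BA) w = ρ (R_AA + R_BB + γτI) w`; the ISC score is the sum of
  the three largest component correlations `ρ₁ + ρ₂ + ρ₃`.
* **Interbrain connectivity** — instantaneous phase by Hilbert transform,
  then the phase lag index `PLI = |⟨sign sin(φ_j − φ_k)⟩_t|` for scalp
  channel pairs (blind to zero-lag volume conduction) and the time-averaged
  phase locking value `PLV = |⟨e^{i(φ−ψ)}⟩_t|` for cortical region pairs.
  Only cross-subject pairs enter the matrices.
* **Cortex branch** — a standardized minimum-norm inverse
  (`K = Aᵀ(AAᵀ + λH)⁺`, sLORETA standardization by the resolution diagonal,
  zero localization error in the noiseless case), then PCA reduction to
  62 atlas regions grouped into 7 cortical areas.
* **Network-based statistic (NBS)** — paired edgewise t-maps across dyads,
  signed suprathreshold clustering at |t| ≥ 1.96 on the bipartite
  interbrain graph, and a within-dyad sign-flip permutation null of the
  maximum cluster mass giving family-wise-error corrected cluster
  p-values.
* **Graph metrics** — binary degree, clustering coefficient, transitivity,
  global and local efficiency, with per-area aggregation.
* **Power utilities** — sensitivity (minimum detectable paired effect size)
  and post-hoc power for a two-tailed paired t-test via the noncentral t
  distribution.
* **Synthetic dyads** — a coupled-oscillator generator with von Mises phase
  jitter of known concentration and lag, pink background noise and 50 Hz
  line contamination, plus a toy lead-field/atlas fixture, so every stage
  is testable against planted ground truth without human recordings.

## Worked example

```r
library(dyadsync)

# a dyad with rigid alpha-band coupling (lag pi/4) on channel pair (1, 1)
cfg <- simulationConfig(nChannels = 16, duration = 30, band = "alpha",
                        coupledPairs = cbind(1, 1), kappa = 1e6,
                        lag = pi / 4, noiseSd = 0.5, seed = 7)
rec <- simulateDyad(cfg)
ep  <- preprocessDyad(rec, "alpha")
m   <- interbrainMatrix(instantaneousPhase(ep$A), instantaneousPhase(ep$B))
syncValues(m)[1, 1]
#> [1] 0.9960341

posthocPower(dz = 0.767, n = 30, alpha = 0.05)
#> [1] 0.9820603
sensitivityDz(n = 30, alpha = 0.05, power = 0.80)
#> [1] 0.5292356
```

The planted rigid nonzero-lag coupling survives the full preprocessing
chain as a PLI of ~1 on the coupled pair, and the two power utilities
return the analytic values for the 30-dyad design.

A complete run — simulation, ISC contrast, scalp NBS, cortex branch — is
driven by a YAML config:

```r
demo <- system.file("extdata", "demo_config.yaml", package = "dyadsync")
report <- runPipeline(demo)
```

On the packaged demo (8 dyads, alpha coupling planted in the feedback
condition only) the report shows mean ISC 1.17 under feedback versus 0.23
without (paired t(7) = 23.4), one significant positive NBS cluster
(p_fwer ≈ 0.004) covering the planted channel pairs, and the cortex branch
recovering the planted region pair with PLV 1.0 — i.e. coupled conditions
synchronize, uncoupled ones do not, and the planted structure is localized
correctly.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/dyadsync.R` (subcommands `run`, `validate`, `simulate`,
`power`).

## Vignette

`vignettes/interbrain-methods.Rmd` documents the model and procedure, the
tunable parameters and their defaults, what the synthetic generator does
and does not emulate, the numerical choices, and known limitations.
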