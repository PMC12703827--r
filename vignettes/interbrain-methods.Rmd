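---
title: "Interbrain synchronization methods in dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interbrain synchronization methods in dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

# The analysis problem

In a hyperscanning experiment two interacting people are recorded
simultaneously with EEG, and the quantity of interest is interpersonal
neural synchronization: how consistently the band-limited oscillations of
one brain relate to those of the other, and whether that coupling differs
between interaction conditions (for instance, conversation with feedback
versus without). `dyadsync` implements this analysis at two levels:

* **scalp level** — intersubject correlation (ISC) of channel projections
  and a channels-by-channels interbrain matrix of the phase lag index
  (PLI);
* **cortex level** — a standardized linear inverse onto a 62-region
  cortical atlas, region-by-region phase locking values (PLV), thresholded
  binary networks and graph metrics.

Condition contrasts over a cohort of dyads are tested edgewise with the
network-based statistic (NBS), a cluster permutation method that controls
the family-wise error rate over the thousands of edges.

Only *interbrain* (cross-subject) pairs enter every synchronization
matrix. Within-brain connectivity is deliberately excluded from the
matrices: the scientific object here is coupling *between* brains, and
within-brain coupling is both much stronger and dominated by volume
conduction.

# Preprocessing

Each subject's recording passes through, in order: downsampling to
250 Hz, 50 Hz notch, common-average reference, event-based trial
extraction, and band-pass into one of the four canonical bands
(delta 1–3, theta 4–7, alpha 8–12, beta 13–30 Hz).

Every filter in the chain is applied forward–backward (zero phase). This
is not cosmetic: PLI and PLV are statistics of instantaneous phase, and a
causal filter's frequency-dependent group delay would systematically bias
the phase differences the whole analysis rests on. The specific designs
are the package's own choices:

* **Anti-alias low-pass** for the 500→250 Hz decimation: order-4
  Butterworth (maximally flat, so DC and in-band amplitudes are
  preserved) with cutoff at 80 % of the target Nyquist, forward-backward,
  then every second sample.
* **Notch**: a constrained second-order IIR biquad centred at 50 Hz with
  quality factor 30 (≈1.7 Hz wide), forward-backward. At 250 Hz this
  leaves under 1 % amplitude change at 45 Hz and below while attenuating a
  pure 50 Hz tone by more than 60 dB.
* **Band-pass**: order-4 Butterworth per pass.

Channels are reflect-padded by 2 s before filtering, and the first and
last second of every trial are discarded before phase extraction
(configurable), so filter and Hilbert edge transients never reach the
statistics. Samples are 0-based and trial windows half-open
`[start, start + length)`.

Artifact removal by ICA is not part of the package: the synthetic data the
pipeline is validated on contains no ocular or myogenic artifacts, and
real recordings are expected to arrive pre-cleaned by standard tooling.

# Intersubject correlation

ISC uses correlated component analysis: a single projection vector $w$
shared by both subjects, chosen to maximize the correlation between the
projected time series $w^\top x_A$ and $w^\top x_B$. All components solve
the symmetric generalized eigenproblem

$$(R_{AB} + R_{BA})\, w \;=\; \rho\,(R_{AA} + R_{BB} + \gamma\tau I)\, w,$$

with $R$ the channel covariance matrices across time and
$\tau = \operatorname{mean\,diag}(R_{AA}+R_{BB})$, so the shrinkage
$\gamma$ is scale-free. The eigenvalues $\rho_k$ are the component
correlations and the ISC score is $\rho_1+\rho_2+\rho_3$, the sum of the
top three (fixed at three by convention in this literature; configurable
but not silently padded when fewer components exist).

Two numerical points:

* Average-referenced $c$-channel data has rank $c-1$, so the pooled
  covariance is always singular at $\gamma = 0$; the default
  $\gamma = 0.05$ keeps the problem well posed. With $\gamma = 0$ on
  rank-deficient input the fit aborts with an explicit message rather
  than returning noise-dominated eigenvectors.
* Eigenvectors are defined up to sign; the package fixes each weight
  column so its largest-magnitude entry is positive, making fits exactly
  reproducible.

The method is sometimes labelled "CCA" in the hyperscanning literature,
but classic two-sided canonical correlation fits two different
projections; the shared-weight variant implemented here is what the cited
methodology actually uses, and the identity case ($x_B = x_A$, full rank)
returns all correlations equal to 1 as a built-in self-check.

Condition contrasts of ISC are paired two-tailed t-tests across dyads.
The choice of test is the package's own (the contrast is within-dyad by
design, so pairing is the natural structure); the degenerate all-equal
case returns $t = 0,\ p = 1$ rather than failing.

# Phase synchronization metrics

Instantaneous phase is the argument of the FFT-based analytic signal of
each band-limited channel. An all-zero channel has no defined phase; it
is masked, and every matrix entry involving it becomes missing rather
than NaN.

**PLI** is used at the scalp:

$$\mathrm{PLI} = \Bigl|\,\tfrac1n \sum_t \operatorname{sign}
  \sin\bigl(\varphi_j(t) - \varphi_k(t)\bigr)\Bigr| \in [0,1].$$

The convention $\operatorname{sign}(0) = 0$ matters. A definition that
maps zero phase difference to $-1$ would assign PLI = 1 to *identical*
signals — precisely the volume-conduction artifact PLI exists to discard.
The package follows the standard convention, under which identical
signals give PLI = 0 and any consistent nonzero lag gives PLI = 1. The
absolute value makes the index symmetric in the pair ordering and maps it
into $[0, 1]$.

**PLV** is used at the cortex level, where source reconstruction has
already suppressed volume conduction and zero-lag coupling is potentially
meaningful:

$$\mathrm{PLV} = \Bigl|\,\tfrac1T \sum_t e^{i(\varphi(t) - \psi(t))}\Bigr|,$$

the time-averaged variant appropriate for single long trials (rather than
averaging across repeated event-locked trials). Its null value at trial
length $T$ concentrates near $\sqrt{\pi/(4T)}$, about 0.004 at
$T = 45\,000$ samples.

Using PLI where PLV is expected (or vice versa) requires an explicit
override flag, so a mixed-up metric cannot happen silently.

**Thresholding.** Before graph metrics, matrices are sparsified with a
proportional rule: keep the strongest fraction $p$ (default 0.2) of
entries, ties at the cutoff all kept; an absolute-cutoff rule is also
available. The NBS branch consumes *unthresholded* matrices — it has its
own cluster-forming threshold, and pre-thresholding would distort its
permutation null.

# The cortex branch

The forward model is $Y = AX$ with $A$ the channels-by-sources lead
field. Real head modelling (template anatomy, boundary element method)
is out of scope; the module contract starts at a provided lead-field
matrix, and the package ships a controlled toy construction instead:
random orthogonal factors around a log-spaced singular spectrum (so the
condition number is set exactly), with columns projected onto the
average-reference subspace.

The inverse is the standardized minimum norm: kernel
$K = A^\top (A A^\top + \lambda H)^{+}$ with $H$ the average-reference
centering operator, raw estimate $\hat J = K y$, and standardization of
each source by the square root of the corresponding diagonal of the
resolution projection $S = K A$. The default
$\lambda = 0.05 \cdot \operatorname{tr}(A A^\top)/n_{ch}$ is scale-free
diagonal loading; with noiseless data and $\lambda \to 0$, the
standardized estimate attains its maximum at the true source (the
zero-localization-error property), which the test suite verifies
exhaustively over random single-source fixtures.

Sources are then reduced to 62 atlas regions: per region, the first
principal component of its member-source series (covariance PCA, time as
observations, mean-removed), sign-aligned so its correlation with the
region-mean series is non-negative, scaled to unit variance.
Standardization happens *before* ROI reduction: the inverse is the place
where depth bias is corrected, and reducing unstandardized estimates
would let superficial sources dominate every region component. The 62
region names follow the Desikan–Killiany–Tourville parcellation (31 per
hemisphere); their grouping into 7 areas (prefrontal, frontal, central,
parietal, occipital, temporal, limbic) involves judgement calls at the
boundaries — the cingulate subdivisions, entorhinal and parahippocampal
cortex and the insula are grouped as "limbic" here — made once and fixed
in `dktAtlasTable()`.

# Network-based statistic

For a paired contrast over $n$ dyads the per-edge statistic is the
one-sample t of the within-dyad differences,
$t = \bar d \sqrt{n} / s_d$, df $= n - 1$. An edge whose difference is
constant across dyads has $s_d = 0$; its t is set to 0 with a warning
(an infinite t from degenerate data would otherwise dominate every
cluster). Edges missing in any dyad are dropped before thresholding.

Edges with $|t| \ge 1.96$ (the conventional two-tailed 5 % normal
quantile, kept fixed rather than df-adjusted, configurable) are clustered
into connected components of the bipartite graph whose vertices are
subject-tagged channels/regions — positive and negative edges separately,
since a cluster mixing signs would be uninterpretable. The graphs are
undirected, so "strongly connected" and "connected" components coincide;
the package computes the latter.

The null distribution of the maximum cluster mass $|\sum_{e} t_e|$ comes
from within-dyad sign flips: flipping a dyad's condition labels negates
its difference vector while preserving the dyad's internal structure,
which is the correct exchangeability for a paired design (a fully
unpaired shuffle would break the pairing and inflate the null). When
$2^n$ does not exceed the requested permutation count the enumeration is
exhaustive and the seed becomes irrelevant. Cluster p-values use the
$+1$ correction, $p = (1 + \#\{\text{null} \ge |m|\})/(1 + n_{perm})$,
so they are never exactly zero.

Computationally, a sign flip leaves each edge's sum of squared
differences unchanged, so all permutation t-maps reduce to one matrix
product; only the (few) suprathreshold edges of each permutation are
clustered, with a small union-find. This keeps a 200-repetition
family-wise-error calibration (20 dyads, 500 permutations, 8×8 matrices)
in the test suite's seconds range.

# Graph metrics

Metrics are binary and undirected: degree (row sums), clustering
$C_i = 2t_i/(k_i(k_i-1))$ with $t_i$ the triangles through node $i$ (0
when degree < 2), transitivity $\sum 2t_i / \sum k_i(k_i-1)$, global
efficiency as the mean inverse shortest-path length over ordered pairs
with $1/\infty = 0$ for disconnected pairs, and local efficiency of a
node as the global efficiency of its neighbor-induced subgraph. Binary
metrics after proportional thresholding is the most common protocol in
this literature; weighted variants are out of scope.

One structural caveat is worth stating loudly: a purely interbrain
network is bipartite and therefore triangle-free, so its clustering
coefficients and transitivity are identically zero. Nonzero values of
these metrics require within-brain edges in the adjacency. The package
computes whatever adjacency it is given and leaves the choice — and the
caveat — to the analyst; the area-aggregation step works identically for
either.

# Power utilities

Sensitivity and post-hoc power for the two-tailed paired t-test use the
noncentral t distribution (df $= n-1$, noncentrality $d_z\sqrt n$), not a
normal approximation; the lower rejection tail is included, which moves
the fourth decimal. At $d_z = 0$ the power equals the test size $\alpha$
exactly. The sensitivity solver inverts the power function by bracketed
root-finding to $10^{-6}$. A design-analysis caveat: effect sizes
reported as Cohen's $d_{rm}$ (repeated-measures, correlation-corrected)
are not identical to $d_z$, but power routines for paired designs consume
$d_z$; the package reproduces that standard computation and leaves the
$d_{rm}$-vs-$d_z$ distinction to the user.

# The synthetic-data generator

Because public dyadic recordings with known coupling do not exist, the
generator is first-class, tested code, and every downstream stage is
validated against its planted ground truth.

Each channel of subject A carries a narrowband oscillation whose
instantaneous frequency is an AR(1) process with ≈0.3 s correlation time
spanning the configured band, integrated to phase — so independent
channels decorrelate quickly and null PLI/PLV decay with trial length as
they should. A coupled channel of subject B reuses A's phase plus a fixed
lag plus per-sample von Mises jitter of concentration $\kappa$: the
planted circular phase-difference distribution is exactly
von Mises($\mathrm{lag}, \kappa$), giving analytic control of the
ground-truth PLV (the Bessel ratio $I_1(\kappa)/I_0(\kappa)$) and a PLI
that increases monotonically in $\kappa$. $\kappa = 0$ is fully
independent; $\kappa \to \infty$ is rigid locking with PLI = 1 at any
nonzero lag. A zero lag is legal but flagged with a warning, since PLI is
blind to it by construction. Each subject-B channel can follow at most
one subject-A channel (a phase can only track one driver); configurations
violating this are rejected at validation.

All channels receive pink (1/f) background noise by spectral shaping and
a pure 50 Hz sinusoid, so the notch stage is genuinely exercised. Cohort
generation derives per-dyad, per-condition child seeds from the master
seed by a fixed multiplicative recurrence, so any single dyad is
reproducible in isolation. One event mark is placed at trial start;
trials are generated per condition rather than cut from a long
concatenated recording, avoiding boundary effects.

What the generator does *not* emulate: realistic scalp topographies,
ocular/myogenic artifacts, amplifier-specific quirks, or inter-channel
volume-conduction mixing beyond what the common-average reference
introduces. Passing tests therefore demonstrate the *statistical
machinery* — filters, phase metrics, eigenproblems, permutation inference
— not robustness to real-world artifact structure. No published
quantitative SNR description exists for this kind of recording; the
defaults (10 µV oscillations, 1 µV pink noise, 0.5 µV line) were chosen
once for testability, not realism.

Recordings are serialized to the plain continuous-recording subset of EDF
(16-bit samples, 1 s records, per-signal physical scaling) with events in
a sidecar manifest TSV rather than an annotations channel; cortex
fixtures are TSV directories.

# Problem sizes

The defaults mirror the acquisition this pipeline targets: 32 channels
per subject, 500 Hz, 3-minute trials, four bands, 5000 permutations,
$t_{crit} = 1.96$, $\alpha = 0.05$, top-3 ISC. The test suite and the
packaged demo run the same code at reduced sizes chosen by the package —
6–16 channels, 12–30 s trials, 8–20 dyads, 200–500 permutations, a
64-channel/62-source toy lead field — which keep each planted effect
detectable (the rigid-coupling PLI check, for instance, needs enough
channels that the common-average subtraction perturbs each channel only
mildly) while the whole suite runs in well under a minute.

# Known limitations

* ICA artifact handling, head modelling, and electrode calibration are
  out of scope; the pipeline starts at cleaned data and a given lead
  field.
* Only two-subject (dyadic) CorrCA; no multi-subject extension.
* NBS supports the paired (within-dyad) design only; no unpaired
  two-group variant.
* Graph metrics are binary; no weighted, small-world, modularity or
  rich-club variants.
* The EDF reader covers the fixed-rate 16-bit subset the writer emits,
  not EDF+ annotations or variable-rate signals.
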