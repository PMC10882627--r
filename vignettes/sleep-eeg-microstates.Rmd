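---
title: "Methods: all-night spectral and NREM-3 microstate analysis of two-group sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: all-night spectral and NREM-3 microstate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

somnistate implements a complete two-group all-night sleep-EEG comparison:
a stage-resolved spectral arm (multitaper relative band power with
cluster-based permutation statistics) and an NREM-3 microstate arm
(polarity-invariant topographic clustering, template validation by spatial
correlation, backfitting, and temporal/transition statistics). Because
clinical polysomnography of this kind is rarely shareable, the package
also ships a seeded synthetic cohort generator whose spectral and
microstate ground truth is known exactly; every stage of the pipeline is
validated by recovering what was planted.

This vignette is the package's methods account: the models, the tunable
parameters and why their defaults are what they are, what the generator
does and does not emulate, the numerical choices, and the known limits of
what the tests demonstrate.

## Preprocessing

Recordings are 19-channel 10–20 scalp EEG (plus mastoid reference
channels M1/M2), nominally acquired at 1 kHz and analysed at 250 Hz
(`downsample()`, integer decimation behind a zero-phase anti-alias
low-pass). Both analysis arms re-derive their data from the raw recording
independently:

* **Spectral arm** — linked-mastoid reference (mean of M1/M2 subtracted,
  mastoids dropped), band-pass 0.5–30 Hz.
* **Microstate arm** — average reference (per-sample mean over the 19
  scalp channels subtracted, so every sample sums to zero across
  channels), band-pass 1–40 Hz, per-epoch demeaning and linear
  detrending.

Filtering is a Hamming-window FIR band-pass applied forward and backward
(zero net phase), implemented as a single FFT convolution with the
filter's autocorrelation kernel — numerically identical to the two-pass
form. The nominal order (1000) refers to the 1 kHz acquisition rate; at a
working rate of 250 Hz the order is scaled to 250 so the impulse response
keeps its physical duration. An order-250 Hamming FIR at 250 Hz has a
transition width of roughly 3 Hz; the 0.5 Hz lower edge is therefore a
gentle roll-off rather than a brick wall, and measured relative delta
power sits slightly below the generator's planted weight. This affects
both groups identically and cancels out of every group contrast.

Epoching follows the hypnogram: 30-s epochs, half-open sample windows
`[kL, (k+1)L)`. An epoch is rejected iff its arousal fraction is
*strictly greater* than 0.15 — "more than 15%" is read literally, so a
fraction of exactly 0.15 is retained. Epochs overlapping the first or
last filter-order samples of the recording are dropped to keep filter
transients out of the analysis.

## Spectral arm

Power spectral densities are estimated per epoch with DPSS (Slepian)
multitapers. The tapers are computed from the standard symmetric
tridiagonal eigenproblem (Sturm-sequence bisection for the K largest
eigenvalues, inverse iteration for the vectors), and each taper's in-band
concentration is evaluated exactly through a Toeplitz-times-vector FFT
product; the tapered periodograms are averaged with concentration
weights. The default half-bandwidth is 0.5 Hz, which on 30-s epochs gives
NW = 15 and 29 tapers and resolves the 0.5 Hz delta edge. The density is
one-sided and scaled so that its integral over frequency equals the
signal variance (the test suite checks this Parseval identity to 1%).

Band powers (delta 0.5–4, theta 4–8, alpha 8–12 Hz; beta deliberately not
analysed) are trapezoidal integrals of the density, exactly additive over
adjacent bands. Relative power divides each band by the total power over
the analysed 0.5–30 Hz range, computed **per channel**; normalizing by a
channel-pooled total is a defensible alternative, but per-channel
normalization keeps each electrode's relative profile self-contained and
is what the difference topographies assume. Subject-level values are
unweighted means over the subject's retained epochs.

Group statistics are two-level. Within each (stage, band) cell a
cluster-based permutation test runs over channels: pooled-variance t per
channel, channels beyond the two-sided t critical value at
`cluster_alpha = 0.05` clustered under montage adjacency (electrodes
closer than 0.63 head-radii are neighbours), cluster mass = sum of t, and
a Monte-Carlo null from `n_perm = 1000` random group relabelings using
the maximum cluster mass (p = (1 + #{null ≥ obs}) / (1 + n_perm)).
Across cells, the minimum cluster p-values are BH-FDR corrected; a
separate BH-FDR over all channel-wise t-test p-values
(channels × stages × bands) yields per-channel significance flags for the
difference topographies. Both layers are reported separately.

## Microstate arm

Analysis is restricted to NREM 3 by default (the stage is configurable):
deep sleep is where subject topographies correlate best with the
canonical template geometry, and restricting the analysis keeps the
parameter statistics comparable across subjects.

Per subject, the retained N3 epochs are concatenated and the topographic
maps at **GFP peaks** (strict local maxima of the spatial standard
deviation; endpoints never qualify) are clustered with the **modified
k-means** algorithm: assignment by maximal squared spatial correlation
(polarity ignored), template update as the dominant eigenvector of the
assigned maps' outer-product sum, convergence on a GEV improvement below
1e-7 or 300 iterations, 20 random restarts (restart r seeds the RNG with
`seed + r - 1`), best restart by GEV. Empty clusters are re-seeded from
the worst-explained map. All GFP peaks enter the clustering (no
subsampling); cohort sizes here never make that prohibitive, and
subsampling is an easy extension if memory demands it.

Spatial correlation is the printed global-dissimilarity formula
`sum(u*v)/sqrt(sum(u^2)*sum(v^2))`, which on average-referenced maps
equals the spatial Pearson correlation. (The literature calls the
quantity a *dissimilarity* index; the formula as printed is a similarity,
and the package names the operation `spatial_correlation` accordingly.)

Aggregation is subject → group → grand mean: each group's pooled subject
template maps are re-clustered with the same modified k-means (a
two-level clustering; sign-aligned averaging is the documented
alternative), group sets are sorted against parametric canonical
templates (exhaustive best permutation maximizing total |r|, signs
flipped positive, ties broken by map index), and the grand mean averages
the sign-aligned group maps. Subject sets are sorted against the grand
mean; a subject whose best template-to-GM |r| falls below 0.5 is excluded
from statistics and logged — the screening act mirrors practice, the 0.5
value is this package's choice and is configurable.

Temporal parameters come from backfitting the grand-mean templates to
every sample of each subject's N3 data (squared-correlation argmax;
zero-variance samples inherit the previous label). Coverage, mean run
duration (ms), occurrence (runs/s) and mean per-class GFP are computed
from the run-length encoding; transitions are counts of consecutive
distinct runs normalized globally (all ordered pairs sum to 1, matching
mean-transition-percentage displays) with a row-normalized version
exported alongside. Groups are compared per parameter and class with the
Wilcoxon rank-sum test (exact for pooled n ≤ 20 without ties), Bonferroni
corrected with m = 16 (4 classes × 4 parameters). Transitions use m = 12,
the count of directed pairs among 4 classes without self-transitions
(0.05/12 = 0.0042); a coefficient of 16 appears in parts of the
literature for the same comparison and `transition_m` is configurable for
that reading.

## The synthetic cohort generator

The generator is the package's test bed. It emulates exactly what the
pipeline consumes: two groups of 17 subjects, 19-channel 10–20 EEG at
250 Hz plus mastoid channels, 30-s staged epochs (plausible W → N1 → N2 →
N3 → N2 → REM cycles with seeded jitter; short nights compress the cycle
so all stages stay represented), Poisson arousals (3–15 s, recorded only
as per-epoch fractions — arousal is a rejection criterion, not a signal
feature), and two planted group effects:

* **Spectral**: per stage, the signal is a sum of band-limited noise
  components (delta/theta/alpha plus a 12–30 Hz residual), each
  synthesized directly in the frequency domain and mixed through smooth
  spatial patterns for channel correlation, scaled by stage-dependent
  weights (rows sum to 1) and per-stage RMS amplitudes. Each band's
  mixing uses a stereotyped topography shared by all subjects plus a
  0.35-weight individual perturbation — scalp band topographies are
  fairly consistent across people, and a fully idiosyncratic topography
  per subject would bury a scalp-wide group effect in channel-level
  between-subject variance that real data do not show. Patients' theta
  weight in N2 and REM is multiplied by `theta_effect = 1.3`; per-subject
  log-normal weight jitter (SD 0.08) supplies the between-subject
  variability the group tests must overcome.
* **Microstates**: N3 samples carry an additive component: a semi-Markov
  sequence over the four canonical topographies (geometric dwell times,
  mean 90 ms — memoryless, the simplest law consistent with a first-order
  transition matrix; occurrence then lands near 2.8 s⁻¹), each run
  expressed as a 10 Hz sinusoidal activation of its template with a
  run-wise random phase. Controls use a uniform transition matrix;
  patients have A↔B reduced to 0.15 and C↔D raised to 0.50 per row.

Two generator choices deserve their rationale. First, the activation is a
*signed* sinusoid rather than a positive envelope: any strictly positive
envelope loses its DC component in the 1–40 Hz band-pass and acquires
spurious zero crossings, whereas a sinusoid passes the filter unchanged,
produces the same 20 GFP peaks per second, and polarity is ignored by the
entire microstate machinery anyway. Second, its amplitude
(`ms_amplitude = 600` µV against an N3 background RMS of 40 µV per
channel) was calibrated once, by a small recovery experiment, to the
weakest setting at which template recovery, backfit accuracy and
transition recovery are all comfortably attainable — the real study
reports no SNR to match, so the amplitude is a test-bed parameter, not a
physiological claim, and the resulting GFP scale is likewise not matched
to clinical microvolt values.

A sinusoidal activation crosses zero twice per cycle, and at those
instants the sample's topography is pure background: a per-sample
backfit acquires 1–2-sample mislabelled blips there. The pipeline's
metric path therefore merges runs shorter than `smooth_ms = 20` ms into
the better-correlated neighbour before computing parameters (the
`backfit()` operation itself defaults to no smoothing). The merging
absorbs genuinely short dwells too, which biases mean durations upward by
roughly 20% relative to the planted 90 ms and correspondingly lowers
occurrence; transition *structure* — the quantity the group comparison
targets — is recovered to within 0.05 per row entry on 30 minutes of N3,
which the acceptance suite checks.

What the generator does **not** emulate: spindles and K-complexes,
realistic sleep architecture and its overnight evolution, EOG/EMG and
other polygraphy, movement or electrode artifacts, 1/f background
structure, or volume-conduction physics. Passing recovery tests therefore
demonstrates the pipeline's correctness and statistical calibration on
data satisfying its model assumptions — not robustness to clinical
artifact or to template geometries far from the canonical set.

## Numerical choices and degenerate inputs

* GFP uses the population (1/n) spatial standard deviation.
* GEV is GFP²-weighted squared correlation, computed on the same samples
  the fit used (peaks for clustering, all samples for backfit metrics).
* Template maps are always average-referenced and unit-normalized; the
  eigenvector update preserves both.
* Zero-variance samples cannot be labelled; backfitting lets them inherit
  the previous label (a leading degenerate stretch takes the first valid
  label). Zero-variance maps make spatial correlation undefined and raise
  an error rather than returning a value.
* Epochs with zero total power are dropped from relative-power tables
  with a flag.
* The Wilcoxon implementation switches from exact enumeration to the
  tie-corrected normal approximation beyond pooled n = 20; the two paths
  agree within 0.02 at n = 10 + 10.
* EDF I/O uses the 16-bit continuous subset with 1-s records; round-trip
  error is bounded by half a quantization step of the per-channel
  physical range.
* All stochastic steps (generator, k-means restarts, permutations) are
  seeded and restore the caller's RNG state; identical configurations
  reproduce cohorts and reports bit for bit.

## Problem sizes used by the test and acceptance runs

The packaged validation runs at desk scale, chosen as the smallest sizes
at which every planted effect is still comfortably detectable: smoke
tests use 4 + 4 subjects with one compressed 7.5-minute sleep cycle;
the replication suite uses ten seeded cohorts of 17 + 17 subjects with
7.5-minute nights and evaluates the spectral arm on N2 and REM (where the
planted theta effect lives); transition recovery uses one subject with
30 minutes of N3; the permutation-test calibration uses 1000 null
replicates of 17 + 17 subjects over 19 channels. With these sizes the
planted theta elevation and both transition asymmetries are flagged in
at least 9 of 10 cohorts, and the null family-wise error rate of the
cluster test stays within [0.03, 0.07].

## Limitations

* The canonical template geometry is parametric (two diagonal gradients,
  an anterior–posterior gradient, a fronto-central extremum); real
  normative maps differ in detail, and sorting against them would change
  labels, not machinery.
* Global transition proportions are coupled across cells (they sum to 1),
  so a planted change in one pair necessarily shifts others; the
  row-normalized export disentangles this at the cost of conditioning on
  the source state.
* The two-level correction scheme (cluster MC within cell, FDR across
  cells) is one reading of a procedure that combines cluster correction
  with FDR "across spectra and sleep phases"; both layers are reported so
  either can be consumed alone.
* Durations and occurrences inherit the smoothing bias described above;
  between-group contrasts are unaffected because both groups share the
  estimator.
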