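---
title: "Full-brain correlation models and conditional reconstruction of intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-brain correlation models and conditional reconstruction of intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingp)
```

## The model and its assumptions

Intracranial recordings sample a patient's brain at a sparse, clinically
chosen set of electrode locations. `braingp` treats the multichannel
voltage trace as a draw from a zero-mean Gaussian process over brain
locations whose correlation structure is (i) smooth in space and (ii)
partially shared across people. Under those two assumptions, recordings
from *other* patients constrain the correlations between locations a given
patient never recorded, and the conditional expectation of a jointly
Gaussian vector provides the reconstruction:

$$\hat Y_\beta = \left( K_{\beta\alpha} K_{\alpha\alpha}^{-1} Y_\alpha^\top \right)^\top,$$

where $\alpha$ indexes the patient's observed model locations, $\beta$ the
unobserved ones, and $K$ is the merged full-brain correlation matrix. The
estimator is applied independently at every timepoint, so long sessions
are processed in chunks with bitwise-identical results.

Everything operates on per-session z-scored voltages. This is a modeling
decision, not a convenience: electrode impedances (and hence absolute
voltage scales) are unknowable for electrodes that were never implanted,
so the method recovers activity in standard-deviation units. The observed
columns of a reconstruction are the z-scored inputs, passed through
untouched.

The correlation model itself is built in three steps.

1. **Per-patient correlations.** Pearson correlations are computed per
   session and averaged across sessions on the Fisher z scale
   ($z(r) = \tfrac12[\log(1+r) - \log(1-r)]$, inverse $\tanh$), which makes
   correlations approximately additive. The diagonal is forced to 1, and
   correlations are clipped to $\pm(1 - 10^{-6})$ before the transform so
   degenerate $|r| = 1$ inputs cannot produce infinities.
2. **Spatial expansion.** Each patient's electrode-pair correlations are
   spread over arbitrary model locations by radial-basis-function
   weighting, $w(\chi \mid \eta) = \exp(-\lVert\chi - \eta\rVert^2/\lambda)$,
   accumulating a weighted numerator (z-values) and denominator (weights)
   over unordered electrode pairs. The raw pair sum is asymmetric in the
   target pair; we accumulate the sum plus its transpose, which for the
   full pair sum equals $W Z W^\top$ with a zero-diagonal $Z$ — a
   correlation matrix must be symmetric, and the diagonal is defined to be
   1 at materialization rather than carried through the sums.
3. **Merging.** Numerators and denominators sum across patients —
   exactly associative and commutative — and the model materializes as
   $\tanh(\Sigma N / \Sigma D)$ with unit diagonal. A patient's influence
   on any location pair is proportional to how close their electrodes come
   to both locations.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `lambda` | 20 | mm² | RBF width; larger values smooth correlations over more cortex and generalize further from the electrodes at the cost of spatial resolution. The default matches the scale at which pooled electrode coverage spans a 4-mm brain grid. |
| `ridge` | 1e-5 | correlation scale | Eigenvalue floor applied to $K_{\alpha\alpha}$ before the solve (below). |
| `kurtosis_threshold` | 10 | excess kurtosis | Channels whose maximum per-session excess (Fisher) kurtosis reaches this are treated as spike-contaminated/epileptiform and dropped. Gaussian channels score ≈ 0. |
| `target_rate_hz` | 250 | Hz | Common samplerate after downsampling. |
| `notch_hz ± halfwidth` | 60 ± 0.5 | Hz | Line-noise stop band, 4th-order Butterworth, zero phase. Harmonics are left alone by default (`extra_notch_hz` adds them). |
| `chunk_size` | 10000 | timepoints | Reconstruction block length; affects memory only, never values. |
| `radius` | 20 | mm | Closed ball used by density and information-score maps (ties at exactly the radius are included). |
| `fraction` | 0.1 | — | Top-fraction cutoff for map intersections; ties at the cutoff are all kept, so the set can slightly exceed the fraction but is deterministic. |

Kurtosis is computed on notched, downsampled data (the exclusion step sits
after those two in the pipeline) with the moment formula
$m_4/m_2^2 - 3$; the threshold applies to the excess statistic. Both the
position of the exclusion step and the excess convention are configurable
interpretations — the pipeline order is explicit in `preprocess()`.

## Numerical choices

**Scaled accumulators.** With $\lambda = 20$ and MNI-scale distances,
products of RBF weights underflow double precision beyond roughly 120 mm,
which would zero the denominator for distant location pairs even though
the pair sum is mathematically strictly positive. The accumulator
therefore stores, per target pair, scaled sums plus a log scale factor
(the minimum squared electrode distance per target, factored out of the
weights); merging rescales to the elementwise maximum scale, as in
log-sum-exp. Ratios are scale-invariant, so the materialized model equals
the literal sums wherever those are representable — the unit tests verify
this against nested-loop evaluation — and remains defined everywhere else.
A genuinely zero denominator (possible only in degenerate hand-built
accumulators) is still an error naming the uncovered pair.

**Conditioning.** The weighted-average estimator is not guaranteed
positive semi-definite. Before inversion, $K_{\alpha\alpha}$ has negative
eigenvalues clipped to zero (with renormalization to unit diagonal; a
no-op for PSD input), then a ridge is folded in as
$(K + \text{ridge}\,I)/(1 + \text{ridge})$, flooring the smallest
eigenvalue at $\text{ridge}/(1+\text{ridge})$ while perturbing any entry
of a PSD matrix by less than the ridge. The solve is a Cholesky
back-substitution; an explicit inverse is never formed.

**Zero-phase filtering.** Forward–backward IIR filtering has transfer
function $|H(\omega)|^2$. We apply that response directly in the frequency
domain rather than running `filtfilt` twice in time: a 1-Hz-wide 4th-order
notch rings for seconds, and time-domain startup transients leave several
percent residual RMS on short segments, while the spectral application is
transient-free (at the cost of circular boundary conditions, negligible
for near-allpass stop/pass bands). Phase is exactly zero either way, which
matters because phase distortion would corrupt the cross-electrode
correlations the whole method is built on.

**Resampling** is Fourier-domain spectrum truncation (the new length is
$\mathrm{round}(T \cdot f_\text{new}/f_\text{old})$); truncation doubles
as the anti-aliasing filter. Upsampling is rejected.

**Electrode matching.** Electrodes are matched to model rows by nearest
neighbor within 0.5 mm (they normally originate from the same table);
near-duplicate model locations are collapsed at $10^{-6}$ mm. Unmatched
electrodes error with the nearest row and distance, never silently
reassign.

**Non-finite samples** at ingestion are an error by default; an explicit
flag drops affected timepoints with a logged count. Silent imputation
would bias correlations.

## Spectral derivatives

Narrowband activity uses second-order Butterworth band passes at the
canonical bands (δ 2–4, θ 4–8, α 8–12, β 12–30, γL 30–60, γH 60–100 Hz;
the γH upper edge sits below the 125-Hz Nyquist of 250-Hz data, asserted
at validation). Broadband power is the mean height of a robust line fit
(bisquare IRLS, tolerance $10^{-8}$, 50 iterations) in log-log space to
the Morlet wavelet power spectrum at 50 log-spaced frequencies from 2 to
100 Hz. "Mean height" is the mean of the fitted line over the grid —
equivalently the fit at the mean log frequency; an intercept-at-1-Hz
reading of the same fit would differ only by a slope multiple. Natural
logs are used throughout; any fixed base would rescale BB by a constant.

The Morlet wavelet of order (wavenumber) $q$ has spectral SD $f/q$ at
center frequency $f$ and is applied as a one-sided Gaussian in the
frequency domain, **L2-normalized** so the mean squared gain across the
DFT grid is 1. This normalization makes white noise of variance $v$ read
as flat log power $\log v$ at every analysis frequency, and $1/f^\gamma$
inputs read as lines of slope $-\gamma$ — the properties that make the
broadband estimator interpretable. The time-resolved BB series is
computed on 1-s windows by default (the window length is an exposed
choice; nothing in the estimator pins it) and is returned as a recording
at the window rate, so band-limited traces, Hilbert band power
(band pass → squared analytic-signal amplitude) and BB series all flow
into the correlation model unchanged.

## What the synthetic generator emulates — and what it does not

`make_ground_truth()` draws $M$ locations uniformly in a brain-sized box
and builds a correlation matrix from a Gaussian spatial covariance
$\exp(-d^2/2s^2)$ (default scale $s = 30$ mm) mixed with a random rank-3
component at weight 0.3, floored in eigenvalue and renormalized. The two
ingredients mirror the model's own assumptions: smooth local structure
plus distributed long-range correlations shared by all patients. The
low-rank part matters for the cross-patient analyses — with purely local
structure, electrodes far from every other patient's coverage would carry
no transferable signal.

`simulate_patient()` samples a clustered electrode subset (random anchor
plus nearest neighbors) to mimic grid/strip implants: each patient's
nearest neighbors are their own electrodes, which is exactly the geometry
that makes the within- versus across-patient comparison meaningful.
Sessions are independent multivariate normal draws from the restricted
ground truth — Gaussian marginals by default so the correlation model is
exactly matched. Options add 60-Hz line noise, spike contaminants (1% of
samples at ±20σ, which pushes excess kurtosis far past the exclusion
threshold), and $1/f^\gamma$-shaped marginals via identical per-channel
frequency shaping (which preserves the zero-lag correlation matrix in
population while exercising the spectral stack).

Default study conditions, fixed once: 8 patients, 12 electrodes each, one
session of 10 000 samples at 250 Hz, $M = 40$ ground-truth locations,
contaminants off. The model-recovery property uses 5 000 samples per
patient; the evaluation-noise grid in the tests spans 30–1500 samples
because correlation-estimation noise stops limiting accuracy past roughly
a thousand samples, after which the spatial-smoothing bias of the
expansion dominates.

Passing tests on this generator demonstrate that the estimator chain is
correct *under its own assumptions* — stationary Gaussian signals, a
single correlation structure shared exactly across patients, electrodes
located exactly at model locations. Real intracranial data violate all
three (nonstationarity, task- and person-specific correlations,
localization error), so synthetic accuracies bound what clean data could
give; they do not predict clinical accuracy.

## Evaluation design

Leave-one-electrode-out accuracy holds out each electrode of each patient,
reconstructs it from the patient's remaining electrodes, and correlates
reconstruction with truth per session, aggregating sessions on the Fisher
z scale (the same averaging space used everywhere else; the choice is
consistent rather than consequential). In **across** mode the correlation
model is merged from every patient except the one being reconstructed —
the held-out patient's data can never leak into the model, which the
implementation asserts against the accumulator's provenance log. In
**within** mode the model comes from the held-out patient's remaining
electrodes only. Mode comparisons use per-patient means of z-transformed
accuracies: one-sample t against zero per mode, paired t across modes.

Information-score maps assign every electrode its patient's mean
reconstruction accuracy and average those values over all electrodes
within 20 mm of each voxel center, so patients with more electrodes near a
voxel weigh proportionally more; voxels with no electrode in range stay
missing. This electrode-count weighting is the most literal reading of a
"weighted average over patients with nearby electrodes" and is the one
implemented; a patient-level mean-of-means would weight sparse and dense
patients equally and is deliberately not used.

Train/test session splits (`train_sessions`) generalize the evaluation to
across-recording-set designs without hard-coding any task semantics.

## Degenerate inputs and edge cases

Zero-variance channels error (they should have been excluded upstream);
sessions shorter than 3 samples cannot be correlated; a patient reduced to
one electrode is dropped entirely with a reasoned report row; an empty
model (zero patients) loads but refuses to materialize; an empty-mask
voxel map writes an all-NaN volume with a warning; a constant spectrum
still yields a defined broadband fit (slope 0, via the least-squares
fallback when the IRLS weights degenerate).

## Known limitations

- The RBF width is fixed, not learned; cross-validating λ is a natural
  extension the package deliberately leaves out.
- Correlation structure is assumed static over time; session-to-session
  drift is averaged, not modeled.
- Only the conditional mean is produced — no posterior variance, hence no
  uncertainty on reconstructed traces.
- Reconstructions are in z-units; absolute voltages are unrecoverable by
  design.
- The shipped brain mask is a synthetic ellipsoid approximating the
  MNI152 head box, adequate for masking synthetic studies but not a
  tissue boundary; substitute a real template mask for anatomical work.
- With very sparse coverage (few patients with small, distant clusters),
  model entries between locations no training patient covers jointly are
  extrapolations; the evaluation machinery reports the resulting accuracy
  honestly, but such configurations sit outside the regime the method is
  meant for.
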