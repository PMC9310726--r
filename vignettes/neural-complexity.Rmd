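---
title: "Normalized LZ78 complexity of intracranial signals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized LZ78 complexity of intracranial signals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurolz)
```

## The measure

Lempel–Ziv complexity quantifies the diversity of a signal by counting the
distinct patterns an incremental dictionary parser discovers in its
binarized form. `neurolz` implements the LZ78 word-dictionary variant: the
scanner grows the current phrase while it matches a dictionary entry and,
at the first mismatch, stores the extended phrase and restarts; a trailing
phrase that ends the sequence while still matching a dictionary entry
counts as one more phrase. For an epoch of length $T$ samples with phrase
count $L$, the normalized complexity is

$$C = \frac{L \log_2 L}{T},$$

with the convention $C = 0$ for $L \le 1$. This normalization makes $C$
roughly length-independent: a constant sequence at $T = 5120$ gives
$L = 101$ and $C \approx 0.13$, a strict two-sample alternation gives
$C \approx 0.20$, and i.i.d. binary noise approaches the finite-length
ceiling near $C \approx 1.2$ (asymptotically 1). Intracranial signals
during wakefulness typically land in the 0.5–0.7 range under this scaling,
which is where the package's synthetic wake epochs sit as well.

Three operations precede the parse:

1. **Band-pass, 0.5–200 Hz.** Each channel is filtered with a 4th-order
   Butterworth high-pass at 0.5 Hz and a 4th-order low-pass at 200 Hz,
   each applied forward–backward (zero phase), so threshold-crossing times
   are not shifted. The channel mean (0 Hz, below any admissible lower
   edge) is removed exactly before filtering; otherwise the high-pass edge
   transient — whose time constant at 0.5 Hz is of the order of seconds —
   dominates short windows.
2. **Segmentation.** Consecutive non-overlapping half-open windows of 5120
   samples (5 s at 1024 Hz), 0-indexed; a trailing remainder is dropped,
   never zero-padded, because padding repeats a symbol and biases $C$
   downward.
3. **Binarization.** A least-squares linear trend is removed per epoch and
   the residual is thresholded at zero (strictly positive residuals map
   to 1). Detrending makes the bits invariant to amplifier gain and slow
   drift; a mean-only variant is available via the `detrend` argument.

## Numerical choices

* **Filter realization.** A single band-pass transfer-function design with
  a relative lower edge of $0.5/512 \approx 10^{-3}$ is numerically
  fragile; the high-pass/low-pass cascade is stable at double precision.
  Applied twice, the cascade attenuates a 300 Hz tone by well over 20 dB
  while passing 100 Hz within 5%.
* **Idempotence.** Re-applying the band-pass changes the RMS of a signal
  whose content lies inside the band by well under 1%. Signals with
  substantial energy in the transition bands (e.g. white noise extending
  past 200 Hz) keep losing a few percent per application — that is the
  filter doing its job, not an instability.
* **Ties at zero.** Residuals within $\sqrt{\varepsilon}\,\max|x|$ of zero
  count as ties and map to bit 0. On real data an exact zero residual is a
  measure-zero event, but the rule makes degenerate inputs deterministic:
  a constant epoch or a pure ramp binarizes to all zeros rather than to
  machine-noise coin flips.
* **Overflow.** Bayes factors are computed on the log scale; a value that
  would overflow `exp()` is clamped to the largest representable double,
  and `log_bf` stays exact.

## Artifact screening

Visual artifact rejection is replaced by a deterministic rule: an epoch is
dropped when its peak absolute amplitude exceeds `z_max` (default 6) times
the median-absolute-deviation scale of its channel's full-session signal.
For a stationary Gaussian-like channel of 300 s the expected peak is
around 4.5 robust SDs, so clean epochs survive while movement-like
transients (tens of scale units) are removed. The rule is order-invariant
and logs every decision.

## The synthetic generator

No public recordings exist for the target design, so the package ships a
seeded generator with two modes.

**Signal mode** emulates the qualitative spectral composition of feline
electrocorticography: a slow 0.7–2 Hz oscillation, 7–14 Hz spindle bursts
gated by an on/off envelope with exponentially distributed burst (mean
1 s) and inter-burst (mean 3 s) durations, 30–45 Hz narrowband gamma, and
$1/f$ broadband noise, each normalized to unit SD and weighted per state.
The default weights make slow-wave sleep slow-dominated, light sleep
intermediate with spindles, and wakefulness and REM broadband/gamma
dominated and mutually near-identical. Under the default calibration the
full chain yields per-epoch wake complexity of about 0.68 (all wake-like
epochs inside 0.4–0.8), SWS near 0.26–0.28, and a wake-minus-SWS Cohen's
d in the twenties — deliberately large, since the generator's purpose is
to verify machinery, not to titrate borderline power. A per-cat
multiplicative log-normal jitter (SD 0.1) on the mixture weights supplies
between-animal variability.

**Direct-value mode** skips signal synthesis and draws per-epoch
complexity from the hierarchical model the statistics assume:
$C_{ijk} = \beta_0 + \beta_1 \tilde d + \beta_2 \tilde d^2
+ \gamma\,\mathrm{stim} + u_i + u_{ij} + \varepsilon_{ijk}$, with dose
centred at 7.5 mg/kg (decorrelating the linear and quadratic terms over
doses 0/5/10/15), $u_i \sim N(0, 0.01^2)$ per cat,
$u_{ij} \sim N(0, 0.005^2)$ per session nested in cat, and
$\varepsilon \sim N(0, 0.02^2)$. Defaults: $\beta_0 = 0.62$,
curvature magnitude $8\times 10^{-4}$ per (mg/kg)$^2$ (the `inverted_u`
and `u` shapes), slope $-4\times 10^{-3}$ per mg/kg (`linear`), and an
additive stimulation shift of $0.04$. Sleep has a direct-value variant
with state targets W 0.62, LS 0.48, SWS 0.33, REM 0.60. These values are
inside the empirical envelope of wake intracranial recordings and give
the designed-in effects comfortable margins at the default sample sizes
(3 cats × 60 epochs per state for sleep; 5 cats × 4 doses × 4 sessions ×
60 epochs for the dose design).

What signal mode does **not** emulate: biophysical neural mass dynamics,
volume conduction and montage effects, EMG/ECG contamination,
state-transition dynamics within a recording, or quantitatively matched
power spectra — the spectral targets are qualitative by design. Passing
tests therefore demonstrate that the pipeline recovers the statistical
structure it assumes, not that it would behave identically on animal
recordings.

## The statistical layer

* **Pairwise state contrasts** use one-way ANOVA with Tukey HSD
  (Tukey–Kramer under imbalance) and pooled-SD Cohen's d.
* **Shape selection** fits polynomial mixed models of degree 1–3 on the
  centred dose (or on the state code 0–3 over the progression W, LS, SWS,
  REM — a coding choice exposed via the configuration) and compares them
  through the BIC approximation to the Bayes factor,
  $\mathrm{BF}_{ab} = \exp\!\big((\mathrm{BIC}_b - \mathrm{BIC}_a)/2\big)$,
  i.e. a unit-information prior. This is an approximation, chosen because
  it reproduces the workflow of reporting BIC and BF side by side;
  fully Bayesian (sampled-posterior) factors are out of scope. Evidence
  is called *substantial* when the winning BF exceeds 5.
* **ML vs REML.** Models entering a BIC/BF comparison are fitted by
  maximum likelihood, since REML likelihoods are not comparable across
  fixed-effect structures; REML remains available for reporting variance
  components.
* **Random-effect structure** mirrors the designs: cat-only intercepts
  for the sleep analysis (one session per cell), cat plus session-nested-
  in-cat for the dose analysis. Singular fits (variance component at the
  boundary, inevitable when a true component is zero) are retained with a
  warning rather than discarded.
* **$\eta^2$** is defined as the term's sum of squares over the total sum
  of squares of the centred response, taken from the ML fit's sequential
  fixed-effects decomposition.
* **Reliability labelling.** In the stimulation report a term is labelled
  reliable only when both $p < 0.01$ and $\mathrm{BF} > 5$; p-values and
  Bayes factors can disagree, and the conjunction is the conservative
  reading of reporting both.

Calibration of the selection rule is checked by simulation at the default
design size: on flat-truth data the quadratic term is "substantial" in at
most 10% of 100 seeded replicates (the BIC penalty makes the realized
rate far smaller), while on inverted-U truth it is substantial in at
least 90% (realized: essentially always).

## Problem sizes

The shipped tests and acceptance script use the default design sizes
throughout: 60 epochs of 5120 samples per condition, 3 cats for the sleep
design (720 pooled epochs per cortex), 5 cats × 4 doses × 4 sessions × 60
epochs (4800 values) for the dose design, and 100 seeded replicates per
calibration rate. Exhaustive oracle verification of the LZ78 parser
covers all 32,766 binary strings up to length 14 plus 1000 random strings
of length 5120.

## Known limitations

* The BIC Bayes factor inherits the unit-information prior; with very
  large epoch counts it favours sparser models more aggressively than a
  subjective prior might.
* Epochs within a session are treated as exchangeable; temporal
  autocorrelation between neighbouring epochs is not modelled, which on
  real data would make the effective sample size smaller than the epoch
  count.
* No multiple-testing correction is applied across cortices; each cortex
  is reported on its own evidence.
* The delimited-text signal format is the supported input; each
  recording's sampling rate comes from the file's JSON sidecar.
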