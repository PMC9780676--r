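---
title: "Motor-cortex laterality from home-based fNIRS: models and methods"
author: "fnirsLat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-cortex laterality from home-based fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsLat)
```

## The problem

The laterality of primary motor cortex (M1) activity during paretic
upper-extremity movement is a candidate biomarker of post-stroke motor
recovery: survivors with more severe deficits tend to show a more
bilateral, less contralateralized hemodynamic response. A wearable
two-wavelength fNIRS headband makes it possible to measure this at home,
but the raw optical signals are dominated by systemic physiology (cardiac
pulsation, respiration, Mayer waves), motion artifacts and sensor noise,
and the clinical question — does laterality track impairment and
function? — involves small cohorts, ordinal clinical scales and noisy
trial-level measures. `fnirsLat` implements the full analysis chain:

1. a **synthetic-data generator** producing raw two-wavelength recordings
   and ordinal clinical-item responses with known ground truth;
2. a **denoising chain** from raw intensities to clean oxyhemoglobin;
3. the per-trial **M1-LAT statistic** (contralesional minus ipsilesional
   task-window slope at homotopic locations);
4. a Bayesian hierarchical **latent-trait SEM** linking laterality to
   impairment (FM-12) and self-reported function (SIS-Hand).

## Measurement geometry

`m1Montage()` encodes the headband: five detectors across the top of the
head, nine long-path LEDs at 30 mm (745/850 nm) and five short-path LEDs
at 8 mm (735/850 nm). The three medial detectors each see four long-path
sources and the two lateral end detectors two each, giving exactly 16
long-path measurement locations arranged as 8 homotopic pairs with a
shared medial-to-lateral index. Short channels are scalp/systemic noise
references; every long channel maps to the short channel of its detector.

```{r montage}
m <- m1Montage()
table(m$pathType)
homotopicPairs(m)
```

## The synthetic cohort generator

The generator's defaults are the study conditions the analysis targets:
11 participants, 10 trials of a 10 s fist-squeeze task followed by 40 s
rest, 5.4 Hz sampling, with a 30 s lead-in rest so filters and baselines
have context (the lead-in is our addition; some pre-task baseline is
required for any filtering to settle).

Ground truth is drawn hierarchically, mirroring the structure the SEM
assumes on its laterality arm:

* latent trait $u_i \sim t_{\nu}(0, 1)$ (unit scale, $\nu = 15$ by
  default);
* latent laterality sub-trait
  $\eta_i = \rho\,u_i + \sqrt{1-\rho^2}\,z_i$ with
  $\rho = \texttt{true\_rho\_m1lat}$ (default 0.44, a plausible
  moderate positive coupling);
* per-location scores
  $\ell_{il} = \lambda_l \eta_i + \sqrt{1-\lambda_l^2} z_{il}$ with
  loadings $\lambda_l$ increasing from 0.3 (medial) to 0.9 (lateral),
  emulating the hand-area topology in which lateral locations carry the
  most information;
* per-trial laterality values
  $m_{ilt} = g\,(\ell_{il} + e^{v_{il}/2}\,t_{(8)})$, with
  $g = \texttt{laterality\_link} = 0.03\ \mu M/s$ and log-variances
  $v_{il}$ spread around $2\log(\texttt{trial\_noise\_sd})$ — heavy-tailed
  trial noise of roughly the latent scale, a deliberately unfavourable
  signal-to-noise ratio for a single trial.

Each recording is then synthesized *forward through the optics*:
oxyhemoglobin is built from a boxcar convolved with a canonical
double-gamma response (peak 6 s; the shape is unspecified by convention
in this kind of experiment, and any monotone-rise response behaves
identically over a 10 s window), hemispheric gains are split so each
pair's slope difference equals that trial's $m_{ilt}$; deoxyhemoglobin is
the classic anti-correlated dip at $-1/3$ amplitude. Sinusoidal
cardiac/respiration/Mayer components are shared across channels up to
per-channel delays (uniform within ±0.2 s, ±0.5 s, ±1.0 s — their
magnitudes are a modelling choice, bounded by plausible physiological
phase lags). Attenuation is exponentiated onto a baseline intensity, so
the Beer–Lambert stage is tested as a genuine inversion rather than an
identity. Ordinal items are generated per item by thresholding a
propensity $\mathcal N(\rho\,u_i,\, 1-\rho^2)$ against per-item
cutpoints (FM-12: 12 items scored 0–2; SIS-Hand: 5 items scored 1–5).

**What the generator does not emulate.** Optode-scalp coupling, hair and
skin chromophores; non-sinusoidal or amplitude-modulated physiology;
realistic motion statistics (artifacts are exponential spikes and steps at
a Poisson rate). Two consequences matter for interpreting green tests.
First, the synthetic systemic noise is *chromophore-proportional* (deoxy
= 0.3 × oxy everywhere), which correlation-based signal improvement can
cancel single-handedly; the physiological-suppression check therefore
holds CBSI fixed in both arms to isolate the short-channel stages.
Second, the per-item propensity variance is $1-\rho^2$ (the stated
generator contract), slightly less than the $2-\rho^2$ the ordinal
likelihood's extra unit-variance propensity implies, so the item-side
influence parameters are estimated against a mildly mis-specified
generator; the laterality arm, whose influence parameter carries the
scientific claim, matches the fitted likelihood exactly.

## The denoising chain

Stages in order, each preserving sample count and sampling rate:

1. **Temporal derivative distribution repair** on every intensity
   channel: the signal is split at 0.5 Hz; the low-frequency derivative is
   iteratively re-weighted (Tukey biweight, robust scale $1.4826\times$
   MAD) until convergence, shrinking motion spikes and steps, and
   re-integrated. Our implementation matches the published reference
   implementation to $10^{-9}$ on a frozen fixture. TDDR assumes
   noise-dominated derivatives; on *strictly noise-free* synthetic data
   its robust scale collapses and the task response itself becomes the
   outlier, so the noise-free round-trip check runs with this stage
   toggled off (degenerate exactly-constant derivatives are returned
   unchanged).
2. **Inter-channel delays** per band (cardiac 0.5–1.5 Hz, respiration
   0.15–0.3 Hz, Mayer 0.05–0.15 Hz) from 850 nm data: cross-correlation
   against the across-short-channel mean (a symmetric, single-bad-channel
   robust reference), search window one period of the band centre capped
   at ±2 s, parabolic sub-sample refinement.
3. **Modified Beer–Lambert** conversion with per-wavelength molar
   extinction coefficients and configurable differential pathlength
   factors (default 6.0 both wavelengths). Absolute concentration scale is
   immaterial: laterality is a within-recording difference.
4. **Latent common signal** of the short channels, in four permutations
   (unfiltered + three band-filtered, delay-removed versions, separately
   per chromophore): the leading eigencomponent of the short-channel
   correlation matrix, i.e. the minimal deterministic one-factor summary
   of "latent common influences", unit variance, sign fixed by the mean
   loading. All four are regressed out of every channel *jointly* (one
   least-squares fit per target; joint fits are order-invariant).
5. **Local short-channel regression** per long channel, again four
   permutations jointly. By default regression targets are left
   unshifted (delays are removed only from the latent-estimation inputs
   and band-filtered regressors); `alignTargets = TRUE` instead moves
   every band regressor into the target channel's own time frame.
6. **Hemodynamic band-pass** 0.01–0.1 Hz: zero-phase (forward–backward)
   Butterworth, two second-order sections, odd-reflection edge padding —
   zero-phase filtering protects slope estimates from group delay.
7. **CBSI**: $x_0 = (x - \alpha y)/2$, $\alpha = sd(x)/sd(y)$; the
   corrected oxy/deoxy pair has correlation exactly $-1$.
8. **Per-trial baseline correction** to the value at the task-onset
   sample.

## M1-LAT

For each trial, an ordinary least-squares slope is fitted to clean
oxyhemoglobin over the half-open window $[onset, onset+10\,s)$ (time
origin at onset, so the intercept is the baseline term; half-open windows
keep the sample count identical across onsets). The per-trial laterality
of pair $l$ is

$$\mathrm{M1\text{-}LAT}_{lt} = \beta^{contra}_{lt} - \beta^{ipsi}_{lt},$$

with the ipsilesional hemisphere fixed by the participant's lesion side.
The raw difference convention is kept literal; interpretive sign flips
(e.g. "positive = more atypical") belong to reporting, not to the
statistic. Swapping the lesion side negates every value, and a typically
lateralized response (ipsilesional dominant during paretic-hand movement)
yields negative values under this convention.

## The latent-trait SEM

For participants $i$, locations $l$, trials $t$, items $j$:

$$
\begin{aligned}
u_i &\sim t_{\nu_u}(0, 1), & \nu_u/30 &\sim \mathrm{Beta}(2,2)\\
\eta^{(s)}_i &\sim \mathcal N\!\big(\rho_s u_i,\; 1-\rho_s^2\big),
  & s &\in \{\mathrm{FM}, \mathrm{SIS}, \mathrm{M1LAT}\}\\
\ell_{il} &\sim \mathcal N\!\big(\lambda_l \eta^{(M1)}_i,\; 1-\lambda_l^2\big)\\
v_{il} &\sim \mathcal N(\mu_v, \sigma_v^2) \quad \text{(log variance)}\\
y_{ilt} &\sim t_{\nu_y}\!\big(a_l + b_l \ell_{il},\; e^{v_{il}/2}\big),
  & \nu_y/30 &\sim \mathrm{Beta}(2,2)
\end{aligned}
$$

with ordinal responses connected through a cumulative normal propensity:
$P(y_{ij} = k) = \Phi(c_{jk} - \eta_i) - \Phi(c_{j,k-1} - \eta_i)$, one
cutpoint set per item shared across participants. Residual variances are
tied to the influences as $1-\rho^2$ (and $1-\lambda^2$), so each
sub-trait and location score has unit marginal variance and $\rho_s$,
$\lambda_l$ read directly as correlation coefficients. $\rho_{FM}$ and
$\rho_{SIS}$ are constrained to $(0,1)$ — they *define* the orientation of
the latent trait — while $\rho_{M1LAT}$ ranges over $(-1,1)$, imposing no
prior belief about the sign or size of the laterality relationship.
Location loadings are constrained to $(0,1)$.

**Priors.** Influence parameters: flat, i.e. uniform on their constrained
interval (the proper reading of "flat" on a bounded support). Cutpoints:
induced Dirichlet — a unit Dirichlet on the category probabilities induced
under a standard-normal propensity anchored at 0 (the zero-mean propensity
scale), Jacobian included; `inducedDirichletLogPrior()` exposes the
density, and inside the sampler the exactly equivalent simplex
parameterization is used (Dirichlet(1,…,1) on probabilities, cutpoints =
$\Phi^{-1}$ of their cumulative sums). Both degrees-of-freedom
parameters: $DF/30 \sim \mathrm{Beta}(2,2)$, a parabola on $(0,30)$
peaked at 15. Location shifts and the noise mean: $\mathcal N(0,1)$;
every SD-like parameter: Weibull(shape 2, scale 1), zero-avoiding with
unit scale. These weakly-informed priors presume pre-scaled data, which
is why the laterality matrix is robustly centred/scaled per pair (median,
$1.4826\times$MAD) before fitting — per pair rather than globally so the
shift/scale parameters start near $(0,1)$; a `prescale = FALSE` switch
keeps the alternative.

**Degrees-of-freedom count.** The latent trait uses one shared DF scalar
and the trial likelihood a second one — two scalars total, the more
specific of the two plausible readings of the design; a
`perParticipantDF = TRUE` switch preserves the per-participant
alternative.

**Sampler.** The model is expressed in the BUGS language and sampled with
JAGS (`rjags`), the Bayesian MCMC engine this package builds on; each
chain gets an explicitly seeded Mersenne–Twister stream, so fits are
exactly reproducible. JAGS's conjugate/slice samplers have no concept of
a divergent transition, so the diagnostics report records
`nDivergent = 0` as a sampler-metadata pass-through and the convergence
gate rests on rank-normalized split-Rhat (< 1.01 for every parameter,
bulk and folded) and tail effective sample size (floor 100 per parameter
by default; the floor is configurable because no canonical threshold
exists). Constrained parameters are sampled directly on their intervals
under their uniform priors — with a Gibbs-family sampler there is no need
for the logit/tanh reparameterizations a gradient-based sampler would
use, and the implied distributions are identical. Sampler defaults are 4
chains, 500 adaptation + 500 burn-in, 1000 retained draws per chain, all
configurable; correctness is gated by the diagnostics, not by the
defaults.

## Numerical choices and degenerate inputs

* Flat channels are excluded from factor estimation and delay estimation
  (delay 0, flagged) and dropped as regressors; if fewer than two short
  channels are usable the latent-common stage degrades to a no-op.
* Collinear regressors are dropped by the rank-revealing least-squares
  solve, with a warning.
* Interpolation shifts pad edges with endpoint values, avoiding steps
  that the artifact-repair stage would misread.
* A residual-variance guard of $10^{-10}$ keeps precisions finite if an
  influence parameter is sampled at the very edge of its interval.
* `cbsi()` refuses zero-variance inputs ($\alpha$ undefined);
  `prescaleLaterality()` refuses zero-MAD pairs by name.

## What the tests establish (and at what scale)

The test suite exercises every stage against independent oracles
(reference artifact-repair output frozen from an independent
implementation; brute-force lag scans; forward-model inversion;
normal-equations residuals; closed-form ordinal probabilities;
prior-only sampling against scaled-Beta quantiles). Parameter recovery
runs at 30 participants × 20 trials with generative laterality
correlations $\{-0.6, 0, 0.6\}$, two fixed-seed replicates each, sampled
with 2 chains × 500 retained draws: the 95% credible interval must cover
the truth in at least 5 of 6 replicates and exclude zero in at most 1 of
the 2 null replicates. These sizes are the package's chosen desk-scale
conditions — large enough that the posterior is informative, small enough
that the whole suite runs in minutes — and the same machinery scales to
larger designs unchanged. The spatial check asks the posterior loading
medians to reproduce the generator's medial < lateral ordering.

Because the generator, not real data, defines these conditions, green
tests demonstrate correctness of the implementation under the stated
generative assumptions — not robustness to everything real home
recordings can contain (coupling loss, non-stationary physiology,
task-correlated motion).

## Known limitations

* The latent common signal is the leading eigencomponent — a deterministic
  one-factor summary, not a fitted measurement-error SEM; with five short
  channels and four permutations this is the honest minimal version of
  "latent common influences".
* With 11 participants (the default cohort), the posterior on
  $\rho_{M1LAT}$ is wide; that is the method working as intended, not a
  failure of the sampler.
* Small-sample ordinal scales leave cutpoint posteriors diffuse; the
  induced Dirichlet prior keeps them proper without informative content.
* The JAGS backend mixes more slowly than a gradient-based sampler on the
  correlated $(\rho, \eta)$ geometry; the diagnostics gate is the
  arbiter, and longer chains are a configuration change.
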