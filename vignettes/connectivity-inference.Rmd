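---
title: "Estimating monosynaptic connectivity from parallel spike trains"
author: "connectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating monosynaptic connectivity from parallel spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A monosynaptic connection between two simultaneously recorded neurons leaves
a stereotyped trace in their cross-correlogram (CCG): a short-latency,
millisecond-scale peak (excitatory) or trough (inhibitory) on the causal
side of lag zero. In principle one can reconstruct a local circuit diagram
by scanning every pair of units for this signature. In practice the CCG of
cortical data is dominated by slow comodulation — shared inputs, state
fluctuations, oscillations — which produces large undulations that both hide
true synaptic features and mimic spurious ones.

`connectr` implements two complementary detectors operating on the same
100-bin CCG (lags −50 to +50 ms, 1 ms bins):

* **a small 1-D convolutional network** that maps the raw integer counts to
  a connection probability $z \in [0,1]$ and a postsynaptic-potential (PSP)
  amplitude in mV, trained end-to-end on simulated circuits with known
  wiring; and
* **a generalized linear model (GLMCC)** that explicitly fits the CCG as a
  smooth baseline plus exponential coupling kernels, with a likelihood-ratio
  test per direction.

The package also contains the third leg the first two stand on: a
conductance-based network simulator of multi-timescale adaptive threshold
(MAT) neurons that supplies spike trains with fully known ground truth, used
for training, calibration and validation.

## The simulator

### Membrane and threshold dynamics

Each neuron is a MAT unit: a leaky membrane whose potential $v_m$ relaxes as

$$\tau_m \frac{dv_m}{dt} = -(v_m - V_L)
  - \tau_m\left[g_e (v_m - V_E) + g_i (v_m - V_I)\right] - R I_{\mathrm{bg}},$$

with synaptic conductances $g_e, g_i$ decaying exponentially
($\tau_{s,e} = 1$ ms, $\tau_{s,i} = 2$ ms) and jumping by the synaptic
weight $G$ one transmission delay after each presynaptic spike. A spike is
emitted when $v_m$ crosses an adaptive threshold

$$\theta(t) = \omega + \sum_{\text{spikes } j} \left[
  \alpha_1 e^{-(t - t_j)/\tau_1} + \alpha_2 e^{-(t - t_j)/\tau_2}\right],
  \qquad \tau_1 = 10\ \text{ms},\ \tau_2 = 200\ \text{ms},$$

and the membrane potential is *not* reset — adaptation lives entirely in the
threshold, as is the MAT convention. An absolute refractory period of 2 ms
is imposed (configurable); the underlying model family leaves this choice
open and 2 ms is the customary value.

On units: the background term $R I_{\mathrm{bg}}$ is a conductance-type
drive $g^{\mathrm{bg}}(v_m - E^{\mathrm{bg}})$ scaled by the membrane
resistance. With the standard specific capacitance $C_m = 1\ \mu F/cm^2$,
$R = \tau_m / C_m$, so the background enters the membrane equation with
exactly the same $\tau_m$ factor as the recurrent synaptic conductances.
This is the reading implemented here; it is also the only one under which
the stated background parameters put neurons in the intended
fluctuation-driven regime (excitatory cells hovering a few mV below
threshold, firing at a few Hz with Lv near 1, and inhibitory cells firing
faster than excitatory ones — all of which the test suite asserts).

### Wiring and weights

The reference configuration is 1000 neurons, 800 excitatory and 200
inhibitory. Every neuron receives exactly 100 excitatory partners drawn
without replacement from the excitatory pool and 50 inhibitory partners
from the inhibitory pool (self-connections excluded), i.e. per-pair
connection probabilities of 12.5 % and 25 %. Excitatory peak conductances
are log-normal (ln-mean −5.543, ln-SD 1.30, in mS/cm²); inhibitory ones are
normal (mean 0.0217, SD 0.00171 mS/cm²) with non-positive draws resampled.
Delays are uniform on 3–5 ms (excitatory) and 2–4 ms (inhibitory).
Excitatory neurons draw their fast threshold-jump weight $\alpha_1$ once at
construction from Gauss(1.5, 0.25) mV; inhibitory neurons use fixed
$\alpha_1 = 3$, $\alpha_2 = 0$.

Scaled-down configurations (used throughout the tests) keep the connection
probabilities by scaling in-degrees as `round(nExc/8)` and `round(nInh/4)`.

### Ground-truth PSP

The teaching signal for the regression head is a PSP amplitude in mV, which
is not a primitive of a conductance-based model. The package defines it
operationally via `pspAmplitude()`: the signed peak deflection of a passive
postsynaptic membrane from $V_L$ when the single synapse fires once, with
no background and no other inputs. This definition is reproducible,
strictly monotone in $G$, and reduces to the familiar
difference-of-exponentials peak in the small-$G$ limit (verified against
the closed form to 1 %).

### Background noise and oscillations

Background excitatory and inhibitory conductances follow independent
Ornstein–Uhlenbeck processes (means 0.123 / 0.322 mS/cm², SDs 0.0163 /
0.0265, time constants 2.7 / 10.5 ms). Three disjoint groups, each one
tenth of the population (80 % E, 20 % I members), additionally receive a
slow modulation of the *excitatory* background at 7, 10 and 20 Hz: the term
$A \sin(\omega t + \delta)\,\xi(t)$ multiplies white noise, with per-neuron
phase uniform on $[0, 2\pi)$ and amplitude uniform on
$[\tilde A/2, 3\tilde A/2]$, $\tilde A = 0.015$. Because the sinusoid
multiplies noise rather than adding to the mean, it modulates the noise
*variance*: the conductance spectrum itself stays flat while the squared
centred conductance acquires a sharp spectral line at $2f$ (the variance
envelope has period $1/2f$). The property test asserts exactly this
signature against a direct R-level integration of the same equation.
Whether inhibitory group members should receive the term too is ambiguous
(the groups contain inhibitory neurons but the modulation is introduced for
the excitatory background); the package applies it to the excitatory
background conductance of every group member.

### Numerical scheme

* forward Euler for the membrane at `dt = 0.1` ms;
* synaptic conductances decay by the exact exponential factor per step;
* delayed deliveries are queued at spike time + delay, rounded to the
  nearest step;
* background OU conductances are advanced with the exact discretization
  $g' = \mu + (g-\mu)e^{-\Delta/\tau} + \sigma\sqrt{1-e^{-2\Delta/\tau}}\,n$
  every 5th membrane step (0.5 ms) and held in between. The exact update is
  distribution-correct at any step; holding for 0.5 ms, far below
  $\tau^{\mathrm{bg}}_e = 2.7$ ms, leaves the transferred spectrum
  essentially untouched while cutting the per-step cost of Gaussian
  generation five-fold. `bgUpdateEvery = 1` restores per-step updates.
* OU conductances may transiently go negative, as is usual for
  point-conductance background models; values enter the membrane equation
  as-is.
* The simulator aborts with a diagnostic if any membrane potential leaves
  ±500 mV.

Determinism: network construction uses the session RNG (seed it with
`set.seed()`); the compiled simulation loop uses its own xoshiro256++
stream seeded from the configuration, so identical network + config + seed
reproduce spike trains bit-for-bit.

## Correlograms

`computeCorrelogram()` counts spike pairs by lag $t_{\mathrm{tgt}} -
t_{\mathrm{ref}}$ in half-open 1 ms bins over ±50 ms; the lower edge is
inclusive, so an exact coincidence falls in the first positive bin and the
100 bins split 50/50. A causal effect of the reference on the target
appears at positive lags.

Spike sorting misses near-synchronous spikes on the same electrode array
(the shadowing effect), carving an artifactual notch around lag zero that
overlaps exactly where monosynaptic evidence lives. `shadowTrim()` removes
the four bins covering −2 to +2 ms and concatenates the flanks (96 bins);
the end-to-end pipeline works in trimmed space throughout so that simulated
training data and preprocessed experimental data share one geometry.

`rescaleAugment()` implements training-set augmentation by time dilation:
spike times multiplied by 2 and 4, halving and quartering all rates while
leaving labels untouched. The two ways of phrasing this augmentation
(rescaling correlations "by 2 and 4" vs rates "1/2 and 1/4") are
reconciled as time dilation, which is the operation that produces both.
The default factor set is {1, 2, 4}.

## The CNN estimator

Architecture (96-bin trimmed input by default; a 100-bin untrimmed variant
is available through `cnnModelSpec(inputLength = 100)`):

| stage | shape |
|---|---|
| 1-D convolution, kernel 10, 5 channels, stride 1, no padding, tanh | 96 → 87 × 5 |
| average pooling, window 2, stride 1 | 87 → 86 × 5 |
| fully connected, 100 nodes, ReLU | 430 → 100 |
| output: logistic $z$, linear PSP (mV) | 100 → 2 |

Pooling geometry is not pinned down by the architecture's published
outline; window 2 / stride 1 was chosen because it makes the total
parameter count about 45k, i.e. "about fifty thousand", and it is
configurable. Raw integer counts are fed directly (no input normalization).

Each unordered pair contributes one correlogram presented in both
orientations — original and lag-reversed — because the network reads the
candidate causal direction from the positive-lag half; labels are $z = 1$
and the signed true PSP when the oriented connection exists, else
$z = 0$ and 0 mV. At the default wiring about 15 % of oriented examples
are connected; no class re-weighting is applied.

Training: Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$), 20 epochs, no dropout, minibatch 256 (batch size is an
implementation choice), composite loss
$0.5\,\mathrm{BCE}(z) + 0.5\,(\widehat{\mathrm{PSP}} -
\mathrm{PSP})^2$. Because the inputs are raw counts of order $10^1$–$10^2$,
the convolution kernel is initialized at a small fixed scale (uniform
±0.01) so the tanh starts in its active region; the dense layers use
Glorot initialization on the bounded tanh features. The network,
backpropagation and Adam are implemented
directly in base R matrix algebra; at these sizes (≈45k parameters,
$10^4$–$10^5$ examples) BLAS-backed batches train in tens of seconds, and
the implementation is deterministic under fixed seeds, which a testthat
suite can then hold to bit-for-bit reproducibility.

Detection thresholds $z > \theta$ with $\theta = 0.5$; a sweep of
$\theta$ against macro-MCC on held-out simulated data shows a broad
plateau around 0.5 (asserted as a property, peak within [0.3, 0.7]).
Estimated PSP is reported as 0 for undetected pairs.

## GLMCC

The CCG of a pair is modelled as an inhomogeneous Poisson intensity

$$\lambda_{cc}(t) = \exp\!\left[a(t) + J_{12} f(t) + J_{21} f(-t)\right],
\qquad f(t) = e^{-(t-d)/\tau}\ \mathrm{for}\ t > d,\ 0\ \text{otherwise},$$

with $\tau = 4$ ms, delay $d$ selected per direction from {1, 2, 3, 4} ms,
and $a(t)$ a 100-bin baseline absorbing slow comodulation under the
smoothness prior $-\sum_k (a_{k+1}-a_k)^2 / (\gamma\Delta)$,
$\gamma = 2\times10^{-4}$ ms⁻¹. The likelihood is evaluated on the 1 ms
binned counts (identical information at this resolution;
$\sum_k c_k \eta_k - \Delta e^{\eta_k}$ discretizes the Poisson integral
per bin). $a$ is in log expected counts per bin; divide by bin width and
reference spike count for an intensity per reference spike.

Fitting is a damped Newton ascent on the 102-dimensional posterior with
analytic gradient and Hessian. The posterior is strictly concave (linear
predictor, concave likelihood, quadratic prior), so Newton converges in a
handful of iterations from the flat initialization
$a \equiv \log \bar c$, $J = 0$; convergence is declared at gradient
max-norm $10^{-6}$ (1000-iteration cap), and the same optimum is reached
from random initializations (asserted). Delays are selected independently
per direction by the maximal penalized posterior of single-coupling fits,
followed by a joint fit at the selected delays.

Significance per direction uses the likelihood ratio
$D = \log L^*(J = \hat J) - \log L^*(J = 0)$, with all other parameters
re-optimized under each constraint (including the opposite coupling) and
$L^*$ the likelihood term at the MAP solutions. The null is rejected when
$2D$ exceeds the upper-$\alpha$ quantile of $\chi^2_1$, $\alpha = 10^{-4}$
(≈15.14). Because the constrained and unconstrained optima maximize the
*posterior*, the likelihood difference can be a hair negative numerically;
it is clamped at 0.

Two calibration notes. First, Wilks' theorem applies to a fixed model: when
the delay is additionally optimized over four candidates, $2D$ is the
maximum of four strongly correlated statistics and the test is mildly
anticonservative — one reason the operational $\alpha$ is as small as
$10^{-4}$. The χ²₁ calibration harness therefore runs with a single delay
candidate; the default hyper keeps the 4-delay grid. Second, on trimmed
correlograms the four shadow bins are *masked out* of the likelihood
rather than concatenated, so $f(t)$ keeps its true lag alignment.

No conversion from $\hat J$ to mV is attempted; the coupling is reported in
its own log-intensity units.

## Evaluation

`confusion()` scores a directed estimate table one-vs-rest per category.
True excitatory connections weaker than 0.1 mV are excluded from the
excitatory tally — they are invisible at realistic durations — and
detections of them are not punished as false positives either (the
connection does exist). MCC is guarded to 0 whenever a marginal is zero.
The macro average $(\mathrm{MCC_E} + \mathrm{MCC_I})/2$ weights both
categories equally. The published definition of FPR/FNR does not pin down
denominators; the package defaults to the discovery/omission reading
($\mathrm{FP}/(\mathrm{FP+TP})$, $\mathrm{FN}/(\mathrm{FN+TP})$) and
exposes the classic alternative via `rates = "classic"`.

`durationCurve()` truncates a recording (default 10/30/120 min) and
re-estimates: excitatory misses shrink with duration while false positives
stay roughly flat. `eiDominance()` classifies units as putative excitatory
or inhibitory by the sign of $(n_e - n_i)/(n_e + n_i)$ over detected
outgoing connections, undetermined at zero or no detections.
`splitRecording()` supports the split-half stability analysis (sign
agreement of jointly detected connections across halves).

## Validation scales

The test suite exercises the full pipeline at a deliberately reduced scale:
training network of 100 neurons (80 E / 20 I, in-degrees 10 / 5) simulated
for 30 minutes, an independent validation network simulated for 60 minutes,
CNN trained on all 4950 pairs with {1, 2, 4} augmentation (29,700 oriented
examples), evaluation across 10/30/60-minute truncations. These sizes keep
the complete suite in the ten-minute range on one core while preserving the
connection-probability structure, the weight distributions and the
fluctuation regime of the reference configuration; the full 1000-neuron,
120-minute, 80,000-pair replication is the same code with larger numbers.
The distributional checks (weight samplers at $n = 10^6$, χ²₁ calibration
over 500 null pairs, wiring of the full 1000-neuron graph) run at full
fidelity.

## What the synthetic data does and does not show

The generator reproduces the features that make CCG-based inference hard —
log-normal weight tails, fluctuation-driven irregular firing, slow
oscillatory comodulation at several frequencies, shadow-trimmed
correlograms — so passing tests demonstrate that the estimators recover
known ground truth under realistic nuisance structure. It does not emulate
electrode drift, sorting contamination between units, bursting cell types,
conduction-delay jitter, or non-Poisson higher-order correlations beyond
what the recurrent dynamics produce; performance numbers on simulated data
are therefore upper bounds, and real-data use should lean on the agreement
between the CNN and GLMCC rather than on either alone.

## Known limitations

* The CNN is trained per run rather than shipped as fixed weights; two
  training runs with different seeds give slightly different estimators
  (the tests pin seeds).
* GLMCC fits one pair at a time and does not model common input explicitly;
  a shared-rate confound that mimics an exponential kernel at 1–4 ms can
  still fool it.
* The PSP scale is defined by the single-synapse passive deflection; it is
  consistent across the package but not identical to an experimental PSP
  measured at arbitrary holding potential.
* Inhibitory PSPs at the reference weight distribution are narrow
  (≈0.2–0.4 mV), so PSP-amplitude recovery is dominated by excitatory
  connections; inhibitory performance is mainly a detection problem.
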