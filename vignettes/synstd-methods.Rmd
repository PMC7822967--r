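---
title: "Modeling and estimating short-term depression at GABAergic synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and estimating short-term depression at GABAergic synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstd)
```

## Scope

`synstd` analyzes trains of evoked inhibitory postsynaptic currents
(IPSCs) at depressing GABAergic synapses. It combines four layers that
are usually scattered across lab scripts: a mechanistic
depletion/recovery model of short-term depression (STD), variance–mean
quantal analysis, descriptive train metrics, and Bayesian estimation of
the model's kinetic constants. A stochastic generator produces
synthetic datasets with the exact structure of the underlying
experimental design, which is how the package validates itself and how
users can power-check their own designs.

## The depression model

The model is a two-state, event-driven dynamical system. Its state is
the normalized presynaptic calcium elevation $C$ (rest $C = 0$) and the
available fraction of releasable sites $R \in [0, 1]$.

Between stimuli:

$$\frac{dC}{dt} = -\frac{C}{\tau_{Ca}}, \qquad
  \frac{dR}{dt} = k(C)\,(1 - R), \qquad
  k(C) = k_{min} + \Delta k \frac{C}{C + K_r}.$$

At each stimulus, in this order: the calcium jumps, $C \leftarrow C +
\Delta$ (with $\Delta = 1$, calcium is measured in units of the
per-stimulus increment); the release probability is evaluated,

$$P(C) = P_{max}\frac{C}{C + K};$$

the *observable* release probability of pulse $n$ is recorded as
$p_n = P(C)\,R$ (this is what IPSC amplitude divided by $Nq$
estimates); and the pool depletes, $R \leftarrow R\,(1 - P(C))$.
Release is triggered by the spike-evoked calcium, so $P$ acts on the
post-jump value.

Both saturating functions are first-order (Hill coefficient 1), the
simplest forms consistent with their parameters being "half calcium
concentration values": $P(K) = P_{max}/2$ and $k(K_r) = k_{min} +
\Delta k/2$, with $k(0) = k_{min}$ the resting (calcium-independent)
recovery rate.

Because calcium decays exponentially, the recovery-rate integral over
an inter-pulse interval $T$ is analytic:

$$\int_0^T k(C(t))\,dt
  = k_{min} T + \Delta k\, \tau_{Ca}
    \ln\!\frac{C_0 + K_r}{C_0 e^{-T/\tau_{Ca}} + K_r},$$

so `propagate_interval()` is an exact closed-form map, used everywhere
in production; numerical ODE integration appears only as an independent
oracle in the test suite (agreement to $10^{-6}$ relative on random
draws).

### Parameters

| Parameter | Units | SH | HC | Meaning |
|---|---|---|---|---|
| $\tau_{Ca}$ | ms | 27.7 | 22.4 | calcium decay time constant |
| $P_{max}$ | – | 0.75 | 0.91 | maximum release probability (from VM analysis; fixed in fits) |
| $K$ | norm. Ca | 0.69 | 0.68 | half-saturation of $P(C)$ |
| $k_{min}$ | ms$^{-1}$ | 9.0e-4 | 1.2e-3 | resting recovery rate (~1 s baseline recovery) |
| $\Delta k$ | ms$^{-1}$ | 0.017 | 9.4e-3 | calcium-dependent span of the recovery rate |
| $K_r$ | norm. Ca | 1.18 | 0.19 | half-saturation of $k(C)$ |
| $\Delta$ | norm. Ca | 1 | 1 | per-stimulus calcium increment (fixed) |

All times are ms and all rates per-ms. The 6.2-fold difference in $K_r$
is the mechanistic heart of the comparison: the HC recovery rate is
nearly saturated already at single-jump calcium, whereas the SH synapse
converts further calcium accumulation at 20–50 Hz into faster
replenishment (`fold_change_table()` tabulates the ratios).

Two model behaviors are worth flagging because they are easy to
mistake for bugs. First, at stimulation rates above ~20 Hz the
post-jump calcium exceeds 1 (geometric summation,
$C_{ss} = \Delta/(1 - e^{-T/\tau_{Ca}}) \approx 1.9$ at 50 Hz); any
display normalization of $C$ is cosmetic. Second, the SH paired-pulse
recovery curve is *non-monotone* below ~100 ms: at a 20 ms interval the
residual calcium still elevates both the test-pulse release probability
and the replenishment rate, producing a slightly higher ratio than at
50–75 ms. The curve rises monotonically to 1 once residual calcium has
cleared.

## Quantal (variance–mean) analysis

For binomial release from $N$ sites with quantal amplitude $q$ and
intrasite quantal coefficient of variation $CV$, the variance of the
evoked response is a parabola in its mean $I$:

$$\sigma^2 = (1 + CV^2)\,q\,I - \frac{I^2}{N_{VM}},$$

exactly the second moment of
$\mathrm{Var} = N p q^2 (1 + CV^2 - p)$ at $I = N p q$ (asserted as an
algebraic identity in the tests). $CV$ is fixed at 0.3, the
conventional value for central GABAergic synapses.

`variance_mean_fit()` computes per-pulse means and variances across
repeats; P1 of each frequency enters as its own point; P2–P20 from all
frequencies are pooled and binned by mean amplitude with bin width
0.1 × the grand-mean P1 amplitude, averaging the (mean, variance) pairs
within bins and dropping bins with fewer than 2 points. Because the
parabola is linear in $(I, I^2)$, the fit is ordinary (unweighted)
least squares via `lm` with no intercept, and degenerate data
(non-positive $q$ or a non-negative quadratic coefficient) raise an
error rather than returning nonsense. $p_{max}$ is the largest mean
amplitude divided by $N_{VM} q$, clipped to $[0, 1]$.

Choices made where the procedure is underdetermined: binned variances
are averages of per-pulse variances (not variances of pooled
amplitudes), and each frequency's P1 enters un-binned; both choices
keep every point an unbiased estimate of a point on the parabola.

## Train metrics

* `pr_series()` — mean amplitude per pulse over $Nq$.
* `ppr()` — mean(P2)/mean(P1); the ratio of means, not the mean of
  ratios, which would be biased upward by P1 noise.
* `cv_series()` — SD/mean across repeats, per pulse.
* `ssd()` — mean amplitude over pulses 16–20 divided by the mean P1,
  then normalized to the same quantity at 5 Hz. Normalization uses the
  repeat-averaged P1 for the same reason `ppr()` uses a ratio of means.
* `rrp_from_cumulative()` — cumulative mean amplitude vs pulse index,
  OLS line through the last five points, back-extrapolated intercept at
  pulse 0 divided by $q$. Users should know this estimator's standard
  caveat, which the package's own model makes vivid: vesicles
  replenished *during* the train inflate the steady-state slope and
  deflate the intercept, so under strong calcium-dependent recovery the
  estimate can sit well below the true site count (about half of it for
  the SH parameters at 50 Hz). The tests therefore validate the
  stochastic estimate against the estimator's own deterministic value,
  not against $N$.

## IPSC waveforms and kinetics

Synthetic sweeps are superpositions of peak-normalized biexponential
kernels $e^{-t/\tau_d} - e^{-t/\tau_r}$ at the pulse times, scaled to
the per-pulse amplitudes, with linear summation of overlapping tails
and Gaussian baseline noise; the default kernel has $\tau_d = 8.5$ ms
and $\tau_r$ solved so the 10–90% rise time is 1.0 ms, with 20 kHz
sampling.

`extract_amplitudes()` detects stimulus-locked peaks in a short window
after each pulse, measuring each against a baseline estimated in the
1 ms before that pulse. The baseline is a *sloped* (linear) fit
extrapolated under the peak: at 50 Hz the preceding IPSC's tail decays
appreciably between the baseline window and the peak, and a constant
baseline under-measures summating amplitudes by several percent. With
the sloped baseline the noiseless round-trip
generate → synthesize → extract is accurate to 2% or ~3 pA.

`ipsc_kinetics()` reports the interpolated 10–90% rise time and a
single-exponential decay constant. The decay fit starts 1.5 ms after
the peak: the fast rise component still contributes several percent at
the peak itself and inflates a from-peak fit by ~0.2 ms for an 8.5 ms
kernel; 1.5 ms (about two rise constants) reduces the bias below
0.05 ms while costing little data.

## The synthetic-data generator

`generate_experiment()` reproduces the experimental design the analysis
is built for: 20-pulse trains at 5, 10, 20 and 50 Hz, each repeated 7
times, plus paired pulses from rest at 20/50/100/500/1000/3000 ms, each
repeated 7 times. Per repeat and pulse, each of `n_sites` sites
releases independently with probability $p_n$ from the model; each
released quantum is a zero-truncated Normal$(q, CV\,q)$; Gaussian
measurement noise (default SD 2 pA, small next to the quantal
variance) is added and the result rectified at zero. This is exactly
the generative model under which the variance–mean parabola is exact —
between-site heterogeneity of $q$ and site-wise vesicle tracking are
deliberately omitted, since the analysis equations assume a single $q$
and mean-field depletion.

What the generator does *not* emulate: between-train carryover (every
train starts from rest, while real trains delivered in sequence may
not), optogenetic spike failures or conduction jitter, correlated or
non-Gaussian recording noise, electrotonic filtering, and between-cell
parameter heterogeneity. Passing tests therefore certify the estimators
under ideal binomial conditions, not robustness to those artifacts.

All generation is seed-deterministic (identical seed → bit-identical
dataset) and leaves the caller's RNG state untouched.

## Parameter estimation

The fitting target is the 92-value vector of observed release
probabilities: 4 frequencies × 20 pulses plus P1 and P2 at six recovery
intervals, all weighted equally (the relative weighting of train vs
recovery points is a free choice; equal weight per point is the
default). The objective is the mean squared error between these values
and the model's $p_n$ over the same protocols.

`fit_map()` minimizes the objective by Nelder–Mead over the logs of the
five free parameters $\{\tau_{Ca}, K, k_{min}, \Delta k, K_r\}$ —
log-space enforces positivity without constraints — with $P_{max}$
(taken from the variance–mean analysis, which measures it more directly
than the train shapes do) and $\Delta = 1$ fixed. Convergence is a
relative objective change below $10^{-4}$ by default, with a 5,000
evaluation cap.

`run_mcmc()` is an adaptive random-walk Metropolis sampler in the same
log-space. The likelihood is Gaussian with unknown error variance
$\sigma^2$, Gibbs-sampled from its conjugate inverse-gamma conditional
under a weak IG($10^{-6}$, $10^{-6}$) prior — weak enough that, on
noiseless data, the posterior can actually collapse onto the generating
parameters instead of being floored by the prior. Parameter priors are
flat on the log scale within a factor of 1000 of the start. The
proposal covariance is the scaled empirical covariance of the chain
history ($2.38^2/d$ plus a small jitter), updated every 100 iterations
after an initial 1,000-iteration phase; windows with zero acceptances
halve the proposal scale, which lets the sampler self-tune when the
posterior is much narrower than the initial guess. Intended chain
lengths are 50,000–150,000 (shorter runs work but warn); summaries
discard a 20% burn-in by default — generous for chains started at the
MAP — and report means, SDs and the parameter correlation matrix.

### Identifiability

$K_r$ and $\tau_{Ca}$ are strongly correlated in the posterior (a
longer-lived calcium transient trades off against a recovery rate that
saturates at higher calcium), and `posterior_summary()` reports this
correlation explicitly. In repeated synthetic experiments at the
design's own noise level (7 repeats per train, population averages over
12–19 cells), the replicate-to-replicate scatter of the recovered
$\tau_{Ca}$ and $K$ is comparable to their posterior SDs — which is
what calibrated inference predicts, and which means single-experiment
point estimates of these two constants should be read with their
uncertainties, not as precise values. $k_{min}$ and $\Delta k$ are well
constrained; $K_r$ is typically recovered within a factor of two.

## Numerical policy and problem sizes

Fixed points of the per-pulse map iterate to a relative tolerance of
$10^{-6}$ (cap 10,000 iterations); the closed-form map needs no
tolerance. Degenerate inputs fail loudly: zero-variance amplitude data,
missing 5 Hz reference for SSD, non-positive parameters, windows past
the trace end.

The test suite sizes its simulations to what the statistics require
rather than more: moment identities use 10,000-repeat tables (averaged
over ten tables where a 2% check is applied, since one table's variance
estimate carries ~1.5% Monte-Carlo noise), consistency checks use a few
hundred to a few thousand repeats, and the full MAP + MCMC recovery
study uses ten replicate experiments at 50,000 iterations each.

## Limitations

No facilitation term, multi-pool vesicle models, GABA_B autoreceptor
modulation, multi-exponential decay fitting, spontaneous-event
analysis, or hierarchical multi-cell pooling; fits operate on whatever
single dataset vector they are given. These are scope decisions, not
oversights: the model is deliberately the smallest one that captures
calcium-dependent recovery from depression.
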