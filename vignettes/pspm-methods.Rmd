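---
title: "Pre-Synaptic Pool Modification: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-Synaptic Pool Modification: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Fitting the synaptic weights of a recurrent spiking network so that it
reproduces a target set of spike trains is a core problem both for inferring
effective connectivity from recordings and for programming neuromorphic
circuits. Gradient methods need differentiable post-synaptic kernels and
mostly feed-forward structure; evolutionary search ignores the causal
structure of spiking altogether. Pre-Synaptic Pool Modification (PSPM) sits
between the two: it pairs observed with desired spikes, and for every spike
that remains unpaired it stochastically nudges the incoming weights of the
neurons that fired shortly beforehand — no gradients, no assumptions about
the neuron model beyond "recent presynaptic spikes are the causes".

This vignette documents the models, the learning rule, the similarity
metrics and the avalanche analysis as implemented here, together with the
numerical conventions and the genuinely open design choices and how we
resolved them.

## The leaky integrate-and-fire network

Each of $N$ neurons carries a membrane potential $V_i(t)$ integrated by
forward Euler with step $dt$:

$$V_i \leftarrow V_i + \frac{dt}{\tau}\Bigl(-V_i + R_m I_i(t) +
  \sum_j W_{ij}\, s_j(t-1)\Bigr),$$

and a neuron whose potential reaches $V_{th}$ emits a spike and resets to
0 within the same step. Defaults ([`lif_params()`]): $\tau = 30$ ms,
$R_m = 100\,\mathrm{M\Omega}$, $V_{th} = 30$ mV, $dt = 3$ ms, $N = 400$,
20% inhibitory neurons. Conventions worth making explicit:

* **One-step synaptic delay.** The synaptic sum uses spikes from the
  previous Euler step. Instantaneous (within-step) coupling would make the
  update order-dependent; the one-step delay is the unique well-defined
  synchronous scheme.
* **No autapses.** $W_{ii} = 0$ always; a self-loop would let a neuron
  re-excite itself one step after reset.
* **Initial condition** $V_i(0) = 0$ (the reset value); **no refractory
  period** — a neuron may fire on consecutive steps.
* **Units.** Weights are stored in volts, currents in amperes; the
  constructors are the boundary where mV / MΩ / ms conventions live.
  Sign structure follows Dale's principle per presynaptic neuron, and no
  update may flip a weight's sign — crossings are clipped to exactly 0.

External drive is i.i.d. Gaussian current, $I_{i}(t) \sim
N(2.5\times10^{-10}\,\mathrm{A},\ 10^{-10}\,\mathrm{A})$, chosen so the
drive alone produces low firing rates (measured: about 1.4 Hz at zero
weights under these defaults) while recurrent weights can push rates far
higher — the weights, not the drive, dominate the output.

Four named initial-weight configurations are provided by
[`init_weights()`] (`uniform`, `gaussian`, `sparse`, `naive-half-max`);
magnitudes in mV are $U[0,5]$, truncated $N(0.4, 0.4)$ (negative draws
redrawn, not clipped, so the magnitude distribution stays proper),
$U[0,5]$ with half of the naive entries zeroed, and $U[0,5]$ vs
$U[0,2.5]$ respectively. A reference and a naive network within a trial
share the inhibitory-neuron assignment (pass `sign_mask`); the mirrored
control updates must respect the same sign structure, which forces the
shared assignment.

## Matching spikes

For one neuron, reference spike times $t^{(r)}_k$ and observed times
$t^{(o)}_l$ are paired by a dynamic program over monotone (non-crossing)
pairings. Pairing costs the temporal distance $d_{k,l} = |t^{(r)}_k -
t^{(o)}_l|$; leaving a spike unpaired costs $a_{cap}$ (default 15 steps,
about 45 ms):

$$\Lambda_{k,l} = \min\{\Lambda_{k-1,l-1} + d_{k,l},\;
  \Lambda_{k-1,l} + a_{cap},\; \Lambda_{k,l-1} + a_{cap},\;
  \Lambda_{k-1,l-1} + 2a_{cap}\},$$

with $\Lambda_{0,l} = l\,a_{cap}$, $\Lambda_{k,0} = k\,a_{cap}$. Two
subtleties:

* As written, the recursion will pair spikes up to $2a_{cap}$ apart
  (one pairing at distance $d < 2a_{cap}$ beats two penalties), even
  though $a_{cap}$ is described as the maximum pairable separation. We
  implement the recursion literally and expose a `strict` post-filter
  (default off) that unpairs such pairs.
* Ties in the minimum are broken with fixed precedence (pair, skip-ref,
  skip-obs, skip-both). All tied choices are cost-optimal; fixing an
  order makes results bit-reproducible. The fourth branch is dominated
  by compositions of the two skip branches but is retained verbatim.

The matrix is filled along anti-diagonals (each diagonal is one
vectorised `pmin`), so matching stays fast for spike trains with
thousands of spikes; exactness is guaranteed by an exhaustive-search
oracle over all monotone pairings in the test suite.

## The learning loop

Each epoch ([`run_pspm()`]): simulate with the current weights; match
every neuron's observed train against its reference; then

1. **Local updates** ([`local_updates()`]). For each unpaired reference
   spike at time $t$ of neuron $i$ (a *missing* spike), every
   presynaptic $j \ne i$ that spiked in the observed raster within the
   closed window $[t - z, t]$ ($z = 10$ steps) receives
   $W_{ij} \leftarrow W_{ij} + \delta$, $\delta \sim U[0,
   \delta_{max}]$, independently per synapse. Unpaired observed
   (*extra*) spikes trigger the mirror-image decrement. Default
   $\delta_{max} = 10^{-7}$ V.
2. **Homeostasis** ([`homeostatic_update()`]). With $x$ reference and
   $y$ observed spikes in total, every off-diagonal weight receives an
   independent draw between 0 and $(x - y) \times 10^{-11}$ V — blanket
   potentiation when the network is too quiet, depression when too
   active, the identity when $x = y$. The signed-interval reading makes
   the rule self-gating, so it runs every epoch without an activity
   tolerance.
3. **Control mirroring** ([`control_mirror()`]). Every local delta is
   replayed on a copy of the naive network at a uniformly random
   off-diagonal synapse (independently per delta, irrespective of
   excitatory/inhibitory identity, clipping at the target). The control
   also receives its own homeostatic draws from the same $(x-y)$
   interval: homeostatic changes already hit every synapse, so
   randomising their location would be a no-op, and fresh draws keep
   the two networks' homeostatic treatment statistically identical.
   After training, the control isolates what update *placement* (as
   opposed to update budget) contributes.

Ordering decisions: pairings are computed from the epoch's fixed rasters
(they depend on spikes, not weights, so neuron-by-neuron evaluation is
order-independent); neurons are visited in index order, missing-spike
updates before extra-spike updates; one homeostatic pass closes the
epoch. The per-epoch history records spike counts, unpaired counts, the
update budget and distance snapshots; `tidy()` returns it, `glance()`
the final state, `autoplot()` the training curves.

## Spike-train similarity

Binary trains are convolved with a truncated symmetric Gaussian kernel
$K(t) = e^{-t^2/2\sigma^2}$, $\sigma = 5\sqrt2$ steps ($\approx 21$ ms),
support $\pm 5\sigma$, zero-padded at the boundaries. The symmetric
kernel (instead of the causal exponential of the classic van Rossum
metric) grants tolerance on both sides of a spike. From the activity
signals two distances are formed, with all time integrals realised as
unit-weight sums over steps (distances are in timestep units):

* **Pairwise** $D_P = \sum_i \sum_t [a(s_i,t) - a(r_i,t)]^2$ — sensitive
  to which neuron fires when;
* **Aggregate** $D_A = \sum_t [A(S,t) - A(R,t)]^2$ with $A = \sum_i a$ —
  invariant under neuron relabelling, a population-activity comparison.

Inter-spike-interval distributions are concatenated network-wide and
compared as fixed-bin histograms by the $\ell_2$ norm of the count
difference. The bin width is not dictated by anything in the method; we
default to 3 steps ($\approx 9$ ms), roughly the kernel's half-width,
and expose it. Spike-count variance over neurons uses the population
convention (divide by $N$). Weight recovery is measured by the
component-wise sum of squared differences (squared Frobenius norm).

## The probabilistic integrate-and-fire model and criticality

The PIF is a binary stochastic network:
$s_i(t+1) = \Theta[\sum_j W_{ij} s_j(t) + I_i(t) - \xi_i(t)]$ with
$\xi_i \sim U[0,1]$, i.e. a neuron fires with probability equal to its
summed input (clamped to $[0,1]$); $\Theta(0) = 1$ by convention, which
only matters on measure-zero events. [`build_pif_network()`] draws
Bernoulli(0.1) connectivity with $U[0, 0.02]$ weights and rescales the
matrix to spectral radius exactly 1 — the critical point of the linear
branching approximation. Drive is $0.001 \times \mathrm{Poisson}(1)$
per neuron and step.

A dynamical caveat that matters for interpretation: with no
refractoriness, a spectral radius of 1 makes summed activity a
*marginal* branching random walk with an absorbing-ish ceiling where
firing probabilities saturate. Under sustained drive the walk reaches
high-activity levels within a few thousand steps and wanders there
(measured per-neuron rates around 0.5 spikes/step at $N = 400$,
$T = 50{,}000$), which yields hundreds — not thousands — of
threshold-crossing avalanches, and size/duration exponents near 1.13
and 1.39 under the maximum-likelihood fit. We implement the update rule
literally and report what it produces rather than adding stabilising
mechanisms (refractoriness, subcritical rescaling) the model definition
does not contain; at smaller $N$ and shorter horizons the walk stays in
the low-activity regime and the avalanche statistics are much better
behaved, which is the regime the scaled-down transfer study (below)
operates in.

**Avalanches** ([`extract_avalanches()`]) are maximal runs of summed
activity strictly above the 20th percentile of all $T$ values (zeros
included; linear-interpolation quantile). Size is the spike total of
the run, duration its length; runs truncated by the raster edge are
kept (a flag drops them). **Power laws** are fitted by the discrete
zeta-normalised maximum likelihood with $x_{min} = 1$
([`fit_power_law()`]; the Hurwitz zeta is evaluated by direct summation
with an Euler–Maclaurin tail, accurate well below $10^{-10}$), with
standard errors from the observed information. A log-binned density
regression is available for comparison. **The crackling-noise
relation**: from size exponent $\tau$ and duration exponent $\alpha$ the
predicted scaling of mean size with duration is $\beta_p =
(\alpha-1)/(\tau-1)$; the observed $\beta_o$ is the OLS slope of
$\log \langle S \rangle(D)$ against $\log D$ (mean size per observed
duration; a per-avalanche regression is optional). $\beta$ is reported
as a positive growth exponent, the standard convention. Agreement
$|\beta_o - \beta_p| \approx 0$ alongside power-law size and duration
statistics is the criticality signature.

## Problem sizes and the desk-scale update calibration

The full-scale studies (400 neurons, 10,000-step trials, 150 epochs, 30
trials; 50,000-step PIF reference split into five segments) are what the
defaults of `run_lif_learning_study()` / `run_pif_criticality_study()`
describe. The test suite and examples run *scaled-down* versions: 20
neurons, 1,000 steps, 50 epochs and 10 trials for the learning study;
80 neurons, two 1,500-step segments, 20 epochs and 5 seeds for the
criticality transfer.

At full scale a synapse accumulates thousands of $U[0, 10^{-7}]$ V local
draws and the homeostatic interval is driven by spike-count differences
in the tens of thousands, so the cumulative change is commensurate with
the mV weight scale. Scaling $N$, $T$ and the epoch count down by a
combined factor of order $10^3$ shrinks the number of update events by
the same factor, and with unchanged per-update magnitudes the weights
could move by at most $\sim 10^{-5}$ V over a whole desk run — no spike
would ever be created or removed and training would be exactly frozen.
The desk-scale runs therefore scale the two update magnitudes by the
inverse of the event-budget reduction, keeping the *cumulative* update
budget a fixed fraction of the weight scale: $\delta_{max} = 10^{-4}$ V
and homeostatic unit $10^{-8}$ V/spike for the 20-neuron learning study
(whose weights are mV-scale), and $10^{-5}$ V with $10^{-9}$ V/spike for
the criticality transfer (whose naive weights are $U[0, 10^{-3}]$ V).
This is a property of the scaled experimental design, fixed once by the
dimensional argument above; the full-scale defaults are untouched.

## What the synthetic generators do and do not emulate

All data are generated internally: weight ensembles from the four named
configurations, Gaussian currents, Poisson drive, and rasters simulated
from them. This emulates the ground-truth-recovery setting — a known
generative network, identical inputs for reference and learner — and
none of the complications of real recordings: no measurement noise or
missed spikes, no non-stationary drive (a single input distribution per
trial), no hidden neurons, no axonal delays beyond the one-step
convention, and neuron models far simpler than real cells. Passing
tests therefore show that the learning rule recovers *spike trains*
(and collective statistics) of a matched model class; they cannot show
that weights inferred from biological data would be correct — indeed
the weight-error results demonstrate non-identifiability even within
the matched class.

## Known limitations

* The matching cost matrix is exact but $O(nm)$ per neuron; saturated
  rasters (thousands of spikes per train) make training epochs
  expensive.
* Two free hyper-parameters, $a_{cap}$ and $z$, must be chosen a
  priori; $z$ encodes a guess about how far back the causal history of
  a spike reaches.
* The power-law fits use $x_{min} = 1$ throughout (single-exponent
  reporting); cutoff selection by KS minimisation is deliberately not
  performed.
* At spectral radius 1 the literal PIF saturates under sustained drive
  (see above), so full-scale avalanche counts are limited by long
  excursions rather than by the simulation horizon.
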