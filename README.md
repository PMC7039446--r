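# pspm

Supervised learning of synaptic weights in recurrent spiking neural
networks by **Pre-Synaptic Pool Modification (PSPM)**, together with the
simulators, spike-train distance metrics and neuronal-avalanche
criticality analysis needed to evaluate it.

The package is for computational neuroscientists asking whether fitting a
spiking network to reproduce target spike trains also recovers the
generating weights (connectome inference from activity), and for anyone
who needs a gradient-free rule for tuning recurrent leaky
integrate-and-fire (LIF) networks to produce prescribed spike patterns.

## The method

A reference LIF network produces target spike trains `R`; a naive network
with different weights sees the same input currents and produces `O`.
Each epoch, every neuron's observed spikes are optimally paired with its
reference spikes by a dynamic program over monotone pairings,

    Λ[k,l] = min( Λ[k-1,l-1] + |t_k - t_l|,   # pair
                  Λ[k-1,l]   + a_cap,          # ref spike unpaired
                  Λ[k,l-1]   + a_cap,          # obs spike unpaired
                  Λ[k-1,l-1] + 2·a_cap )       # both unpaired

with unpaired-spike penalty `a_cap` (15 steps ≈ 45 ms). For every spike
left unpaired, the *presynaptic pool* — neurons that spiked within `z =
10` steps beforehand — has its incoming weights nudged by independent
`Uniform[0, δ_max]` volt draws (up to induce a missing spike, down to
eliminate an extra one), and a network-wide homeostatic update draws
every weight toward the reference's overall spike count (`Uniform[0,
(x−y)·10⁻¹¹]` V). Weights never change sign. A *control* network
receives every local delta at a uniformly random synapse instead,
isolating the contribution of update placement from update budget.

Agreement is scored by Gaussian-filtered (van Rossum style) activity
signals — the pairwise distance `D_P` (neuron by neuron) and aggregate
distance `D_A` (network-summed) — plus inter-spike-interval histogram
distances, spike-count statistics and the Frobenius error between weight
matrices. A probabilistic integrate-and-fire (PIF) network rescaled to
spectral radius 1 provides critical reference spike trains; avalanche
size/duration power laws (discrete MLE) and the crackling-noise relation
`β_p = (α−1)/(τ−1)` versus the observed `β_o` quantify how close a
trained network sits to criticality.

## Worked example

Train a 20-neuron naive network to reproduce a reference raster
(desk-scale: update magnitudes scaled to the reduced spike budget, see
the methods vignette):

```r
library(pspm)

params <- lif_params(n = 20)
w_ref  <- init_weights("naive-half-max", "reference", n = 20, seed = 1)
w_nai  <- init_weights("naive-half-max", "naive", n = 20, seed = 2,
                       sign_mask = w_ref$sign_mask)
I <- generate_lif_inputs(1000, 20, seed = 3)
R <- simulate_lif(w_ref, I, params)$spikes

cfg <- learning_config(epochs = 50, seed = 4,
                       delta_max = 1e-4, homeo_scale = 1e-8)
fit <- run_pspm(R, w_nai, I, params, cfg)
fit
#> <pspm_fit> 20 neurons, 50 epochs
#>   unpaired spikes: 10 -> 4; D_P: 141.5 -> 66.79

pairwise_distance(fit$spikes_optimized, R)
#> [1] 66.79018
pairwise_distance(fit$spikes_control, R)
#> [1] 140.9953
```

Training more than halves the pairwise distance from the reference
(141.5 → 66.8, in timestep units of integrated squared activity-signal
difference), while the control network — which received the *same*
number and magnitude of weight changes at random synapses — barely moves
(141.0): placement, not budget, does the work. `tidy(fit)` returns the
per-epoch history, `autoplot(fit)` the training curves.

Avalanche analysis of any raster:

```r
w <- build_pif_network(400, p = 0.1, seed = 1)   # spectral radius 1
S <- simulate_pif(w, generate_pif_inputs(50000, 400, seed = 2), seed = 3)
criticality_report(S)   # tau, alpha, beta_p, beta_o, |beta_o - beta_p|
```

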