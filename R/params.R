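#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the LIF neuron constants. Defaults are typical cortical values:
#' membrane time constant 30 ms, membrane resistance 100 MOhm, spike
#' threshold 30 mV, Euler step 3 ms, and 20% inhibitory neurons.
#'
#' Internally the simulator works in volts and amperes; this constructor is
#' the boundary where the conventional units (ms, MOhm, mV) live.
#'
#' @param tau_m Membrane time constant, ms.
#' @param r_m Membrane resistance, MOhm.
#' @param v_th Spike threshold, mV.
#' @param dt Euler integration step, ms.
#' @param n Number of neurons.
#' @param inhib_fraction Fraction of neurons that are inhibitory, in `[0, 1)`.
#' @return A list of class `lif_params`.
#' @examples
#' lif_params(n = 50)
#' @export
lif_params <- function(tau_m = 30, r_m = 100, v_th = 30, dt = 3,
                       n = 400, inhib_fraction = 0.2) {
  stopifnot(tau_m > 0, r_m > 0, v_th > 0, dt > 0,
            n >= 1, inhib_fraction >= 0, inhib_fraction < 1)
  structure(
    list(tau_m = tau_m, r_m = r_m, v_th = v_th, dt = dt,
         n = as.integer(n), inhib_fraction = inhib_fraction),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat("<lif_params>",
      sprintf("  tau_m = %g ms, R_m = %g MOhm, V_th = %g mV, dt = %g ms",
              x$tau_m, x$r_m, x$v_th, x$dt),
      sprintf("  N = %d neurons (%g%% inhibitory)", x$n, 100 * x$inhib_fraction),
      sep = "\n")
  invisible(x)
}

#' PSPM learning configuration
#'
#' Hyper-parameters of the Pre-Synaptic Pool Modification training loop.
#'
#' @param a_cap Pairing cost cap: per-unpaired-spike penalty and the scale of
#'   the maximum temporal separation considered for pairing, in timesteps.
#' @param z Causal window, in timesteps: presynaptic neurons that spiked in
#'   the closed interval `[t - z, t]` before an unpaired spike at `t` form
#'   the presynaptic pool and receive local updates.
#' @param delta_max Cap of the local update magnitude; each pool synapse
#'   receives an independent draw from `Uniform[0, delta_max]` volts.
#' @param homeo_scale Homeostatic unit, volts per unit spike-count
#'   difference: with `x` reference and `y` observed spikes every synapse
#'   receives a draw between 0 and `(x - y) * homeo_scale` volts.
#' @param epochs Number of training epochs.
#' @param seed Integer seed controlling all stochastic updates of a run.
#' @param strict_pairing If `TRUE`, pairs further apart than `a_cap` are
#'   post-filtered into unpaired spikes (see [match_spikes()]).
#' @param record_distances If `TRUE` (default), record pairwise and
#'   aggregate activity-signal distances every epoch in the history.
#' @return A list of class `learning_config`.
#' @examples
#' learning_config(epochs = 10, seed = 1)
#' @export
learning_config <- function(a_cap = 15, z = 10, delta_max = 1e-7,
                            homeo_scale = 1e-11, epochs = 150, seed = 1L,
                            strict_pairing = FALSE, record_distances = TRUE) {
  stopifnot(a_cap > 0, z > 0, delta_max > 0, homeo_scale > 0, epochs >= 0)
  structure(
    list(a_cap = a_cap, z = as.integer(z), delta_max = delta_max,
         homeo_scale = homeo_scale, epochs = as.integer(epochs),
         seed = as.integer(seed), strict_pairing = isTRUE(strict_pairing),
         record_distances = isTRUE(record_distances)),
    class = "learning_config"
  )
}

#' @export
print.learning_config <- function(x, ...) {
  cat("<learning_config>",
      sprintf("  a_cap = %g steps, z = %d steps", x$a_cap, x$z),
      sprintf("  delta_max = %g V, homeo_scale = %g V/spike", x$delta_max,
              x$homeo_scale),
      sprintf("  epochs = %d, seed = %d", x$epochs, x$seed),
      sep = "\n")
  invisible(x)
}
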