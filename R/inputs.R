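#' Generate Gaussian external input currents for a LIF network
#'
#' Independent draws from `N(mu, sigma)` amperes for every timestep and
#' neuron. The defaults (`mu = 2.5e-10` A, `sigma = 1e-10` A) are tuned so
#' that a network with all weights zero fires at a mean rate in `(0, 1]` Hz,
#' while nonzero synaptic weights can push rates beyond 10 Hz -- i.e. the
#' external drive stays weak relative to recurrent input, so the weights,
#' not the drive, dominate the output spike trains.
#'
#' @param t_steps Number of timesteps.
#' @param n Number of neurons.
#' @param mu Mean input current, amperes.
#' @param sigma Input current standard deviation, amperes.
#' @param seed Integer seed.
#' @return A `t_steps x n` numeric matrix of currents (amperes).
#' @examples
#' I <- generate_lif_inputs(100, 10, seed = 1)
#' @export
generate_lif_inputs <- function(t_steps, n, mu = 2.5e-10, sigma = 1e-10,
                                seed = 1L) {
  stopifnot(t_steps >= 1, n >= 1, sigma >= 0)
  with_seed(seed, matrix(rnorm(t_steps * n, mu, sigma), t_steps, n))
}

#' Generate scaled Poisson inputs for a PIF network
#'
#' Entries are `scale` times independent `Poisson(1)` draws; they enter the
#' PIF update as dimensionless additive firing probabilities. The default
#' `scale = 0.001` yields a network-wide spontaneous rate above 0.003
#' spikes per timestep once recurrent amplification at criticality is
#' taken into account.
#'
#' @param t_steps Number of timesteps.
#' @param n Number of neurons.
#' @param scale Multiplier applied to the Poisson draws.
#' @param seed Integer seed.
#' @return A `t_steps x n` numeric matrix of dimensionless inputs.
#' @examples
#' I <- generate_pif_inputs(100, 10, seed = 1)
#' @export
generate_pif_inputs <- function(t_steps, n, scale = 0.001, seed = 1L) {
  stopifnot(t_steps >= 1, n >= 1, scale >= 0)
  with_seed(seed, matrix(scale * rpois(t_steps * n, 1), t_steps, n))
}
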