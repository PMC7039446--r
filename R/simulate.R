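#' Simulate a leaky integrate-and-fire network
#'
#' Forward-Euler integration of the LIF membrane equation. At every step
#' each subthreshold neuron follows
#' \deqn{V_i \leftarrow V_i + \frac{dt}{\tau}\left(-V_i + R_m I_i(t) +
#'   \sum_j W_{ij} s_j(t-1)\right)}
#' and any neuron whose potential reaches the threshold emits a spike and
#' resets to 0 in the same step. The synaptic sum uses spikes from the
#' previous step (a one-step synaptic delay), which makes the update
#' well-defined and independent of neuron ordering. All neurons start at
#' `V = 0`, the reset value; there is no refractory period, so a neuron may
#' spike on consecutive steps. The simulation is fully deterministic given
#' `(W, I, params)`.
#'
#' @param W A [weight_matrix()] or bare `n x n` matrix, volts.
#' @param I A `t_steps x n` matrix of input currents, amperes.
#' @param params A [lif_params()] object.
#' @return A list of class `pspm_sim` with `spikes` (`t_steps x n` 0/1
#'   integer matrix) and `voltages` (`t_steps x n`, mV, recorded after
#'   reset handling so spiking steps show 0).
#' @examples
#' p <- lif_params(n = 1)
#' W <- matrix(0, 1, 1)
#' I <- matrix(4e-10, 50, 1)
#' sim <- simulate_lif(W, I, p)
#' which(sim$spikes == 1)
#' @export
simulate_lif <- function(W, I, params = lif_params(n = ncol(I))) {
  W <- as_weight(W)
  stopifnot(is.matrix(I), all(is.finite(I)), all(is.finite(W)))
  n <- ncol(I)
  if (!identical(dim(W), c(n, n))) {
    stop("`W` must be n x n with n matching the columns of `I`",
         call. = FALSE)
  }
  t_steps <- nrow(I)
  dt_tau <- params$dt / params$tau_m
  v_th <- params$v_th * 1e-3        # mV -> V
  r_ohm <- params$r_m * 1e6         # MOhm -> Ohm
  V <- numeric(n)
  spikes <- matrix(0L, t_steps, n)
  volt <- matrix(0, t_steps, n)
  prev <- integer(0)                # indices of neurons that spiked at t-1
  for (t in seq_len(t_steps)) {
    syn <- if (length(prev)) .rowSums(W[, prev, drop = FALSE], n,
                                      length(prev)) else 0
    V <- V + dt_tau * (-V + r_ohm * I[t, ] + syn)
    fired <- V >= v_th
    if (any(fired)) {
      V[fired] <- 0
      spikes[t, fired] <- 1L
      prev <- which(fired)
    } else {
      prev <- integer(0)
    }
    volt[t, ] <- V
  }
  structure(list(spikes = spikes, voltages = volt * 1e3, params = params),
            class = "pspm_sim")
}

#' @export
print.pspm_sim <- function(x, ...) {
  cat(sprintf("<pspm_sim> %d steps x %d neurons, %d spikes\n",
              nrow(x$spikes), ncol(x$spikes), sum(x$spikes)))
  invisible(x)
}

#' Simulate a probabilistic integrate-and-fire network
#'
#' Each neuron's binary state evolves as
#' \deqn{s_i(t+1) = \Theta\left[\sum_j W_{ij} s_j(t) + I_i(t) - \xi_i(t)\right]}
#' with `xi_i(t)` i.i.d. `Uniform[0, 1]` and `Theta` the unit step
#' (convention `Theta(0) = 1`; since `xi` is continuous this matters only
#' on measure-zero events). Equivalently, a neuron fires with probability
#' `min(1, max(0, sum_j W_ij s_j + I_i))`. The network starts silent.
#'
#' @param W Nonnegative [weight_matrix()] or bare matrix (PIF synapses are
#'   excitatory).
#' @param I A `t_steps x n` matrix of dimensionless inputs.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A `t_steps x n` 0/1 integer spike raster.
#' @examples
#' S <- simulate_pif(matrix(0, 3, 3), matrix(0.3, 100, 3), seed = 1)
#' mean(S)
#' @export
simulate_pif <- function(W, I, seed = 1L) {
  W <- as_weight(W)
  stopifnot(is.matrix(I), all(is.finite(I)))
  if (any(W < 0)) {
    stop("PIF weights must be nonnegative", call. = FALSE)
  }
  n <- ncol(I)
  if (!identical(dim(W), c(n, n))) {
    stop("`W` must be n x n with n matching the columns of `I`",
         call. = FALSE)
  }
  t_steps <- nrow(I)
  with_seed(seed, {
    spikes <- matrix(0L, t_steps, n)
    prev <- integer(0)
    for (t in seq_len(t_steps)) {
      drive <- if (length(prev)) .rowSums(W[, prev, drop = FALSE], n,
                                          length(prev)) else 0
      fired <- (drive + I[t, ] - runif(n)) >= 0
      if (any(fired)) {
        spikes[t, fired] <- 1L
        prev <- which(fired)
      } else {
        prev <- integer(0)
      }
    }
    spikes
  })
}
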