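# Independent oracles used to cross-check the vectorized implementations.
# All are deliberately naive (per-element loops, exhaustive enumeration);
# they share no code with the package internals they verify.

# Scalar per-neuron LIF loop: explicit double loop over steps and neurons.
oracle_lif <- function(W, I, params) {
  n <- ncol(I)
  t_steps <- nrow(I)
  dt_tau <- params$dt / params$tau_m
  v_th <- params$v_th * 1e-3
  r_ohm <- params$r_m * 1e6
  V <- numeric(n)
  S <- matrix(0L, t_steps, n)
  volt <- matrix(0, t_steps, n)
  s_prev <- numeric(n)
  for (t in seq_len(t_steps)) {
    V_new <- numeric(n)
    for (i in seq_len(n)) {
      syn <- 0
      for (j in seq_len(n)) syn <- syn + W[i, j] * s_prev[j]
      V_new[i] <- V[i] + dt_tau * (-V[i] + r_ohm * I[t, i] + syn)
    }
    s_now <- numeric(n)
    for (i in seq_len(n)) {
      if (V_new[i] >= v_th) {
        V_new[i] <- 0
        S[t, i] <- 1L
        s_now[i] <- 1
      }
    }
    V <- V_new
    s_prev <- s_now
    volt[t, ] <- V * 1e3
  }
  list(spikes = S, voltages = volt)
}

# Exhaustive minimum cost over all monotone pairings (n, m small).
oracle_pairing_cost <- function(ref, obs, a_cap = 15) {
  n <- length(ref)
  m <- length(obs)
  rec <- function(k, l) {
    if (k > n) return((m - l + 1) * a_cap)
    if (l > m) return((n - k + 1) * a_cap)
    min(abs(ref[k] - obs[l]) + rec(k + 1, l + 1),
        a_cap + rec(k + 1, l),
        a_cap + rec(k, l + 1))
  }
  rec(1, 1)
}

# Direct cost of a returned pairing, from its definition.
pairing_cost <- function(p, ref, obs, a_cap = 15) {
  d <- if (nrow(p$pairs)) sum(abs(ref[p$pairs[, 1]] - obs[p$pairs[, 2]]))
       else 0
  d + a_cap * (length(p$unpaired_ref) + length(p$unpaired_obs))
}

# Sum-of-Gaussians activity signal by direct per-timestep summation.
oracle_activity <- function(s, sigma = 5 * sqrt(2),
                            radius = ceiling(5 * sigma)) {
  t_steps <- length(s)
  a <- numeric(t_steps)
  for (t in seq_len(t_steps)) {
    for (t0 in which(s == 1)) {
      if (abs(t - t0) <= radius) {
        a[t] <- a[t] + exp(-(t - t0)^2 / (2 * sigma^2))
      }
    }
  }
  a
}

oracle_pairwise <- function(S, R) {
  total <- 0
  for (i in seq_len(ncol(S))) {
    total <- total + sum((oracle_activity(S[, i]) - oracle_activity(R[, i]))^2)
  }
  total
}

oracle_aggregate <- function(S, R) {
  A_S <- 0
  A_R <- 0
  for (i in seq_len(ncol(S))) {
    A_S <- A_S + oracle_activity(S[, i])
    A_R <- A_R + oracle_activity(R[, i])
  }
  sum((A_S - A_R)^2)
}

# Run-length scan of a summed-activity vector against a fixed threshold.
oracle_avalanches <- function(f, thr) {
  out <- list()
  in_run <- FALSE
  start <- 0
  for (t in seq_along(f)) {
    if (f[t] > thr && !in_run) {
      in_run <- TRUE
      start <- t
    }
    if (in_run && (f[t] <= thr)) {
      out[[length(out) + 1]] <- c(start, t - 1)
      in_run <- FALSE
    }
  }
  if (in_run) out[[length(out) + 1]] <- c(start, length(f))
  do.call(rbind, lapply(out, function(run) {
    data.frame(start = run[1], duration = run[2] - run[1] + 1,
               size = sum(f[run[1]:run[2]]))
  }))
}

# Inverse-CDF sampler for the discrete power law P(x) ~ x^-s, x >= x_min:
# exact CDF table up to `kmax`, continuous Pareto mapping for the tail.
sample_power_law <- function(n, exponent, x_min = 1, kmax = 1e5) {
  k <- x_min:kmax
  pk <- k^(-exponent)
  cdf <- cumsum(pk)
  tail_mass <- kmax^(1 - exponent) / (exponent - 1)
  z <- cdf[length(cdf)] + tail_mass
  u <- runif(n) * z
  x <- numeric(n)
  inside <- u <= cdf[length(cdf)]
  x[inside] <- k[findInterval(u[inside], cdf, left.open = TRUE) + 1]
  if (any(!inside)) {
    v <- (u[!inside] - cdf[length(cdf)]) / tail_mass
    x[!inside] <- floor(kmax * (1 - v)^(-1 / (exponent - 1)))
  }
  x
}

# Small random raster with approximately `rate` spikes per step per neuron.
random_raster <- function(t_steps, n, rate = 0.1) {
  matrix(as.integer(runif(t_steps * n) < rate), t_steps, n)
}

# Small random signed weight matrix respecting a sign mask.
random_weights <- function(n, inhib = max(1, floor(0.2 * n)), scale = 5e-3) {
  sign_mask <- rep("excitatory", n)
  sign_mask[sample.int(n, inhib)] <- "inhibitory"
  W <- matrix(runif(n * n, 0, scale), n, n)
  W[, sign_mask == "inhibitory"] <- -W[, sign_mask == "inhibitory"]
  diag(W) <- 0
  weight_matrix(W, sign_mask)
}
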