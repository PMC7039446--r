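test_that("zero weights and zero input are a fixed point of the LIF dynamics", {
  p <- lif_params(n = 3)
  sim <- simulate_lif(matrix(0, 3, 3), matrix(0, 20, 3), p)
  expect_equal(sum(sim$spikes), 0)
  expect_equal(sim$voltages, matrix(0, 20, 3))
})

test_that("a single neuron under constant suprathreshold drive follows the scalar Euler recurrence", {
  p <- lif_params(n = 1)
  # independent scalar oracle: V <- V + (dt/tau) * (40 - V) in mV, reset at 30
  v <- 0
  expected <- integer(0)
  for (t in 1:60) {
    v <- v + 0.1 * (40 - v)
    if (v >= 30) {
      v <- 0
      expected <- c(expected, t)
    }
  }
  sim <- simulate_lif(matrix(0, 1, 1), matrix(4e-10, 60, 1), p)
  expect_identical(which(sim$spikes[, 1] == 1L), expected)
  expect_equal(expected[1], 14)           # first spike step
  expect_equal(unique(diff(expected)), 14) # inter-spike period
})

test_that("a strong excitatory synapse propagates a spike one step downstream", {
  p <- lif_params(n = 3)
  # neuron 1 driven over threshold at step 1 by a single current pulse;
  # W[2,1] alone exceeds the threshold gap scaled by tau/dt; neuron 3 is
  # disconnected
  W <- matrix(0, 3, 3)
  W[2, 1] <- 0.4 # volts: dt/tau * 0.4 V = 40 mV > 30 mV
  I <- matrix(0, 10, 3)
  I[1, 1] <- 4e-9 # R_m I = 400 mV in one step
  sim <- simulate_lif(W, I, p)
  expect_equal(which(sim$spikes[, 1] == 1L), 1L)
  expect_equal(which(sim$spikes[, 2] == 1L), 2L)
  expect_equal(sum(sim$spikes[, 3]), 0)
})

test_that("the vectorized LIF simulator agrees exactly with a per-neuron loop oracle", {
  p <- lif_params(n = 5, inhib_fraction = 0.2)
  withr::with_seed(101, {
    for (rep in 1:5) {
      W <- random_weights(5, scale = 0.2)
      I <- matrix(rnorm(50 * 5, 2.5e-10, 1e-10), 50, 5)
      sim <- simulate_lif(W, I, p)
      ora <- oracle_lif(W$W, I, p)
      expect_identical(sim$spikes, ora$spikes)
      expect_equal(sim$voltages, ora$voltages, tolerance = 1e-12)
    }
  })
})

test_that("LIF simulation is deterministic, leaves W untouched, and records subthreshold voltages", {
  p <- lif_params(n = 4)
  W <- withr::with_seed(7, random_weights(4, scale = 0.1))
  W_copy <- W$W
  I <- generate_lif_inputs(100, 4, seed = 8)
  s1 <- simulate_lif(W, I, p)
  s2 <- simulate_lif(W, I, p)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(W$W, W_copy)
  expect_true(all(s1$voltages < p$v_th))
})

test_that("PIF firing follows the stated threshold rule", {
  # saturating input: every neuron fires every step
  S <- simulate_pif(matrix(0, 3, 3), matrix(1.5, 20, 3), seed = 1)
  expect_true(all(S == 1L))
  # no drive: silence
  S0 <- simulate_pif(matrix(0, 3, 3), matrix(0, 20, 3), seed = 1)
  expect_equal(sum(S0), 0)
  # negative weights rejected
  expect_error(simulate_pif(matrix(-0.1, 2, 2), matrix(0, 5, 2)),
               "nonnegative")
})

test_that("an isolated PIF neuron fires as a Bernoulli process with rate equal to its input", {
  t_steps <- 1e5
  S <- simulate_pif(matrix(0, 1, 1), matrix(0.3, t_steps, 1), seed = 42)
  se <- sqrt(0.3 * 0.7 / t_steps)
  expect_lt(abs(mean(S) - 0.3), 3 * se)
})

test_that("build_pif_network normalizes the spectral radius to one at the requested density", {
  w <- build_pif_network(400, p = 0.10, w_range = c(0, 0.02), seed = 5)
  lambda <- max(Mod(eigen(w$W, only.values = TRUE)$values))
  expect_lt(abs(lambda - 1), 1e-9)
  # normalization is idempotent
  W2 <- normalize_spectral_radius(w$W)
  expect_equal(max(Mod(eigen(W2, only.values = TRUE)$values)), 1,
               tolerance = 1e-9)
  # off-diagonal density close to p
  offdiag <- w$W[row(w$W) != col(w$W)]
  dens <- mean(offdiag > 0)
  se <- sqrt(0.1 * 0.9 / length(offdiag))
  expect_lt(abs(dens - 0.10), 3 * se)
  expect_true(all(w$W >= 0))
})

test_that("spectral normalization matches the closed form on a fixed 2 x 2 matrix", {
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2) # eigenvalues +-0.5
  expect_equal(normalize_spectral_radius(W), matrix(c(0, 1, 1, 0), 2, 2))
})

test_that("initial weight configurations respect their stated distributions and sign structure", {
  for (cfg in c("uniform", "gaussian", "sparse", "naive-half-max")) {
    w <- init_weights(cfg, "naive", n = 30, seed = 3)
    expect_equal(diag(w$W), rep(0, 30))
    exc <- w$sign_mask == "excitatory"
    expect_true(all(w$W[, exc] >= 0))
    expect_true(all(w$W[, !exc] <= 0))
    expect_equal(sum(!exc), floor(0.2 * 30))
  }
  # naive-half-max naive magnitudes bounded by 2.5 mV; reference by 5 mV
  w_nai <- init_weights("naive-half-max", "naive", n = 40, seed = 4)
  expect_lte(max(abs(w_nai$W)), 2.5e-3)
  w_ref <- init_weights("naive-half-max", "reference", n = 40, seed = 4)
  expect_gt(max(abs(w_ref$W)), 2.5e-3)
  # sparse naive: exactly floor(n^2 / 2) zeroed entries beyond the diagonal
  w_sp <- init_weights("sparse", "naive", n = 40, seed = 5)
  offdiag_zero <- sum(w_sp$W[row(w_sp$W) != col(w_sp$W)] == 0)
  expect_equal(offdiag_zero, floor(40^2 / 2))
  # reference role of sparse is dense
  w_spr <- init_weights("sparse", "reference", n = 40, seed = 5)
  expect_equal(sum(w_spr$W[row(w_spr$W) != col(w_spr$W)] == 0), 0)
  # seeded RNG contract
  expect_identical(init_weights("uniform", "naive", n = 10, seed = 9)$W,
                   init_weights("uniform", "naive", n = 10, seed = 9)$W)
  expect_false(identical(init_weights("uniform", "naive", n = 10, seed = 9)$W,
                         init_weights("uniform", "naive", n = 10, seed = 10)$W))
  # a shared sign mask is honoured
  w2 <- init_weights("uniform", "naive", n = 30, seed = 11,
                     sign_mask = w_nai$sign_mask[1:30])
  expect_identical(w2$sign_mask, w_nai$sign_mask[1:30])
})

test_that("gaussian-config magnitudes are nonnegative with the stated moments", {
  w <- init_weights("gaussian", "reference", n = 60, seed = 6)
  mags <- abs(w$W[row(w$W) != col(w$W)])
  expect_true(all(mags >= 0))
  # N(0.4, 0.4) mV truncated at 0 has mean 0.4 + 0.4 * phi(-1)/Phi(1)
  mu_trunc <- (0.4 + 0.4 * dnorm(-1) / pnorm(1)) * 1e-3
  expect_lt(abs(mean(mags) - mu_trunc), 2e-5)
})

test_that("input generators match their stated distributions", {
  I <- generate_lif_inputs(1000, 1000, seed = 21)
  se <- 1e-10 / sqrt(1e6)
  expect_lt(abs(mean(I) - 2.5e-10), 4 * se)
  expect_true(all(generate_lif_inputs(10, 3, sigma = 0, seed = 1) == 2.5e-10))
  J <- generate_pif_inputs(1000, 1000, seed = 22)
  se_p <- 0.001 / sqrt(1e6)
  expect_lt(abs(mean(J) - 0.001), 4 * se_p)
  expect_true(all(generate_pif_inputs(10, 3, scale = 0, seed = 1) == 0))
  # seeded contract
  expect_identical(generate_lif_inputs(5, 5, seed = 2),
                   generate_lif_inputs(5, 5, seed = 2))
})

test_that("the external drive is weak: zero-weight LIF rates are low and recurrent weights dominate", {
  p <- lif_params(n = 200)
  I <- generate_lif_inputs(1000, 200, seed = 31)
  rate_zero <- mean(simulate_lif(matrix(0, 200, 200), I, p)$spikes) /
    (p$dt / 1000)
  expect_gt(rate_zero, 0)
  expect_lt(rate_zero, 2) # Hz; the tuning target is of order 1 Hz
  W <- init_weights("uniform", "reference", n = 200, seed = 32)
  rate_w <- mean(simulate_lif(W, I, p)$spikes) / (p$dt / 1000)
  expect_gt(rate_w, 10) # nonzero weights push rates beyond 10 Hz
})

test_that("a driven critical PIF network exceeds the stated spontaneous rate", {
  w <- build_pif_network(200, p = 0.1, seed = 41)
  I <- generate_pif_inputs(2000, 200, seed = 42)
  S <- simulate_pif(w, I, seed = 43)
  expect_gt(mean(S), 0.003) # spikes per neuron per step
})

test_that("weight_matrix validates sign structure and dimensions", {
  expect_error(weight_matrix(matrix(1, 2, 3)), "is.matrix|nrow")
  expect_error(weight_matrix(diag(2)), "diagonal")
  W <- matrix(c(0, 1, -1, 0), 2, 2)
  expect_error(weight_matrix(W, c("excitatory", "excitatory")), ">= 0")
  expect_s3_class(weight_matrix(W, c("excitatory", "inhibitory")),
                  "weight_matrix")
})
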