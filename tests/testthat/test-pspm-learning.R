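test_that("local updates target exactly the presynaptic pool inside the causal window", {
  cfg <- learning_config(seed = 1)
  n <- 4
  W <- weight_matrix(matrix(0, n, n) + 1e-3 * (1 - diag(n)))
  obs <- matrix(0L, 40, n)
  obs[12, 2] <- 1L # inside [10, 20] for an unpaired spike at t = 20, z = 10
  obs[9, 3] <- 1L  # outside the closed window
  obs[20, 4] <- 1L # boundary: included
  withr::with_seed(2, {
    up <- local_updates(W, obs, neuron = 1, unpaired_time = 20, "induce", cfg)
  })
  expect_setequal(up$applied$j, c(2, 4))
  expect_true(all(up$applied$delta >= 0 & up$applied$delta <= cfg$delta_max))
  expect_equal(up$W$W[1, 3], 1e-3) # untouched
  expect_equal(up$W$W[1, 2], 1e-3 + up$applied$delta[up$applied$j == 2])
  # rows of other neurons untouched
  expect_equal(up$W$W[2:4, ], W$W[2:4, ])
})

test_that("local updates never touch the postsynaptic neuron's own synapse or empty pools", {
  cfg <- learning_config(seed = 1)
  n <- 3
  W <- weight_matrix(matrix(1e-3, n, n) * (1 - diag(n)))
  # only the postsynaptic neuron itself spiked in the window
  obs <- matrix(0L, 30, n)
  obs[18, 1] <- 1L
  up <- local_updates(W, obs, neuron = 1, unpaired_time = 20, "induce", cfg)
  expect_identical(up$W$W, W$W)
  expect_equal(nrow(up$applied), 0)
})

test_that("eliminate-direction updates clip sign-crossing weights to exactly zero", {
  cfg <- learning_config(delta_max = 1e-7, seed = 3)
  n <- 2
  W <- weight_matrix(matrix(c(0, 0, 3e-8, 0), n, n)) # small excitatory W[1,2]
  obs <- matrix(0L, 30, n)
  obs[15, 2] <- 1L
  # draw until a delta larger than the weight magnitude occurs
  withr::with_seed(4, {
    up <- local_updates(W, obs, neuron = 1, unpaired_time = 15,
                        "eliminate", cfg)
  })
  if (abs(up$applied$delta) > 3e-8) {
    expect_identical(up$W$W[1, 2], 0)
  } else {
    expect_gte(up$W$W[1, 2], 0)
  }
  # inhibitory weights pushed above zero clip to zero too
  W2 <- weight_matrix(matrix(c(0, 0, -3e-8, 0), n, n),
                      c("excitatory", "inhibitory"))
  withr::with_seed(4, {
    up2 <- local_updates(W2, obs, neuron = 1, unpaired_time = 15,
                         "induce", cfg)
  })
  expect_lte(up2$W$W[1, 2], 0)
})

test_that("homeostatic updates draw from the signed interval and vanish when counts agree", {
  cfg <- learning_config(homeo_scale = 1e-11, seed = 5)
  W <- init_weights("uniform", "naive", n = 10, seed = 6)
  expect_identical(homeostatic_update(W, 50, 50, cfg)$W, W$W)
  withr::with_seed(7, {
    up <- homeostatic_update(W, 150, 50, cfg) # x - y = 100
  })
  d <- up$W - W$W
  offdiag <- row(d) != col(d)
  expect_true(all(d[offdiag] >= 0 & d[offdiag] <= 100 * 1e-11 + 1e-18))
  expect_true(all(diag(d) == 0))
  # excess activity depresses: draws negative, excitatory weights clipped at 0
  W_small <- weight_matrix(matrix(c(0, 0, 2e-10, 0), 2, 2))
  withr::with_seed(8, {
    dn <- homeostatic_update(W_small, 0, 100, cfg)
  })
  expect_gte(dn$W[1, 2], 0)
  expect_lte(dn$W[1, 2], 2e-10)
})

test_that("control mirroring conserves the number and magnitude of deltas before clipping", {
  # all off-diagonal weights well away from zero so no delta can clip
  W <- weight_matrix(1e-3 * (1 - diag(8)))
  applied <- tibble::tibble(i = rep(1L, 5), j = 2:6,
                            delta = c(1, -2, 3, -4, 5) * 1e-8)
  withr::with_seed(10, {
    out <- control_mirror(W, applied)
  })
  d <- out$W - W$W
  # weights are ~mV scale so 1e-8 deltas never clip: totals conserved
  # (tolerance reflects 1e-3 + 1e-8 floating-point cancellation)
  expect_equal(sum(d), sum(applied$delta), tolerance = 1e-6)
  expect_lte(sum(d != 0), 5)
  expect_true(all(diag(d) == 0))
  # empty list is the identity; fixed seed reproduces
  expect_identical(control_mirror(W, applied[0, ])$W, W$W)
  withr::with_seed(10, out2 <- control_mirror(W, applied))
  expect_identical(out$W, out2$W)
})

test_that("a reference produced by the naive network itself is a fixed point of training", {
  p <- lif_params(n = 8)
  W <- init_weights("uniform", "naive", n = 8, seed = 11)
  I <- generate_lif_inputs(300, 8, seed = 12)
  R <- simulate_lif(W, I, p)$spikes
  fit <- run_pspm(R, W, I, p, learning_config(epochs = 2, seed = 13))
  expect_identical(fit$W_optimized$W, W$W)
  expect_identical(fit$W_control$W, W$W)
  expect_equal(fit$history$n_missing, c(0L, 0L))
  expect_equal(fit$history$n_extra, c(0L, 0L))
  expect_equal(fit$history$d_pairwise, c(0, 0))
})

test_that("zero epochs return the naive network unchanged", {
  p <- lif_params(n = 5)
  W_ref <- init_weights("naive-half-max", "reference", n = 5, seed = 14)
  W_nai <- init_weights("naive-half-max", "naive", n = 5, seed = 15,
                        sign_mask = W_ref$sign_mask)
  I <- generate_lif_inputs(100, 5, seed = 16)
  R <- simulate_lif(W_ref, I, p)$spikes
  fit <- run_pspm(R, W_nai, I, p, learning_config(epochs = 0, seed = 17))
  expect_identical(fit$W_optimized$W, W_nai$W)
  expect_identical(fit$W_control$W, W_nai$W)
  expect_equal(nrow(fit$history), 0)
})

test_that("training preserves Dale sign structure and is reproducible", {
  p <- lif_params(n = 12)
  W_ref <- init_weights("naive-half-max", "reference", n = 12, seed = 18)
  W_nai <- init_weights("naive-half-max", "naive", n = 12, seed = 19,
                        sign_mask = W_ref$sign_mask)
  I <- generate_lif_inputs(400, 12, seed = 20)
  R <- simulate_lif(W_ref, I, p)$spikes
  cfg <- learning_config(epochs = 8, seed = 21)
  fit <- run_pspm(R, W_nai, I, p, cfg)
  for (W in list(fit$W_optimized, fit$W_control)) {
    exc <- W$sign_mask == "excitatory"
    expect_true(all(W$W[, exc] >= 0))
    expect_true(all(W$W[, !exc] <= 0))
    expect_true(all(diag(W$W) == 0))
  }
  fit2 <- run_pspm(R, W_nai, I, p, cfg)
  expect_identical(fit$W_optimized$W, fit2$W_optimized$W)
  expect_identical(fit$W_control$W, fit2$W_control$W)
  expect_equal(fit$history, fit2$history)
})

test_that("training reduces the pairwise distance on a desk-scale problem", {
  p <- lif_params(n = 20)
  W_ref <- init_weights("naive-half-max", "reference", n = 20, seed = 22)
  W_nai <- init_weights("naive-half-max", "naive", n = 20, seed = 23,
                        sign_mask = W_ref$sign_mask)
  I <- generate_lif_inputs(800, 20, seed = 24)
  R <- simulate_lif(W_ref, I, p)$spikes
  # update magnitudes scaled to the desk-scale spike budget (see the
  # methods vignette): ~10^3 fewer update events than at full scale
  cfg <- learning_config(epochs = 40, seed = 25,
                         delta_max = 1e-4, homeo_scale = 1e-8)
  fit <- run_pspm(R, W_nai, I, p, cfg)
  h <- fit$history
  expect_lt(h$d_pairwise[nrow(h)], h$d_pairwise[1])
  expect_lt(pairwise_distance(fit$spikes_optimized, R),
            h$d_pairwise[1])
  g <- glance(fit)
  expect_equal(g$epochs, 40L)
  expect_equal(tidy(fit), h)
})

test_that("one training epoch equals the manual composition of the update operations", {
  p <- lif_params(n = 10)
  W_ref <- init_weights("naive-half-max", "reference", n = 10, seed = 26)
  W_nai <- init_weights("naive-half-max", "naive", n = 10, seed = 27,
                        sign_mask = W_ref$sign_mask)
  I <- generate_lif_inputs(400, 10, seed = 28)
  R <- simulate_lif(W_ref, I, p)$spikes
  cfg <- learning_config(epochs = 1, seed = 29,
                         delta_max = 1e-4, homeo_scale = 1e-8)
  fit <- run_pspm(R, W_nai, I, p, cfg)
  # manual composition, drawing from the same seeded stream
  W <- W_nai
  W_ctrl <- W_nai
  withr::with_seed(cfg$seed, {
    O <- simulate_lif(W, I, p)$spikes
    x <- sum(R)
    y <- sum(O)
    applied <- list()
    for (i in 1:10) {
      pr <- match_spikes(which(R[, i] == 1L), which(O[, i] == 1L),
                         a_cap = cfg$a_cap)
      for (t in which(R[, i] == 1L)[pr$unpaired_ref]) {
        up <- local_updates(W, O, i, t, "induce", cfg)
        W <- up$W
        applied[[length(applied) + 1L]] <- up$applied
      }
      for (t in which(O[, i] == 1L)[pr$unpaired_obs]) {
        up <- local_updates(W, O, i, t, "eliminate", cfg)
        W <- up$W
        applied[[length(applied) + 1L]] <- up$applied
      }
    }
    W <- homeostatic_update(W, x, y, cfg)
    W_ctrl <- control_mirror(W_ctrl, dplyr::bind_rows(applied))
    W_ctrl <- homeostatic_update(W_ctrl, x, y, cfg)
  })
  expect_equal(fit$W_optimized$W, W$W, tolerance = 1e-15)
  expect_equal(fit$W_control$W, W_ctrl$W, tolerance = 1e-15)
})
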