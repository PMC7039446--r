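# PSPM learning loop: per-epoch simulation, spike matching, local
# presynaptic-pool updates, homeostatic scaling, and the mirrored
# random-synapse control condition.

# Apply a signed delta (or vector of deltas) to W at (i, pool) and clip any
# weight that crossed zero relative to its presynaptic sign back to exactly
# zero. Weights never change sign: an excitatory synapse cannot become
# inhibitory nor vice versa.
clip_signs <- function(w, exc) {
  w[exc & w < 0] <- 0
  w[!exc & w > 0] <- 0
  w
}

#' Local presynaptic-pool update for one unpaired spike
#'
#' Implements the core PSPM rule. For an unpaired reference spike of
#' neuron `i` at time `t` (direction `"induce"`), every presynaptic
#' neuron `j != i` that spiked in the observed raster within the closed
#' window `[t - z, t]` has its synapse `W[i, j]` increased by an
#' independent draw from `Uniform[0, delta_max]`; for an extra observed
#' spike (direction `"eliminate"`) the pool synapses are decreased by such
#' draws. Updates that would flip the sign of a weight are clipped to
#' exactly zero. The window is truncated at the raster boundary.
#'
#' @param W A [weight_matrix()].
#' @param obs_trains The observed `T x N` raster the pool is read from.
#' @param neuron Postsynaptic neuron index `i`.
#' @param unpaired_time Timestep `t` of the unpaired spike (1-based).
#' @param direction `"induce"` or `"eliminate"`.
#' @param cfg A [learning_config()] (supplies `z` and `delta_max`).
#' @return A list with the updated `W` and `applied`, a tibble of the
#'   signed deltas (columns `i`, `j`, `delta`) before clipping; an empty
#'   pool yields `W` unchanged and zero rows.
#' @examples
#' W <- weight_matrix(matrix(c(0, 0, 1e-3, 0), 2, 2))
#' S <- matrix(0L, 30, 2); S[18, 2] <- 1L
#' local_updates(W, S, neuron = 1, unpaired_time = 20,
#'               direction = "induce", cfg = learning_config(seed = 1))
#' @export
local_updates <- function(W, obs_trains, neuron, unpaired_time,
                          direction = c("induce", "eliminate"),
                          cfg = learning_config()) {
  direction <- match.arg(direction)
  obs_trains <- assert_raster(obs_trains)
  t <- as.integer(unpaired_time)
  stopifnot(t >= 1, t <= nrow(obs_trains))
  window <- max(1L, t - cfg$z):t
  pool <- which(colSums(obs_trains[window, , drop = FALSE]) > 0)
  pool <- setdiff(pool, neuron)
  if (!length(pool)) {
    return(list(W = W, applied = empty_applied()))
  }
  delta <- runif(length(pool), 0, cfg$delta_max)
  if (direction == "eliminate") delta <- -delta
  exc <- W$sign_mask[pool] == "excitatory"
  W$W[neuron, pool] <- clip_signs(W$W[neuron, pool] + delta, exc)
  list(W = W,
       applied = tibble::tibble(i = neuron, j = pool, delta = delta))
}

empty_applied <- function() {
  tibble::tibble(i = integer(0), j = integer(0), delta = numeric(0))
}

#' Network-wide homeostatic weight update
#'
#' With `x` total reference spikes and `y` total observed spikes in the
#' epoch, every off-diagonal weight receives an independent additive draw
#' between 0 and `(x - y) * homeo_scale` volts: potentiation across the
#' board when the network is too quiet (`y < x`), depression when it is
#' too active (`y > x`), and the identity when `x == y`. Sign-crossing
#' weights are clipped to zero as in [local_updates()].
#'
#' @param W A [weight_matrix()].
#' @param x,y Total reference and observed spike counts.
#' @param cfg A [learning_config()] (supplies `homeo_scale`).
#' @return The updated [weight_matrix()].
#' @examples
#' W <- init_weights("uniform", "naive", n = 5, seed = 1)
#' W2 <- homeostatic_update(W, x = 100, y = 0, cfg = learning_config())
#' @export
homeostatic_update <- function(W, x, y, cfg = learning_config()) {
  stopifnot(x >= 0, y >= 0)
  if (x == y) return(W)
  n <- nrow(W$W)
  bound <- (x - y) * cfg$homeo_scale
  draws <- matrix(runif(n * n, min(0, bound), max(0, bound)), n, n)
  diag(draws) <- 0
  exc <- matrix(rep(W$sign_mask == "excitatory", each = n), n, n)
  W$W <- clip_signs(W$W + draws, exc)
  W
}

#' Mirror local updates into the control network at random synapses
#'
#' Every local update applied to the optimized network is replayed on the
#' control network with identical magnitude and sign, but at a synapse
#' chosen uniformly at random among all `N(N-1)` off-diagonal positions
#' (independently per delta, irrespective of excitatory/inhibitory
#' identity). Deltas landing on the same synapse accumulate; sign
#' clipping is applied at the target after accumulation. This preserves
#' the per-epoch count and magnitude of weight changes while destroying
#' their placement.
#'
#' @param W_ctrl The control [weight_matrix()].
#' @param applied Tibble of deltas returned by [local_updates()].
#' @return The updated control [weight_matrix()].
#' @examples
#' W <- init_weights("uniform", "naive", n = 5, seed = 1)
#' d <- tibble::tibble(i = 1L, j = 2L, delta = 1e-7)
#' control_mirror(W, d)
#' @export
control_mirror <- function(W_ctrl, applied) {
  if (!nrow(applied)) return(W_ctrl)
  n <- nrow(W_ctrl$W)
  offdiag <- which(row(W_ctrl$W) != col(W_ctrl$W))
  target <- sample(offdiag, nrow(applied), replace = TRUE)
  add <- numeric(n * n)
  agg <- tapply(applied$delta, target, sum)
  add[as.integer(names(agg))] <- agg
  exc <- matrix(rep(W_ctrl$sign_mask == "excitatory", each = n), n, n)
  W_ctrl$W <- clip_signs(W_ctrl$W + matrix(add, n, n), exc)
  W_ctrl
}

#' Run the PSPM training loop
#'
#' Trains a naive LIF network to reproduce a set of reference spike
#' trains. Each epoch: (1) simulate the current network with the shared
#' input currents to obtain observed trains `O`; (2) optimally pair each
#' neuron's observed spikes with its reference spikes
#' ([match_spikes()]); (3) for every unpaired reference spike apply
#' induce-direction [local_updates()] and for every unpaired observed
#' spike eliminate-direction updates (all pairings are computed from the
#' epoch's raster before any weight change; neurons are visited in index
#' order, missing-spike updates before extra-spike updates); (4) apply
#' one [homeostatic_update()] with the epoch's total spike counts; (5)
#' replay all local deltas into the control network at random synapses
#' ([control_mirror()]) and give the control its own homeostatic draws
#' from the same `(x - y)` interval. After the last epoch the optimized
#' and control networks are simulated once more to produce their final
#' rasters.
#'
#' @param reference The target `T x N` binary raster.
#' @param W_naive Initial naive [weight_matrix()].
#' @param I Shared `T x N` input currents, amperes.
#' @param params A [lif_params()].
#' @param cfg A [learning_config()]; `cfg$seed` drives all stochastic
#'   updates, so the full result is reproducible.
#' @return A list of class `pspm_fit`: `W_optimized`, `W_control`,
#'   `W_naive`, `spikes_optimized`, `spikes_control`, `history` (one row
#'   per epoch: spike counts `x`, `y`, unpaired counts, number and summed
#'   magnitude of local updates, and the distances `d_pairwise`,
#'   `d_aggregate` of the epoch's raster from the reference), `params`
#'   and `config`.
#' @examples
#' \donttest{
#' p <- lif_params(n = 10)
#' w_ref <- init_weights("naive-half-max", "reference", n = 10, seed = 1)
#' w_nai <- init_weights("naive-half-max", "naive", n = 10, seed = 2,
#'                       sign_mask = w_ref$sign_mask)
#' I <- generate_lif_inputs(300, 10, seed = 3)
#' R <- simulate_lif(w_ref, I, p)$spikes
#' fit <- run_pspm(R, w_nai, I, p, learning_config(epochs = 5, seed = 4))
#' tidy(fit)
#' }
#' @export
run_pspm <- function(reference, W_naive, I, params, cfg = learning_config()) {
  reference <- assert_raster(reference)
  stopifnot(identical(dim(reference), dim(I)))
  n <- ncol(reference)
  if (!identical(dim(as_weight(W_naive)), c(n, n))) {
    stop("`W_naive` dimensions must match the reference raster",
         call. = FALSE)
  }
  kernel <- gaussian_kernel()
  ref_times <- lapply(seq_len(n), function(i) which(reference[, i] == 1L))
  x <- sum(reference)
  sign_mask <- if (inherits(W_naive, "weight_matrix")) W_naive$sign_mask
               else rep("excitatory", n)
  exc <- sign_mask == "excitatory"
  # bare matrices inside the loop: per-update modifications stay in place
  # instead of copying the weight object once per unpaired spike
  W <- as_weight(W_naive)
  Wc <- W
  offdiag <- which(row(W) != col(W))
  history <- vector("list", cfg$epochs)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      O <- simulate_lif(W, I, params)$spikes
      y <- sum(O)
      obs_times <- lapply(seq_len(n), function(i) which(O[, i] == 1L))
      deltas <- vector("list", n)
      n_missing <- 0L
      n_extra <- 0L
      # pairings depend only on the epoch's fixed rasters, so computing
      # them neuron by neuron while weights change is order-independent
      for (i in seq_len(n)) {
        pr <- match_spikes(ref_times[[i]], obs_times[[i]],
                           a_cap = cfg$a_cap, strict = cfg$strict_pairing)
        miss <- ref_times[[i]][pr$unpaired_ref]
        extra <- obs_times[[i]][pr$unpaired_obs]
        n_missing <- n_missing + length(miss)
        n_extra <- n_extra + length(extra)
        if (!length(miss) && !length(extra)) next
        acc <- vector("list", length(miss) + length(extra))
        a <- 0L
        for (ev in seq_along(miss)) {
          d_i <- pool_deltas(O, i, miss[ev], +1, cfg, W, exc)
          if (length(d_i$delta)) {
            W[i, d_i$pool] <- d_i$w_new
            a <- a + 1L
            acc[[a]] <- d_i$delta
          }
        }
        for (ev in seq_along(extra)) {
          d_i <- pool_deltas(O, i, extra[ev], -1, cfg, W, exc)
          if (length(d_i$delta)) {
            W[i, d_i$pool] <- d_i$w_new
            a <- a + 1L
            acc[[a]] <- d_i$delta
          }
        }
        if (a > 0L) deltas[[i]] <- unlist(acc[seq_len(a)])
      }
      deltas <- unlist(deltas)
      if (is.null(deltas)) deltas <- numeric(0)
      # one homeostatic pass over every off-diagonal synapse
      W <- homeo_pass(W, x, y, cfg, exc)
      # control: identical deltas at uniformly random off-diagonal synapses,
      # then its own homeostatic draws from the same interval
      if (length(deltas)) {
        target <- sample(offdiag, length(deltas), replace = TRUE)
        add <- numeric(n * n)
        agg <- rowsum(deltas, target)
        add[as.integer(rownames(agg))] <- agg
        Wc <- clip_signs(Wc + matrix(add, n, n),
                         matrix(rep(exc, each = n), n, n))
      }
      Wc <- homeo_pass(Wc, x, y, cfg, exc)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, x = x, y = y,
        n_missing = n_missing, n_extra = n_extra,
        n_local_updates = length(deltas),
        local_update_magnitude = sum(abs(deltas)),
        d_pairwise = if (cfg$record_distances)
          pairwise_distance(O, reference, kernel) else NA_real_,
        d_aggregate = if (cfg$record_distances)
          aggregate_distance(O, reference, kernel) else NA_real_
      )
    }
  })
  meta_opt <- list(role = "optimized")
  meta_ctrl <- list(role = "control")
  W_opt <- weight_matrix(W, sign_mask, meta = meta_opt)
  W_ctrl <- weight_matrix(Wc, sign_mask, meta = meta_ctrl)
  structure(
    list(W_optimized = W_opt, W_control = W_ctrl, W_naive = W_naive,
         spikes_optimized = simulate_lif(W_opt, I, params)$spikes,
         spikes_control = simulate_lif(W_ctrl, I, params)$spikes,
         history = dplyr::bind_rows(history),
         params = params, config = cfg),
    class = "pspm_fit"
  )
}

# One local update event on the bare weight matrix: presynaptic pool of an
# unpaired spike at time t, signed Uniform[0, delta_max] draws, sign
# clipping. Mirrors local_updates() exactly (same draw order) but avoids
# the per-call copy of the weight object.
pool_deltas <- function(O, neuron, t, dir, cfg, W, exc) {
  window <- max(1L, t - cfg$z):t
  pool <- which(.colSums(O[window, , drop = FALSE],
                         length(window), ncol(O)) > 0)
  pool <- pool[pool != neuron]
  if (!length(pool)) {
    return(list(pool = integer(0), delta = numeric(0), w_new = numeric(0)))
  }
  delta <- dir * runif(length(pool), 0, cfg$delta_max)
  w_new <- clip_signs(W[neuron, pool] + delta, exc[pool])
  list(pool = pool, delta = delta, w_new = w_new)
}

# Homeostatic pass on a bare matrix; mirrors homeostatic_update().
homeo_pass <- function(W, x, y, cfg, exc) {
  if (x == y) return(W)
  n <- nrow(W)
  bound <- (x - y) * cfg$homeo_scale
  draws <- matrix(runif(n * n, min(0, bound), max(0, bound)), n, n)
  diag(draws) <- 0
  clip_signs(W + draws, matrix(rep(exc, each = n), n, n))
}

#' @export
print.pspm_fit <- function(x, ...) {
  cat(sprintf("<pspm_fit> %d neurons, %d epochs\n",
              nrow(x$W_optimized$W), x$config$epochs))
  if (nrow(x$history)) {
    first <- x$history[1, ]
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  unpaired spikes: %d -> %d; D_P: %s -> %s\n",
                first$n_missing + first$n_extra,
                last$n_missing + last$n_extra,
                format(first$d_pairwise, digits = 4),
                format(last$d_pairwise, digits = 4)))
  }
  invisible(x)
}

#' Tidy and glance methods for PSPM fits
#'
#' @param x A `pspm_fit`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training history tibble. `glance()`:
#'   a one-row summary with epoch count and final unpaired counts and
#'   distances.
#' @method tidy pspm_fit
#' @export
tidy.pspm_fit <- function(x, ...) x$history

#' @rdname tidy.pspm_fit
#' @method glance pspm_fit
#' @export
glance.pspm_fit <- function(x, ...) {
  if (!nrow(x$history)) {
    return(tibble::tibble(epochs = 0L, n_missing = NA_integer_,
                          n_extra = NA_integer_, d_pairwise = NA_real_,
                          d_aggregate = NA_real_))
  }
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = x$config$epochs,
                 n_missing = last$n_missing, n_extra = last$n_extra,
                 d_pairwise = last$d_pairwise,
                 d_aggregate = last$d_aggregate)
}
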