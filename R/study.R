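# Top-level experiment runners: the four-configuration LIF learning study
# and the PIF-to-LIF criticality transfer, both at configurable scale.

trial_metrics <- function(S, R, W, W_ref, kernel, bin_width = 3) {
  stats <- spike_count_stats(S)
  tibble::tibble(
    d_pairwise = pairwise_distance(S, R, kernel),
    d_aggregate = aggregate_distance(S, R, kernel),
    isi_l2 = isi_l2(S, R, bin_width),
    spike_mean = stats$mean,
    spike_variance = stats$variance,
    weight_error = weight_error(W, W_ref)
  )
}

#' Run the LIF learning study
#'
#' For each trial: draw a reference and a naive network from the named
#' initial weight configuration (sharing the inhibitory-neuron
#' assignment), generate one set of Gaussian input currents used by all
#' networks of the trial, simulate the reference raster, train with
#' [run_pspm()], and score the naive, optimized and control rasters
#' against the reference with every spike-train metric plus the weight
#' error. Trials are independent replicates: inputs and networks are
#' redrawn per trial from seeds derived from the master seed, so adding
#' trials never perturbs existing ones.
#'
#' The defaults reproduce the full-scale study design (400 neurons,
#' 150 epochs, 30 trials, 10,000 steps); pass smaller values for a
#' desk-scale run.
#'
#' @param config Initial weight configuration name (see [init_weights()]).
#' @param n Number of neurons.
#' @param t_steps Simulation length per trial, timesteps.
#' @param epochs Training epochs per trial.
#' @param trials Number of independent trials.
#' @param inhib_fraction Fraction of inhibitory neurons.
#' @param cfg A [learning_config()] supplying the learning
#'   hyper-parameters; its `epochs` and `seed` are overridden per trial.
#' @param seed Master seed.
#' @return A list of class `pspm_study`: `trials` (one row per trial and
#'   network, with distances, ISI l2, spike statistics and weight
#'   error), `aggregate` (mean and SD over trials per network and
#'   metric) and `config` (the run settings).
#' @examples
#' \donttest{
#' st <- run_lif_learning_study("naive-half-max", n = 10, t_steps = 200,
#'                              epochs = 3, trials = 2, seed = 1)
#' st$aggregate
#' }
#' @export
run_lif_learning_study <- function(config = "naive-half-max", n = 400,
                                   t_steps = 10000, epochs = 150,
                                   trials = 30, inhib_fraction = 0.2,
                                   cfg = learning_config(), seed = 1L) {
  params <- lif_params(n = n, inhib_fraction = inhib_fraction)
  kernel <- gaussian_kernel()
  rows <- vector("list", trials)
  for (tr in seq_len(trials)) {
    w_ref <- init_weights(config, "reference", n, inhib_fraction,
                          seed = derive_seed(seed, "trial", tr, "reference"))
    w_nai <- init_weights(config, "naive", n, inhib_fraction,
                          seed = derive_seed(seed, "trial", tr, "naive"),
                          sign_mask = w_ref$sign_mask)
    I <- generate_lif_inputs(t_steps, n,
                             seed = derive_seed(seed, "trial", tr, "inputs"))
    R <- simulate_lif(w_ref, I, params)$spikes
    N_raster <- simulate_lif(w_nai, I, params)$spikes
    cfg_tr <- cfg
    cfg_tr$epochs <- as.integer(epochs)
    cfg_tr$seed <- derive_seed(seed, "trial", tr, "learning")
    fit <- run_pspm(R, w_nai, I, params, cfg_tr)
    rows[[tr]] <- dplyr::bind_rows(
      dplyr::mutate(trial_metrics(N_raster, R, w_nai, w_ref, kernel),
                    trial = tr, network = "naive", .before = 1),
      dplyr::mutate(trial_metrics(fit$spikes_optimized, R, fit$W_optimized,
                                  w_ref, kernel),
                    trial = tr, network = "optimized", .before = 1),
      dplyr::mutate(trial_metrics(fit$spikes_control, R, fit$W_control,
                                  w_ref, kernel),
                    trial = tr, network = "control", .before = 1)
    )
  }
  trials_tbl <- dplyr::bind_rows(rows)
  aggregate <- trials_tbl |>
    tidyr::pivot_longer(-c("trial", "network"), names_to = "metric") |>
    dplyr::group_by(.data$network, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  structure(
    list(trials = trials_tbl, aggregate = aggregate,
         config = list(config = config, n = n, t_steps = t_steps,
                       epochs = epochs, trials = trials,
                       inhib_fraction = inhib_fraction, seed = seed)),
    class = "pspm_study"
  )
}

#' @export
print.pspm_study <- function(x, ...) {
  cat(sprintf("<pspm_study> %s, %d trials (N = %d, T = %d, %d epochs)\n",
              x$config$config, x$config$trials, x$config$n,
              x$config$t_steps, x$config$epochs))
  print(x$aggregate)
  invisible(x)
}

#' Run the PIF-to-LIF criticality transfer study
#'
#' Builds a critical PIF network (spectral radius 1), simulates it under
#' scaled Poisson drive to obtain a long critical reference raster, splits
#' the raster into consecutive segments, and trains one all-excitatory
#' naive LIF network (weights `Uniform[0, naive_w_max]` volts, Gaussian
#' input currents) per segment with [run_pspm()]. The naive, optimized
#' and control segment rasters are concatenated and all four rasters
#' (including the PIF reference) are scored with [criticality_report()].
#' Networks whose avalanche statistics cannot support a power-law fit
#' (too few or degenerate avalanches) are reported with `NA` entries
#' rather than failing the run.
#'
#' @param n Number of neurons.
#' @param p PIF connection probability.
#' @param w_range PIF weight interval before spectral rescaling.
#' @param t_total Total PIF simulation length, timesteps.
#' @param segments Number of equal segments used as training targets.
#' @param epochs Training epochs per segment.
#' @param naive_w_max Upper bound of the naive LIF weight magnitudes,
#'   volts.
#' @param percentile Avalanche threshold percentile.
#' @param cfg A [learning_config()]; `epochs` and `seed` are overridden
#'   per segment.
#' @param seed Master seed.
#' @return A list of class `pspm_criticality_study`: `reports` (named
#'   list of `criticality_report` or `NULL` per network), `summary`
#'   (one row per network with exponents, betas, gap and avalanche
#'   count) and `config`.
#' @examples
#' \donttest{
#' st <- run_pif_criticality_study(n = 40, t_total = 2000, segments = 2,
#'                                 epochs = 3, seed = 1)
#' st$summary
#' }
#' @export
run_pif_criticality_study <- function(n = 400, p = 0.1,
                                      w_range = c(0, 0.02),
                                      t_total = 50000, segments = 5,
                                      epochs = 150, naive_w_max = 1e-3,
                                      percentile = 20,
                                      cfg = learning_config(), seed = 1L) {
  stopifnot(t_total %% segments == 0)
  t_seg <- t_total %/% segments
  w_pif <- build_pif_network(n, p, w_range,
                             seed = derive_seed(seed, "pif-network"))
  I_pif <- generate_pif_inputs(t_total, n,
                               seed = derive_seed(seed, "pif-inputs"))
  R <- simulate_pif(w_pif, I_pif, seed = derive_seed(seed, "pif-sim"))
  params <- lif_params(n = n, inhib_fraction = 0)
  seg_naive <- seg_opt <- seg_ctrl <- vector("list", segments)
  for (k in seq_len(segments)) {
    rows <- ((k - 1) * t_seg + 1):(k * t_seg)
    R_seg <- R[rows, , drop = FALSE]
    w_nai <- with_seed(derive_seed(seed, "segment", k, "naive"), {
      W <- matrix(runif(n * n, 0, naive_w_max), n, n)
      diag(W) <- 0
      weight_matrix(W, rep("excitatory", n),
                    meta = list(role = "naive", segment = k))
    })
    I <- generate_lif_inputs(t_seg, n,
                             seed = derive_seed(seed, "segment", k, "inputs"))
    cfg_k <- cfg
    cfg_k$epochs <- as.integer(epochs)
    cfg_k$seed <- derive_seed(seed, "segment", k, "learning")
    fit <- run_pspm(R_seg, w_nai, I, params, cfg_k)
    seg_naive[[k]] <- simulate_lif(w_nai, I, params)$spikes
    seg_opt[[k]] <- fit$spikes_optimized
    seg_ctrl[[k]] <- fit$spikes_control
  }
  rasters <- list(
    reference = R,
    naive = do.call(rbind, seg_naive),
    optimized = do.call(rbind, seg_opt),
    control = do.call(rbind, seg_ctrl)
  )
  reports <- lapply(rasters, function(S) {
    tryCatch(criticality_report(S, percentile = percentile),
             error = function(e) NULL, warning = function(w) NULL)
  })
  summary <- dplyr::bind_rows(lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    if (is.null(rep)) {
      tibble::tibble(network = nm, tau = NA_real_, alpha = NA_real_,
                     beta_predicted = NA_real_, beta_observed = NA_real_,
                     abs_gap = NA_real_, n_avalanches = NA_integer_)
    } else {
      dplyr::mutate(glance(rep), network = nm, .before = 1)
    }
  }))
  structure(
    list(reports = reports, summary = summary, rasters = rasters,
         config = list(n = n, p = p, w_range = w_range, t_total = t_total,
                       segments = segments, epochs = epochs,
                       naive_w_max = naive_w_max, percentile = percentile,
                       seed = seed)),
    class = "pspm_criticality_study"
  )
}

#' @export
print.pspm_criticality_study <- function(x, ...) {
  cat(sprintf(
    "<pspm_criticality_study> N = %d, T = %d (%d segments, %d epochs)\n",
    x$config$n, x$config$t_total, x$config$segments, x$config$epochs))
  print(x$summary)
  invisible(x)
}
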