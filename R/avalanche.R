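#' Network-summed spiking activity
#'
#' `F(t) = sum_i s_i(t)`: the number of neurons spiking at each timestep.
#'
#' @param S A `T x N` binary raster.
#' @return Integer vector of length `T`.
#' @examples
#' summed_activity(diag(3L))
#' @export
summed_activity <- function(S) {
  S <- assert_raster(S)
  as.integer(rowSums(S))
}

#' Extract neuronal avalanches from a raster
#'
#' An avalanche is a maximal run of consecutive timesteps during which the
#' summed activity `F(t)` stays strictly above a percentile threshold of
#' all `T` summed-activity values (zeros included; linear-interpolation
#' quantile). Its duration is the run length and its size the total number
#' of spikes within the run. Runs truncated by the raster edge are kept by
#' default.
#'
#' @param S A `T x N` binary raster, or a precomputed summed-activity
#'   vector.
#' @param percentile Threshold percentile of the summed activity
#'   (default 20).
#' @param drop_truncated Drop avalanches that touch the first or last
#'   timestep (default `FALSE`).
#' @return A tibble of class `avalanche_set` with columns `start`
#'   (1-based timestep), `duration` (timesteps) and `size` (spikes),
#'   ordered and non-overlapping, with attribute `threshold`. A constant
#'   activity trace yields an empty set with a warning.
#' @examples
#' extract_avalanches(c(0, 0, 3, 5, 2, 0, 1, 0))
#' @export
extract_avalanches <- function(S, percentile = 20, drop_truncated = FALSE) {
  stopifnot(percentile >= 0, percentile <= 100)
  f <- if (is.matrix(S) || inherits(S, "pspm_sim")) summed_activity(S)
       else as.numeric(S)
  thr <- unname(quantile(f, percentile / 100, type = 7))
  above <- f > thr
  if (!any(above)) {
    if (all(f == f[1])) {
      warning("summed activity is constant: no avalanches can be extracted",
              call. = FALSE)
    }
    out <- tibble::tibble(start = integer(0), duration = integer(0),
                          size = numeric(0))
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]
    ends <- ends[keep]
    if (drop_truncated) {
      ok <- starts > 1L & ends < length(f)
      starts <- starts[ok]
      ends <- ends[ok]
    }
    out <- tibble::tibble(
      start = starts,
      duration = ends - starts + 1L,
      size = vapply(seq_along(starts),
                    function(i) sum(f[starts[i]:ends[i]]), numeric(1))
    )
  }
  structure(out, threshold = thr, percentile = percentile,
            class = c("avalanche_set", class(out)))
}

#' Predicted crackling-noise scaling exponent
#'
#' At criticality the mean avalanche size scales with duration as
#' `<S> ~ D^beta` with `beta = (alpha - 1) / (tau - 1)`, where `tau` and
#' `alpha` are the size- and duration-distribution exponents. (Both `tau`
#' and `alpha` enter as positive decay exponents; `beta` is reported as
#' the positive growth exponent, the standard convention.)
#'
#' @param tau Avalanche-size distribution exponent (`P(S) ~ S^-tau`),
#'   must exceed 1.
#' @param alpha Avalanche-duration distribution exponent
#'   (`P(D) ~ D^-alpha`).
#' @return `beta_p = (alpha - 1) / (tau - 1)`.
#' @examples
#' crackling_beta_predicted(1.242, 1.327) # 1.351
#' @export
crackling_beta_predicted <- function(tau, alpha) {
  stopifnot(tau > 1)
  (alpha - 1) / (tau - 1)
}

#' Observed crackling-noise scaling exponent
#'
#' For every observed avalanche duration `D`, compute the mean size
#' `<S>(D)`, then regress `log <S>` on `log D` by ordinary least squares;
#' the slope is `beta_o`. With `per_avalanche = TRUE` the regression is
#' instead run on individual `(D, S)` points.
#'
#' @param av An [extract_avalanches()] result (or any data frame with
#'   `duration` and `size` columns).
#' @param per_avalanche Regress per avalanche rather than per duration.
#' @return The fitted slope `beta_o`.
#' @examples
#' av <- tibble::tibble(duration = 1:10, size = (1:10)^1.5)
#' crackling_beta_observed(av) # exactly 1.5
#' @export
crackling_beta_observed <- function(av, per_avalanche = FALSE) {
  stopifnot(all(c("duration", "size") %in% names(av)))
  if (length(unique(av$duration)) < 2) {
    stop("at least two distinct avalanche durations are required",
         call. = FALSE)
  }
  if (per_avalanche) {
    d <- av$duration
    s <- av$size
  } else {
    agg <- dplyr::summarise(dplyr::group_by(av, .data$duration),
                            mean_size = mean(.data$size), .groups = "drop")
    d <- agg$duration
    s <- agg$mean_size
  }
  unname(coef(lm(log(s) ~ log(d)))[2])
}

#' Avalanche criticality report for a spike raster
#'
#' Composes the avalanche pipeline: extract avalanches, fit power laws to
#' sizes (`tau`) and durations (`alpha`) by discrete maximum likelihood,
#' predict `beta_p = (alpha - 1)/(tau - 1)` from the exponents, measure
#' `beta_o` by log-log regression of mean size on duration, and report the
#' gap `|beta_o - beta_p|`. A small gap together with power-law size and
#' duration statistics is the crackling-noise signature of criticality.
#'
#' @param S A `T x N` binary raster.
#' @param percentile Avalanche threshold percentile (default 20).
#' @param x_min Lower cutoff for both power-law fits (default 1).
#' @param method Power-law fitting method, `"mle"` (default) or
#'   `"regression"`; see [fit_power_law()].
#' @param min_samples Minimum number of avalanches required to fit.
#' @return A list of class `criticality_report`: `tau`, `alpha`,
#'   `beta_predicted`, `beta_observed`, `abs_gap`, `n_avalanches`, the
#'   two `power_law_fit` objects and the `avalanche_set`.
#' @examples
#' \donttest{
#' w <- build_pif_network(100, seed = 1)
#' S <- simulate_pif(w, generate_pif_inputs(5000, 100, seed = 2), seed = 3)
#' criticality_report(S)
#' }
#' @export
criticality_report <- function(S, percentile = 20, x_min = 1,
                               method = c("mle", "regression"),
                               min_samples = 50) {
  method <- match.arg(method)
  av <- extract_avalanches(S, percentile)
  size_fit <- fit_power_law(av$size, x_min = x_min, method = method,
                            min_samples = min_samples)
  dur_fit <- fit_power_law(av$duration, x_min = x_min, method = method,
                           min_samples = min_samples)
  tau <- size_fit$exponent
  alpha <- dur_fit$exponent
  beta_p <- crackling_beta_predicted(tau, alpha)
  beta_o <- crackling_beta_observed(av)
  structure(
    list(tau = tau, alpha = alpha,
         beta_predicted = beta_p, beta_observed = beta_o,
         abs_gap = abs(beta_o - beta_p),
         n_avalanches = nrow(av),
         size_fit = size_fit, duration_fit = dur_fit, avalanches = av),
    class = "criticality_report"
  )
}

#' @export
print.criticality_report <- function(x, ...) {
  cat("<criticality_report>",
      sprintf("  avalanches: %d (threshold %g)", x$n_avalanches,
              attr(x$avalanches, "threshold")),
      sprintf("  tau = %.3f, alpha = %.3f", x$tau, x$alpha),
      sprintf("  beta_p = %.3f, beta_o = %.3f, |beta_o - beta_p| = %.3f",
              x$beta_predicted, x$beta_observed, x$abs_gap),
      sep = "\n")
  invisible(x)
}

#' Tidy and glance methods for criticality reports
#'
#' @param x A `criticality_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted exponent (term, estimate,
#'   std.error). `glance()`: a one-row tibble with `tau`, `alpha`,
#'   `beta_predicted`, `beta_observed`, `abs_gap`, `n_avalanches`.
#' @method tidy criticality_report
#' @export
tidy.criticality_report <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "alpha", "beta_predicted", "beta_observed"),
    estimate = c(x$tau, x$alpha, x$beta_predicted, x$beta_observed),
    std.error = c(x$size_fit$std_error, x$duration_fit$std_error, NA, NA)
  )
}

#' @rdname tidy.criticality_report
#' @method glance criticality_report
#' @export
glance.criticality_report <- function(x, ...) {
  tibble::tibble(tau = x$tau, alpha = x$alpha,
                 beta_predicted = x$beta_predicted,
                 beta_observed = x$beta_observed,
                 abs_gap = x$abs_gap, n_avalanches = x$n_avalanches)
}
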