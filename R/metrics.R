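#' Truncated Gaussian smoothing kernel
#'
#' The kernel `K(t) = exp(-t^2 / (2 sigma^2))` evaluated on integer lags
#' `-radius : radius`. The default width `sigma = 5 * sqrt(2)` timesteps
#' (about 21 ms at a 3 ms step) gives temporal tolerance on both sides of
#' a spike; the symmetric window is what distinguishes this activity
#' signal from the causal exponential of the classic van Rossum metric.
#'
#' @param sigma Kernel standard deviation, timesteps.
#' @param radius Truncation half-width, timesteps; must be at least
#'   `4 * sigma` (default `ceiling(5 * sigma)`).
#' @return Numeric vector of length `2 * radius + 1` with attributes
#'   `sigma` and `radius`.
#' @examples
#' k <- gaussian_kernel()
#' k[attr(k, "radius") + 1] # peak value 1 at lag 0
#' @export
gaussian_kernel <- function(sigma = 5 * sqrt(2), radius = ceiling(5 * sigma)) {
  stopifnot(sigma > 0, radius >= 4 * sigma)
  lags <- -radius:radius
  structure(exp(-lags^2 / (2 * sigma^2)), sigma = sigma, radius = radius)
}

# Convolve a numeric time series with the symmetric kernel, zero-padded at
# the boundaries; returns a vector of the same length.
convolve_kernel <- function(x, kernel) {
  r <- attr(kernel, "radius")
  out <- convolve(x, kernel, type = "open")
  out[(r + 1):(r + length(x))]
}

#' Gaussian-filtered activity signal of a spike train
#'
#' Convolves a binary spike train with the truncated symmetric Gaussian
#' kernel; the result is a sum of unit-height Gaussians centred on the
#' spikes. Boundaries are zero-padded.
#'
#' @param s Binary spike train (0/1 vector), or a `T x N` raster whose
#'   columns are filtered independently (returning a `T x N` matrix).
#' @param kernel A [gaussian_kernel()].
#' @return Numeric vector (or matrix) of activity values.
#' @examples
#' s <- integer(100); s[50] <- 1L
#' a <- activity_signal(s)
#' a[50] # 1 at the spike
#' @export
activity_signal <- function(s, kernel = gaussian_kernel()) {
  if (is.matrix(s)) {
    s <- assert_raster(s)
    return(apply(s, 2, convolve_kernel, kernel = kernel))
  }
  stopifnot(all(s %in% c(0, 1)))
  convolve_kernel(as.numeric(s), kernel)
}

#' Pairwise activity-signal distance between two rasters
#'
#' Neuron-by-neuron integrated squared difference of activity signals:
#' \deqn{D_P(S, R) = \sum_{i=1}^N \sum_t \left[a(s_i, t) - a(r_i, t)\right]^2}
#' Integrals over time are unit-weight sums over timesteps, so the distance
#' is reported in timestep units.
#'
#' @param S,R `T x N` binary rasters with identical dimensions.
#' @param kernel A [gaussian_kernel()].
#' @return Nonnegative scalar; 0 iff the rasters are identical.
#' @examples
#' S <- matrix(0L, 50, 2); S[10, 1] <- 1L
#' pairwise_distance(S, S)
#' @export
pairwise_distance <- function(S, R, kernel = gaussian_kernel()) {
  S <- assert_raster(S)
  R <- assert_raster(R)
  assert_same_shape(S, R)
  total <- 0
  for (i in seq_len(ncol(S))) {
    if (identical(S[, i], R[, i])) next  # identical trains contribute 0
    d <- convolve_kernel(as.numeric(S[, i]) - as.numeric(R[, i]), kernel)
    total <- total + sum(d^2)
  }
  total
}

#' Aggregate activity-signal distance between two rasters
#'
#' Integrated squared difference of the network-summed activity signals:
#' \deqn{D_A(S, R) = \sum_t \left[A(S, t) - A(R, t)\right]^2, \quad
#'   A(S, t) = \sum_i a(s_i, t)}
#' Because neurons are summed before comparison, `D_A` is invariant under
#' any permutation of neuron identities within either raster.
#'
#' @inheritParams pairwise_distance
#' @return Nonnegative scalar.
#' @examples
#' S <- matrix(0L, 50, 2); S[10, 1] <- 1L
#' aggregate_distance(S, S[, 2:1]) # 0: label permutation
#' @export
aggregate_distance <- function(S, R, kernel = gaussian_kernel()) {
  S <- assert_raster(S)
  R <- assert_raster(R)
  if (nrow(S) != nrow(R)) {
    stop("rasters must share the same number of timesteps", call. = FALSE)
  }
  # linearity: A(S, t) = kernel * rowSums(S)
  d <- convolve_kernel(rowSums(S) - rowSums(R), kernel)
  sum(d^2)
}

#' Inter-spike intervals of a raster, concatenated network-wide
#'
#' For each neuron, the intervals (in timesteps) between consecutive
#' spikes; neurons with fewer than two spikes contribute none. Per-neuron
#' observations are concatenated into one network-wide set.
#'
#' @param S A `T x N` binary raster.
#' @return A tibble with columns `neuron` (1-based) and `interval`.
#' @examples
#' S <- matrix(0L, 10, 1); S[c(1, 6, 10), 1] <- 1L
#' isi_observations(S)$interval # 5 4
#' @export
isi_observations <- function(S) {
  S <- assert_raster(S)
  per <- lapply(seq_len(ncol(S)), function(i) diff(which(S[, i] == 1L)))
  tibble::tibble(
    neuron = rep(seq_along(per), lengths(per)),
    interval = as.integer(unlist(per, use.names = FALSE))
  )
}

#' l2 distance between inter-spike-interval histograms
#'
#' Bins the network-wide ISI observations of both rasters into shared
#' fixed-width bins (`(0, w], (w, 2w], ...` covering both observation
#' sets) and returns the Euclidean norm of the difference of the two
#' count vectors.
#'
#' @inheritParams pairwise_distance
#' @param bin_width Histogram bin width, timesteps (default 3, i.e. about
#'   9 ms at a 3 ms step).
#' @return Nonnegative scalar; 0 for identical interval multisets.
#' @examples
#' S <- matrix(0L, 20, 1); S[c(1, 5, 9), 1] <- 1L
#' isi_l2(S, S)
#' @export
isi_l2 <- function(S, R, bin_width = 3) {
  stopifnot(bin_width >= 1)
  a <- isi_observations(S)$interval
  b <- isi_observations(R)$interval
  if (!length(a) && !length(b)) return(0)
  nbins <- max(1, ceiling(max(a, b) / bin_width))
  ca <- tabulate(pmin(ceiling(a / bin_width), nbins), nbins)
  cb <- tabulate(pmin(ceiling(b / bin_width), nbins), nbins)
  sqrt(sum((ca - cb)^2))
}

#' Spike-count mean and variance over neurons
#'
#' Counts the spikes in each neuron's train and returns the mean and the
#' population variance (divide by `N`) of the counts.
#'
#' @param S A `T x N` binary raster.
#' @return A tibble with columns `mean` and `variance`.
#' @examples
#' S <- cbind(c(1L, 1L, 0L), c(1L, 1L, 1L))
#' spike_count_stats(S)
#' @export
spike_count_stats <- function(S) {
  S <- assert_raster(S)
  counts <- colSums(S)
  tibble::tibble(mean = mean(counts),
                 variance = mean((counts - mean(counts))^2))
}

#' Component-wise squared error between two weight matrices
#'
#' The squared Frobenius norm of the difference,
#' `sum((W_a - W_b)^2)`, in the squared units of the inputs.
#'
#' @param W_a,W_b Weight matrices ([weight_matrix()] or bare) of equal
#'   dimension.
#' @return Nonnegative scalar; 0 iff the matrices are identical.
#' @examples
#' weight_error(diag(c(1, 2)), matrix(0, 2, 2)) # 5
#' @export
weight_error <- function(W_a, W_b) {
  A <- as_weight(W_a)
  B <- as_weight(W_b)
  if (!identical(dim(A), dim(B))) {
    stop("weight matrices must have identical dimensions", call. = FALSE)
  }
  sum((A - B)^2)
}
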