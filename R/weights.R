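#' Construct a signed synaptic weight matrix
#'
#' `W[i, j]` is the strength (volts) of the synapse from presynaptic neuron
#' `j` onto postsynaptic neuron `i`. Dale's principle is enforced per
#' presynaptic neuron: every column of an inhibitory neuron is `<= 0`,
#' every column of an excitatory neuron is `>= 0`. Self-connections are
#' excluded (`W[i, i] = 0`).
#'
#' @param W Square numeric matrix, volts.
#' @param sign_mask Character vector, one of `"excitatory"` / `"inhibitory"`
#'   per neuron (column). Defaults to all excitatory.
#' @param meta Optional named list of provenance metadata (seed, config
#'   name, ...), carried through serialization.
#' @return An object of class `weight_matrix` with elements `W`,
#'   `sign_mask`, `units` and `meta`.
#' @examples
#' weight_matrix(matrix(c(0, 1, 2, 0), 2, 2) * 1e-3)
#' @export
weight_matrix <- function(W, sign_mask = NULL, meta = list()) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(is.finite(W)))
  n <- nrow(W)
  if (is.null(sign_mask)) sign_mask <- rep("excitatory", n)
  sign_mask <- match.arg(sign_mask, c("excitatory", "inhibitory"),
                         several.ok = TRUE)
  if (length(sign_mask) != n) {
    stop("`sign_mask` must have one entry per neuron", call. = FALSE)
  }
  if (any(diag(W) != 0)) {
    stop("self-connections are excluded: the diagonal of W must be 0",
         call. = FALSE)
  }
  exc <- sign_mask == "excitatory"
  if (any(W[, exc, drop = FALSE] < 0)) {
    stop("columns of excitatory neurons must be >= 0", call. = FALSE)
  }
  if (any(W[, !exc, drop = FALSE] > 0)) {
    stop("columns of inhibitory neurons must be <= 0", call. = FALSE)
  }
  structure(list(W = W, sign_mask = sign_mask, units = "V", meta = meta),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  n <- nrow(x$W)
  cat(sprintf("<weight_matrix> %d x %d synapses (V), %d inhibitory neurons\n",
              n, n, sum(x$sign_mask == "inhibitory")))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.weight_matrix <- function(x) dim(x$W)

#' Draw initial reference / naive weight matrices
#'
#' Weight magnitudes are drawn from one of four named configurations
#' (volts; the magnitudes below are quoted in mV):
#'
#' * `uniform`: `U[0, 5]` mV for both roles.
#' * `gaussian`: `N(mu = 0.4, sigma = 0.4)` mV for both roles, negative
#'   draws rejected and redrawn so magnitudes stay nonnegative.
#' * `sparse`: `U[0, 5]` mV for both roles; for the naive role, 50% of the
#'   entries (exactly `floor(n^2 / 2)` off-diagonal positions) are then
#'   set to 0.
#' * `naive-half-max`: reference `U[0, 5]` mV, naive `U[0, 2.5]` mV.
#'
#' A fraction `inhib_fraction` of neurons is designated inhibitory
#' (columns negated). Pass the reference network's `sign_mask` when
#' drawing the naive network so both share the inhibitory assignment.
#'
#' @param config One of `"uniform"`, `"gaussian"`, `"sparse"`,
#'   `"naive-half-max"`.
#' @param role `"reference"` or `"naive"`.
#' @param n Number of neurons.
#' @param inhib_fraction Fraction of inhibitory neurons.
#' @param seed Integer seed.
#' @param sign_mask Optional shared excitatory/inhibitory assignment.
#' @return A [weight_matrix()].
#' @examples
#' w_ref <- init_weights("naive-half-max", "reference", n = 20, seed = 1)
#' w_nai <- init_weights("naive-half-max", "naive", n = 20, seed = 2,
#'                       sign_mask = w_ref$sign_mask)
#' @export
init_weights <- function(config = c("uniform", "gaussian", "sparse",
                                    "naive-half-max"),
                         role = c("reference", "naive"),
                         n = 400, inhib_fraction = 0.2, seed = 1L,
                         sign_mask = NULL) {
  config <- match.arg(config)
  role <- match.arg(role)
  n <- as.integer(n)
  with_seed(seed, {
    mag <- switch(config,
      "uniform" = matrix(runif(n * n, 0, 5e-3), n, n),
      "gaussian" = matrix(rtruncnorm_nonneg(n * n, 0.4e-3, 0.4e-3), n, n),
      "sparse" = matrix(runif(n * n, 0, 5e-3), n, n),
      "naive-half-max" = {
        upper <- if (role == "naive") 2.5e-3 else 5e-3
        matrix(runif(n * n, 0, upper), n, n)
      }
    )
    if (config == "sparse" && role == "naive") {
      offdiag <- which(row(mag) != col(mag))
      zero_at <- sample(offdiag, min(length(offdiag), floor(n^2 / 2)))
      mag[zero_at] <- 0
    }
    if (is.null(sign_mask)) {
      inhib <- sample.int(n, floor(inhib_fraction * n))
      sign_mask <- rep("excitatory", n)
      sign_mask[inhib] <- "inhibitory"
    }
    mag[, sign_mask == "inhibitory"] <-
      -mag[, sign_mask == "inhibitory", drop = FALSE]
    diag(mag) <- 0
    weight_matrix(mag, sign_mask,
                  meta = list(config = config, role = role, seed = seed))
  })
}

# Nonnegative draws from N(mu, sd) by rejection (redraw, not clip), so the
# magnitude distribution remains proper.
rtruncnorm_nonneg <- function(n, mu, sd) {
  out <- rnorm(n, mu, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Rescale a nonnegative matrix to spectral radius one
#'
#' Divides `W` by the magnitude of its largest eigenvalue so the rescaled
#' matrix has spectral radius exactly 1, the critical point of the linear
#' branching approximation of the probabilistic integrate-and-fire network.
#'
#' @param W Square numeric matrix.
#' @return The rescaled matrix.
#' @examples
#' normalize_spectral_radius(matrix(c(0, .5, .5, 0), 2, 2))
#' @export
normalize_spectral_radius <- function(W) {
  W <- as_weight(W)
  lambda <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (lambda == 0) {
    stop("spectral radius is zero: the matrix cannot be normalized",
         call. = FALSE)
  }
  W / lambda
}

#' Build a critical probabilistic integrate-and-fire network
#'
#' Synapses are created independently with probability `p` (excluding
#' self-connections); created weights are drawn from `Uniform(w_range)` and
#' the whole matrix is rescaled to spectral radius 1 via
#' [normalize_spectral_radius()], placing the network at criticality.
#' All synapses are excitatory (dimensionless, nonnegative weights).
#'
#' @param n Number of neurons.
#' @param p Connection probability in `(0, 1]`.
#' @param w_range Nonnegative weight interval, default `c(0, 0.02)`.
#' @param seed Integer seed.
#' @param max_tries Resampling attempts should a draw come out all-zero.
#' @return A [weight_matrix()] with all-excitatory sign mask and metadata
#'   recording `p`, `w_range`, `seed` and the normalizing eigenvalue.
#' @examples
#' w <- build_pif_network(50, p = 0.1, seed = 1)
#' max(Mod(eigen(w$W, only.values = TRUE)$values)) # 1
#' @export
build_pif_network <- function(n, p = 0.1, w_range = c(0, 0.02), seed = 1L,
                              max_tries = 100L) {
  stopifnot(p > 0, p <= 1, length(w_range) == 2,
            all(w_range >= 0), diff(w_range) > 0)
  n <- as.integer(n)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      mask <- matrix(runif(n * n) < p, n, n)
      diag(mask) <- FALSE
      W <- matrix(0, n, n)
      W[mask] <- runif(sum(mask), w_range[1], w_range[2])
      lambda <- max(Mod(eigen(W, only.values = TRUE)$values))
      if (lambda > 0) {
        return(weight_matrix(W / lambda, rep("excitatory", n),
                             meta = list(p = p, w_range = w_range,
                                         seed = seed, lambda = lambda)))
      }
    }
    stop("failed to draw a network with nonzero spectral radius", call. = FALSE)
  })
}
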