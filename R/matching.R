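#' Absolute temporal distance between two spike times
#'
#' @param t_ref,t_obs Spike timesteps.
#' @return `|t_ref - t_obs|`.
#' @examples
#' temporal_distance(10, 12)
#' @export
temporal_distance <- function(t_ref, t_obs) abs(t_ref - t_obs)

#' Build the spike-pairing cost matrix
#'
#' Dynamic program over monotone pairings of two single-neuron spike
#' trains. `L[k+1, l+1]` is the minimum cost of optimally pairing the first
#' `k` reference spikes with the first `l` observed spikes, where pairing
#' spikes `k` and `l` costs their temporal distance and leaving a spike
#' unpaired costs `a_cap`:
#' \deqn{\Lambda_{k,l} = \min\{\Lambda_{k-1,l-1} + d_{k,l},\;
#'   \Lambda_{k-1,l} + a_{cap},\; \Lambda_{k,l-1} + a_{cap},\;
#'   \Lambda_{k-1,l-1} + 2a_{cap}\}}
#' with base cases \eqn{\Lambda_{0,l} = l\,a_{cap}} and
#' \eqn{\Lambda_{k,0} = k\,a_{cap}}. The fourth branch (leave both
#' unpaired) is retained verbatim even though it is dominated by
#' compositions of the two skip branches.
#'
#' Note the recursion as written will pair spikes up to `2 * a_cap` apart,
#' since one pairing at distance `d < 2 a_cap` beats two unpaired
#' penalties; see the `strict` option of [match_spikes()] for the stricter
#' reading.
#'
#' @param ref,obs Strictly increasing integer spike times (possibly empty).
#' @param a_cap Unpaired-spike penalty, timesteps (default 15, roughly
#'   45 ms at a 3 ms step).
#' @return An `(n+1) x (m+1)` matrix of class `cost_matrix` with
#'   attribute `a_cap`.
#' @examples
#' build_cost_matrix(c(10, 50), c(12, 200))
#' @export
build_cost_matrix <- function(ref, obs, a_cap = 15) {
  stopifnot(a_cap > 0)
  check_spike_times(ref)
  check_spike_times(obs)
  n <- length(ref)
  m <- length(obs)
  L <- matrix(0, n + 1, m + 1)
  L[1, ] <- (0:m) * a_cap
  L[, 1] <- (0:n) * a_cap
  if (n > 0 && m > 0) {
    # wavefront evaluation: all cells with k + l = d depend only on the two
    # previous anti-diagonals, so each diagonal fills as one vector op
    lin <- function(k, l) k + 1L + (n + 1L) * l # matrix[(k+1), (l+1)]
    for (dg in 2:(n + m)) {
      ks <- max(1L, dg - m):min(n, dg - 1L)
      ls <- dg - ks
      dkl <- abs(ref[ks] - obs[ls])
      diag_ <- L[lin(ks - 1L, ls - 1L)]
      L[lin(ks, ls)] <- pmin(diag_ + dkl,
                             L[lin(ks - 1L, ls)] + a_cap,
                             L[lin(ks, ls - 1L)] + a_cap,
                             diag_ + 2 * a_cap)
    }
  }
  structure(L, a_cap = a_cap, class = c("cost_matrix", "matrix"))
}

check_spike_times <- function(x) {
  if (length(x) == 0) return(invisible(x))
  if (any(x < 0) || is.unsorted(x, strictly = TRUE)) {
    stop("spike times must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  invisible(x)
}

#' Backtrack an optimal spike pairing from the cost matrix
#'
#' Walks from `[n, m]` back to a base case, at each cell moving along the
#' branch that attains the recursion minimum. Ties are broken with fixed
#' precedence pair > skip-ref > skip-obs > skip-both; all tied choices are
#' cost-equivalent by construction, so fixing one order simply makes the
#' output bit-reproducible.
#'
#' @param L A [build_cost_matrix()] result.
#' @param ref,obs The spike trains the matrix was built from.
#' @return A list of class `spike_pairing`: `pairs` (two-column matrix of
#'   1-based ref/obs indices, non-crossing), `unpaired_ref`,
#'   `unpaired_obs` (integer index vectors) and `total_cost`
#'   (`= L[n+1, m+1]`).
#' @examples
#' L <- build_cost_matrix(c(10, 50), c(12, 200))
#' backtrack_pairs(L, c(10, 50), c(12, 200))
#' @export
backtrack_pairs <- function(L, ref, obs) {
  a_cap <- attr(L, "a_cap")
  n <- length(ref)
  m <- length(obs)
  stopifnot(identical(dim(L), as.integer(c(n + 1, m + 1))))
  k <- n
  l <- m
  acc <- vector("list", min(n, m))
  np <- 0L
  while (k > 0 && l > 0) {
    cur <- L[k + 1, l + 1]
    d <- abs(ref[k] - obs[l])
    if (cur == L[k, l] + d) {
      np <- np + 1L
      acc[[np]] <- c(k, l)
      k <- k - 1
      l <- l - 1
    } else if (cur == L[k, l + 1] + a_cap) {
      k <- k - 1
    } else if (cur == L[k + 1, l] + a_cap) {
      l <- l - 1
    } else {
      k <- k - 1
      l <- l - 1
    }
  }
  pairs <- if (np > 0) {
    do.call(rbind, rev(acc[seq_len(np)]))
  } else {
    matrix(integer(0), 0, 2)
  }
  dimnames(pairs) <- list(NULL, c("ref", "obs"))
  structure(
    list(pairs = pairs,
         unpaired_ref = setdiff(seq_len(n), pairs[, 1]),
         unpaired_obs = setdiff(seq_len(m), pairs[, 2]),
         total_cost = L[n + 1, m + 1]),
    class = "spike_pairing"
  )
}

#' Optimally pair two single-neuron spike trains
#'
#' Convenience wrapper: builds the cost matrix and backtracks the optimal
#' pairing in one call.
#'
#' @inheritParams build_cost_matrix
#' @param strict If `TRUE`, pairs whose temporal distance exceeds `a_cap`
#'   are post-filtered: both spikes become unpaired and the total cost is
#'   recomputed accordingly. Off by default; the literal recursion governs.
#' @return A `spike_pairing` (see [backtrack_pairs()]).
#' @examples
#' match_spikes(c(10, 50), c(12, 200))
#' @export
match_spikes <- function(ref, obs, a_cap = 15, strict = FALSE) {
  L <- build_cost_matrix(ref, obs, a_cap)
  p <- backtrack_pairs(L, ref, obs)
  if (strict && nrow(p$pairs)) {
    d <- abs(ref[p$pairs[, 1]] - obs[p$pairs[, 2]])
    drop <- d > a_cap
    if (any(drop)) {
      p$unpaired_ref <- sort(as.integer(c(p$unpaired_ref,
                                          unname(p$pairs[drop, 1]))))
      p$unpaired_obs <- sort(as.integer(c(p$unpaired_obs,
                                          unname(p$pairs[drop, 2]))))
      p$pairs <- p$pairs[!drop, , drop = FALSE]
      p$total_cost <- sum(d[!drop]) +
        a_cap * (length(p$unpaired_ref) + length(p$unpaired_obs))
    }
  }
  p
}

#' @export
print.spike_pairing <- function(x, ...) {
  cat(sprintf(
    "<spike_pairing> %d pairs, %d unpaired ref, %d unpaired obs, cost %g\n",
    nrow(x$pairs), length(x$unpaired_ref), length(x$unpaired_obs),
    x$total_cost))
  invisible(x)
}

#' Tidy a spike pairing into a tibble of matched index pairs
#'
#' @param x A `spike_pairing`.
#' @param ... Unused.
#' @return A tibble with columns `ref` and `obs` (1-based spike indices).
#' @method tidy spike_pairing
#' @export
tidy.spike_pairing <- function(x, ...) {
  tibble::tibble(ref = as.integer(x$pairs[, 1]),
                 obs = as.integer(x$pairs[, 2]))
}
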