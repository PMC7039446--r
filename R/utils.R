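# Internal helpers: seed handling, argument checks.

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Experiment runners spawn many independent random streams (one per trial,
#' per network role, per segment). Each stream's seed is derived from the
#' master seed and a stable label via a small multiplicative string hash, so
#' that adding trials or reordering calls never perturbs existing streams.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels identifying the stream.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' derive_seed(1, "trial", 3, "reference")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  label <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                        character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

assert_raster <- function(S, arg = deparse(substitute(S))) {
  if (inherits(S, "pspm_sim")) S <- S$spikes
  if (!is.matrix(S)) {
    stop(sprintf("`%s` must be a T x N binary matrix", arg), call. = FALSE)
  }
  if (!all(S %in% c(0L, 1L))) {
    stop(sprintf("`%s` must contain only 0/1 entries", arg), call. = FALSE)
  }
  storage.mode(S) <- "integer"
  S
}

assert_same_shape <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    stop("spike rasters must have identical dimensions", call. = FALSE)
  }
  invisible(TRUE)
}

# Coerce a weight_matrix object or plain matrix to the bare numeric matrix.
as_weight <- function(W) {
  if (inherits(W, "weight_matrix")) W$W else W
}
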