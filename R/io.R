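# Plain-text file formats: spike-event TSV rasters and TSV weight matrices
# with a JSON metadata sidecar.

#' Read and write spike rasters as spike-event TSV
#'
#' The format is line-oriented text: a first comment line
#' `# raster T=<steps> N=<neurons>` carrying the raster dimensions (so
#' empty rasters round-trip), a header `timestep\tneuron_id`, then one row
#' per spike with 0-based timestep and neuron id. Round-trips losslessly.
#'
#' @param S A `T x N` binary raster (for writing).
#' @param path File path.
#' @return `write_raster()` returns `path` invisibly; `read_raster()`
#'   returns the `T x N` integer raster.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' S <- matrix(0L, 5, 2); S[3, 1] <- 1L
#' write_raster(S, f)
#' identical(read_raster(f), S)
#' @export
write_raster <- function(S, path) {
  S <- assert_raster(S)
  idx <- which(S == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- c(
    sprintf("# raster T=%d N=%d", nrow(S), ncol(S)),
    "timestep\tneuron_id",
    sprintf("%d\t%d", idx[, 1] - 1L, idx[, 2] - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# raster T=\\d+ N=\\d+$", lines[1])) {
    stop("line 1: expected header '# raster T=<steps> N=<neurons>'",
         call. = FALSE)
  }
  dims <- as.integer(regmatches(lines[1], gregexpr("\\d+", lines[1]))[[1]])
  S <- matrix(0L, dims[1], dims[2])
  if (length(lines) >= 2 && lines[2] != "timestep\tneuron_id") {
    stop("line 2: expected column header 'timestep\\tneuron_id'",
         call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  for (k in seq_along(body)) {
    fields <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.integer(fields))
    if (length(vals) != 2 || anyNA(vals) ||
        vals[1] < 0 || vals[1] >= dims[1] ||
        vals[2] < 0 || vals[2] >= dims[2]) {
      stop(sprintf("line %d: malformed spike event '%s'", k + 2L, body[k]),
           call. = FALSE)
    }
    S[vals[1] + 1L, vals[2] + 1L] <- 1L
  }
  S
}

#' Read and write weight matrices as TSV with a JSON sidecar
#'
#' The matrix itself is written as a dense tab-separated table of numbers
#' (volts); a sidecar at `<path>.json` records the neuron count, units,
#' excitatory/inhibitory sign mask and any metadata carried by the object
#' (seed, configuration name, ...). Round-trips losslessly to the
#' precision of the decimal representation (17 significant digits).
#'
#' @param W A [weight_matrix()] (for writing).
#' @param path File path for the TSV; the sidecar is `<path>.json`.
#' @return `write_weights()` returns `path` invisibly; `read_weights()`
#'   returns the [weight_matrix()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' W <- init_weights("uniform", "reference", n = 4, seed = 1)
#' write_weights(W, f)
#' all.equal(read_weights(f)$W, W$W)
#' @export
write_weights <- function(W, path) {
  stopifnot(inherits(W, "weight_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(W$W, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(n = nrow(W$W), units = W$units, sign_mask = W$sign_mask,
         meta = W$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  W <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(W) <- NULL
  if (!identical(dim(W), as.integer(c(sidecar$n, sidecar$n)))) {
    stop("weight matrix dimensions disagree with the JSON sidecar",
         call. = FALSE)
  }
  meta <- as.list(sidecar$meta)
  weight_matrix(W, sidecar$sign_mask, meta = meta)
}
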