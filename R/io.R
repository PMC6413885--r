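# Movie input/output: multi-page TIFF per channel plus a plain-text
# sidecar carrying physical metadata and the (invertible) intensity
# scaling used to fit pixel data into TIFF range.

#' Write a wave movie as multi-page TIFFs
#'
#' One multi-page TIFF per channel (one page per frame), intensities
#' min-max scaled into [0, 1]; the scaling constants, pixel size and
#' frame interval go into `<basename>_metadata.txt` so reading back is
#' exact up to TIFF float precision.
#'
#' @param movie a [WaveMovie-class].
#' @param dir output directory (created if needed).
#' @param basename file-name stem.
#' @return character vector of the files written, invisibly.
#' @export
writeWaveMovie <- function(movie, dir, basename = "movie") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(movie@pixels)
  files <- character(0)
  meta <- c(sprintf("pixel_size = %.17g", movie@pixel_size),
            sprintf("frame_interval = %.17g", movie@frame_interval),
            sprintf("n_frames = %d", d[3L]))
  for (k in seq_len(d[4L])) {
    ch <- movie@pixels[, , , k, drop = FALSE]
    lo <- min(ch); hi <- max(ch)
    span <- max(hi - lo, .Machine$double.eps)
    pages <- lapply(seq_len(d[3L]), function(i)
      (movie@pixels[, , i, k] - lo) / span)
    f <- file.path(dir, sprintf("%s_%s.tif", basename, movie@channels[k]))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L)
    files <- c(files, f)
    meta <- c(meta,
              sprintf("channel_%d = %s", k, movie@channels[k]),
              sprintf("scale_lo_%d = %.17g", k, lo),
              sprintf("scale_hi_%d = %.17g", k, hi))
  }
  mf <- file.path(dir, sprintf("%s_metadata.txt", basename))
  writeLines(meta, mf)
  invisible(c(files, mf))
}

#' Read a wave movie written by [writeWaveMovie()]
#'
#' @param dir directory containing the TIFFs and metadata sidecar.
#' @param basename file-name stem used when writing.
#' @return a [WaveMovie-class] with original intensities restored.
#' @export
readWaveMovie <- function(dir, basename = "movie") {
  mf <- file.path(dir, sprintf("%s_metadata.txt", basename))
  if (!file.exists(mf)) stop("metadata sidecar not found: ", mf)
  kv <- strsplit(trimws(readLines(mf)), " = ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  g <- function(k) vals[match(k, keys)]
  chan_keys <- keys[grepl("^channel_", keys)]
  channels <- vals[match(chan_keys, keys)]
  nch <- length(channels)
  px <- NULL
  for (k in seq_len(nch)) {
    f <- file.path(dir, sprintf("%s_%s.tif", basename, channels[k]))
    pages <- tiff::readTIFF(f, all = TRUE)
    lo <- as.numeric(g(sprintf("scale_lo_%d", k)))
    hi <- as.numeric(g(sprintf("scale_hi_%d", k)))
    if (is.null(px))
      px <- array(0, c(dim(pages[[1L]])[1:2], length(pages), nch))
    for (i in seq_along(pages)) {
      pg <- pages[[i]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
      px[, , i, k] <- pg * max(hi - lo, .Machine$double.eps) + lo
    }
  }
  new("WaveMovie", pixels = px,
      pixel_size = as.numeric(g("pixel_size")),
      frame_interval = as.numeric(g("frame_interval")),
      channels = channels)
}

#' Write a kymograph as a delimited table
#'
#' @param kymo space-by-time matrix.
#' @param path output file (tab-separated, rows = space).
#' @return `path`, invisibly.
#' @export
writeKymograph <- function(kymo, path) {
  utils::write.table(kymo, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a run manifest for provenance
#'
#' Records the full parameter configuration, grid, seed and package
#' version of a simulation run.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(traj, path) {
  tmp <- tempfile()
  writeModelConfig(traj@params, tmp)
  cfg <- readLines(tmp)
  unlink(tmp)
  writeLines(c(
    sprintf("# stencen %s run manifest",
            as.character(utils::packageVersion("stencen"))),
    sprintf("grid = %s", paste(traj@grid@shape, collapse = "x")),
    sprintf("spacing = %.17g", traj@grid@spacing),
    sprintf("boundary = %s", traj@grid@boundary),
    sprintf("seed = %d", traj@seed),
    sprintf("n_frames = %d", length(traj@frames)),
    sprintf("t_max = %.17g", max(traj@times)),
    "", cfg), path)
  invisible(path)
}

setMethod("show", "WaveMovie", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("WaveMovie: %d x %d px, %d frames, %d channel(s) [%s]\n",
              d[1L], d[2L], d[3L], d[4L],
              paste(object@channels, collapse = ", ")))
  cat(sprintf("  pixel_size %.3g, frame_interval %.3g\n",
              object@pixel_size, object@frame_interval))
})
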