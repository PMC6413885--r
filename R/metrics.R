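# Quantification of wave movies: the same estimators are applied to
# simulated readouts and to synthetic microscopy.

#' Moving-average smoothing of a line profile
#'
#' Centred moving average of odd length (default 19 pixels, the
#' biosensor peak-distance convention).  Near the edges the window
#' shrinks symmetrically so the filter stays centred and unbiased for
#' locally linear signals.
#'
#' @param signal numeric vector of intensities.
#' @param window odd window length in pixels, `<= length(signal)`.
#' @return smoothed vector of the same length.
#' @examples
#' smoothProfile(rep(2, 40))        # constant stays constant
#' @export
smoothProfile <- function(signal, window = 19L) {
  n <- length(signal)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L || window > n)
    stop("'window' must be odd, >= 1 and <= length(signal)")
  half <- window %/% 2L
  cs <- cumsum(c(0, signal))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

#' Signed distance between two channels' intensity peaks
#'
#' Both profiles are smoothed ([smoothProfile()], window 19 by
#' default), the location of each maximum is taken (ties broken toward
#' the first index), and the distance is
#' `direction * (argmax_a - argmax_b) * pixel_size`.  With
#' `direction = +1` along the propagation axis, a positive value means
#' channel A's peak precedes channel B's.
#'
#' @param ch_a,ch_b equal-length intensity profiles.
#' @param pixel_size length per pixel.
#' @param direction +1 or -1, the propagation sign convention.
#' @param window smoothing window.
#' @return signed distance (length units).
#' @examples
#' a <- dnorm(1:100, 50, 5); b <- dnorm(1:100, 45, 5)
#' peakDistance(a, b, pixel_size = 0.5)   # +2.5
#' @export
peakDistance <- function(ch_a, ch_b, pixel_size = 1, direction = 1,
                         window = 19L) {
  if (length(ch_a) != length(ch_b)) stop("profiles must have equal length")
  stopifnot(direction %in% c(-1, 1))
  sa <- smoothProfile(ch_a, window)
  sb <- smoothProfile(ch_b, window)
  if (diff(range(sa)) < 1e-12 || diff(range(sb)) < 1e-12)
    warning("flat profile: peak location falls back to the first index")
  direction * (which.max(sa) - which.max(sb)) * pixel_size
}

# 8-connected labelling: 4-connected bwlabel plus union-find over
# diagonally adjacent label pairs.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl < 2L) return(lab)
  pairs <- NULL
  nr <- nrow(lab); nc <- ncol(lab)
  for (dy in c(-1L, 1L)) {
    a <- lab[if (dy == 1L) -nr else -1L, -nc, drop = FALSE]
    b <- lab[if (dy == 1L) -1L else -nr, -1L, drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment wave fronts in a single frame
#'
#' Thresholds at `mean + k * sd` of the frame intensities, removes
#' objects smaller than `min_size` pixels, and labels 8-connected
#' components.
#'
#' @param frame numeric matrix.
#' @param k threshold stringency in standard deviations (default 1).
#' @param min_size minimum object size in pixels (default 9).
#' @return integer label matrix (0 = background); may be all zero.
#' @export
segmentWavefronts <- function(frame, k = 1, min_size = 9L) {
  if (any(!is.finite(frame))) stop("frame must be finite")
  thr <- mean(frame) + k * stats::sd(frame)
  mask <- frame > thr
  if (!any(mask)) return(matrix(0L, nrow(frame), ncol(frame)))
  lab <- .label8(mask * 1)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_size)
  if (!length(keep)) return(matrix(0L, nrow(frame), ncol(frame)))
  out <- match(lab, keep)
  out[is.na(out)] <- 0L
  matrix(as.integer(out), nrow(frame), ncol(frame))
}

# boundary pixels of a labelled/binary mask: object pixels with a
# background 4-neighbour.  The image border replicates (an object
# running out of the field of view is not a front there).
.mask_edges <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  nb <- m[pad(seq_len(nr) - 1L, nr), ] & m[pad(seq_len(nr) + 1L, nr), ] &
    m[, pad(seq_len(nc) - 1L, nc)] & m[, pad(seq_len(nc) + 1L, nc)]
  m & !nb
}

#' Per-frame patch statistics from labelled masks
#'
#' @param masks list of integer label matrices (one per frame).
#' @param pixel_size length per pixel (areas scale with its square).
#' @return list with `count` (patches per frame), `mean_area` (per
#'   frame, `NaN` where empty) and video averages `mean_count`,
#'   `mean_patch_area`.
#' @export
patchStats <- function(masks, pixel_size = 1) {
  stopifnot(length(masks) >= 1L)
  count <- vapply(masks, function(m) length(setdiff(unique(as.vector(m)), 0L)),
                  numeric(1))
  mean_area <- vapply(masks, function(m) {
    a <- tabulate(m[m > 0])
    a <- a[a > 0]
    if (length(a)) mean(a) * pixel_size^2 else NaN
  }, numeric(1))
  list(count = count, mean_area = mean_area,
       mean_count = mean(count),
       mean_patch_area = mean(mean_area, na.rm = TRUE))
}

#' Wave-front speed from frame-to-frame edge displacement
#'
#' Wave fronts are segmented per frame; for each pixel on the boundary
#' of a front in frame n+1 the distance to the closest edge of a front
#' in frame n is read off a distance transform.  Displacements outside
#' `[low, high]` (length units, defaults 0.1 and 5) are discarded as
#' not representing motion of the same front.  The per-frame mean of
#' the kept displacements divided by the frame interval is the wave
#' speed; `fraction_fastest` is the fraction of kept pixels, over the
#' whole video, whose displacement exceeds the video mean by at least
#' one standard deviation.
#'
#' @param movie a [WaveMovie-class].
#' @param channel channel index to analyse.
#' @param low,high displacement acceptance band (length units).
#' @param k,min_size segmentation parameters, see [segmentWavefronts()].
#' @return a [SpeedReport-class].
#' @export
waveSpeed <- function(movie, channel = 1L, low = 0.1, high = 5,
                      k = 1, min_size = 9L) {
  px <- movie@pixels
  nt <- dim(px)[3L]
  if (nt < 2L) stop("need at least 2 frames")
  masks <- lapply(seq_len(nt), function(i)
    segmentWavefronts(px[, , i, channel], k = k, min_size = min_size))
  ps <- patchStats(masks, movie@pixel_size)
  disp <- vector("list", nt - 1L)
  for (i in seq_len(nt - 1L)) {
    e_prev <- .mask_edges(masks[[i]])
    e_next <- .mask_edges(masks[[i + 1L]])
    if (!any(e_prev) || !any(e_next)) { disp[[i]] <- numeric(0); next }
    dmap <- EBImage::distmap(1 - e_prev) * movie@pixel_size
    d <- dmap[e_next]
    disp[[i]] <- d[d >= low & d <= high]
  }
  all_d <- unlist(disp)
  mean_speed <- vapply(disp, function(d)
    if (length(d)) mean(d) / movie@frame_interval else 0, numeric(1))
  accepted <- vapply(disp, length, numeric(1))
  ff <- if (length(all_d) >= 2L) {
    mu <- mean(all_d); s <- stats::sd(all_d)
    mean(all_d >= mu + s)
  } else 0
  new("SpeedReport", mean_speed = mean_speed, accepted_count = accepted,
      fraction_fastest = ff, patch_count = ps$count,
      mean_patch_area = ps$mean_area,
      video_mean_speed = if (length(all_d))
        mean(all_d) / movie@frame_interval else 0)
}

setMethod("show", "SpeedReport", function(object) {
  cat(sprintf("SpeedReport: %d frame pairs, video mean speed %.4g\n",
              length(object@mean_speed), object@video_mean_speed))
  cat(sprintf("  fraction_fastest %.3f; mean patch count %.1f; mean patch area %.4g\n",
              object@fraction_fastest, mean(object@patch_count),
              mean(object@mean_patch_area, na.rm = TRUE)))
})

#' Paired before/after speed reports around an event
#'
#' Averages are computed over 30 frames ending at the event, then 30
#' frames are allowed to elapse for the perturbation to take effect,
#' and a further 30 frames are analysed: the windows are
#' `[event - 30, event)` and `[event + 30, event + 60)`.
#'
#' @param movie a [WaveMovie-class].
#' @param event_frame 1-based frame index of the perturbation event.
#' @param window frames per analysis window (default 30).
#' @param gap frames skipped after the event (default `window`).
#' @param ... passed to [waveSpeed()].
#' @return list with elements `before` and `after`
#'   ([SpeedReport-class]s).
#' @export
beforeAfterReport <- function(movie, event_frame, window = 30L,
                              gap = window, ...) {
  nt <- dim(movie@pixels)[3L]
  if (event_frame < window + 1L || nt < event_frame + gap + window)
    stop(sprintf(
      "insufficient frames: need %d before the event and %d after",
      window, gap + window))
  sub <- function(idx) new("WaveMovie",
                           pixels = movie@pixels[, , idx, , drop = FALSE],
                           pixel_size = movie@pixel_size,
                           frame_interval = movie@frame_interval,
                           channels = movie@channels)
  list(before = waveSpeed(sub(seq(event_frame - window, event_frame - 1L)), ...),
       after = waveSpeed(sub(seq(event_frame + gap,
                                 event_frame + gap + window - 1L)), ...))
}

# centroids and areas of labelled components
.centroids <- function(lab) {
  ix <- which(lab > 0, arr.ind = TRUE)
  if (!nrow(ix)) return(data.frame(label = integer(0), y = numeric(0),
                                   x = numeric(0), area = numeric(0)))
  l <- lab[lab > 0]
  data.frame(label = sort(unique(l)),
             y = tapply(ix[, 1L], l, mean),
             x = tapply(ix[, 2L], l, mean),
             area = tapply(ix[, 1L], l, length))
}

#' Lifetimes of short-lived puncta
#'
#' Detects small bright objects (segmented area between `size_range`
#' pixels), links them across frames by nearest-centroid matching
#' within `link_dist` pixels, and reports each track's lifetime
#' `(last - first + 1) * frame_interval`.
#'
#' @param movie a [WaveMovie-class].
#' @param channel channel to analyse.
#' @param size_range accepted object area in pixels (default 4--100).
#' @param link_dist maximum centroid displacement per frame (pixels).
#' @param k,min_size segmentation parameters; `min_size` defaults to
#'   the lower end of `size_range`.
#' @param drop_censored drop tracks present in the first or last frame,
#'   whose true lifetime is right- or left-censored (default TRUE).
#' @return numeric vector of lifetimes (time units), one per track.
#' @export
punctaLifetime <- function(movie, channel = 1L, size_range = c(4L, 100L),
                           link_dist = 2, k = 1, min_size = size_range[1L],
                           drop_censored = TRUE) {
  px <- movie@pixels
  nt <- dim(px)[3L]
  if (nt < 2L) stop("need at least 2 frames")
  dets <- lapply(seq_len(nt), function(i) {
    lab <- segmentWavefronts(px[, , i, channel], k = k, min_size = min_size)
    ce <- .centroids(lab)
    ce[ce$area >= size_range[1L] & ce$area <= size_range[2L], , drop = FALSE]
  })
  # greedy nearest-neighbour linking
  active <- data.frame(y = numeric(0), x = numeric(0), first = integer(0),
                       last = integer(0))
  done <- data.frame(first = integer(0), last = integer(0))
  for (i in seq_len(nt)) {
    d <- dets[[i]]
    matched_det <- rep(FALSE, nrow(d))
    if (nrow(active)) {
      keep <- rep(FALSE, nrow(active))
      for (j in seq_len(nrow(active))) {
        if (nrow(d)) {
          dist2 <- (d$y - active$y[j])^2 + (d$x - active$x[j])^2
          cand <- which(!matched_det & dist2 <= link_dist^2)
          if (length(cand)) {
            b <- cand[which.min(dist2[cand])]
            matched_det[b] <- TRUE
            active$y[j] <- d$y[b]; active$x[j] <- d$x[b]
            active$last[j] <- i
            keep[j] <- TRUE
          }
        }
      }
      ended <- active[!keep, , drop = FALSE]
      done <- rbind(done, ended[, c("first", "last")])
      active <- active[keep, , drop = FALSE]
    }
    if (any(!matched_det)) {
      nd <- d[!matched_det, , drop = FALSE]
      active <- rbind(active, data.frame(y = nd$y, x = nd$x, first = i,
                                         last = i))
    }
  }
  done <- rbind(done, active[, c("first", "last")])
  if (drop_censored) done <- done[done$first > 1L & done$last < nt, ,
                                  drop = FALSE]
  as.numeric(done$last - done$first + 1L) * movie@frame_interval
}

#' Space-time kymograph along a line
#'
#' Bilinear sampling of each frame along the segment
#' `(x0, y0) -> (x1, y1)`, stacked into a space-by-time matrix.
#'
#' @param movie a [WaveMovie-class].
#' @param line numeric `c(x0, y0, x1, y1)` in pixel coordinates.
#' @param channel channel index.
#' @param n_samples points along the line (default: line length in
#'   pixels, rounded up).
#' @return matrix with one row per line sample and one column per
#'   frame.
#' @export
kymograph <- function(movie, line, channel = 1L, n_samples = NULL) {
  d <- dim(movie@pixels)
  if (any(line[c(1L, 3L)] < 1 | line[c(1L, 3L)] > d[2L]) ||
      any(line[c(2L, 4L)] < 1 | line[c(2L, 4L)] > d[1L]))
    stop("line endpoints outside the frame")
  if (is.null(n_samples))
    n_samples <- max(2L, ceiling(sqrt((line[3L] - line[1L])^2 +
                                        (line[4L] - line[2L])^2)) + 1L)
  vapply(seq_len(d[3L]), function(i)
    .sample_line(movie@pixels[, , i, channel], line, n_samples),
    numeric(n_samples))
}
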