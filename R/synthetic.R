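# Ground-truth-labelled synthetic microscopy emulating two-channel
# basal-surface cortical wave movies: a diffuse one-peak STEN-like band
# and a sharp two-peak CEN-like band with short-lived trailing puncta.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

#' Construct a synthetic wave-movie specification
#'
#' Defaults emulate basal cortical waves at a realistic microscopy
#' scale: 0.5 um pixels, 3 s frames, waves at 0.3 um/s, a ~4 um
#' diffuse signalling band, two sharp ~1.5 um cytoskeletal peaks
#' separated by 5 um with an intermediate-intensity dip, and trailing
#' puncta living ~10.8 s on average.
#'
#' @param speed wave speed (um/s).
#' @param direction propagation direction `c(dx, dy)` (normalised).
#' @param sten_band_width,cen_peak_width,cen_peak_separation widths (um).
#' @param cen_mid_dip_fraction mid-band intensity as a fraction of the
#'   leading-peak intensity.
#' @param channel_offset signed STEN-peak offset from the CEN leading
#'   peak along the propagation direction (um).
#' @param puncta_rate trailing-puncta birth rate (events/um^2/s).
#' @param puncta_lifetime_mean mean punctum lifetime (s).
#' @param noise_sd additive Gaussian noise sd (intensity units; peak
#'   intensity is 1).
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @param duration movie length (s).
#' @param shape frame shape `c(n_y, n_x)` in pixels.
#' @param seed integer seed; all generators are reproducible from it.
#' @return a [SyntheticWaveSpec-class].
#' @export
syntheticWaveSpec <- function(speed = 0.3, direction = c(1, 0),
                              sten_band_width = 4, cen_peak_width = 1.5,
                              cen_peak_separation = 5,
                              cen_mid_dip_fraction = 0.45,
                              channel_offset = 0, puncta_rate = 0,
                              puncta_lifetime_mean = 10.8, noise_sd = 0,
                              pixel_size = 0.5, frame_interval = 3,
                              duration = 300, shape = c(128L, 128L),
                              seed = 1L) {
  direction <- direction / sqrt(sum(direction^2))
  new("SyntheticWaveSpec", speed = speed, direction = direction,
      sten_band_width = sten_band_width, cen_peak_width = cen_peak_width,
      cen_peak_separation = cen_peak_separation,
      cen_mid_dip_fraction = cen_mid_dip_fraction,
      channel_offset = channel_offset, puncta_rate = puncta_rate,
      puncta_lifetime_mean = puncta_lifetime_mean, noise_sd = noise_sd,
      pixel_size = pixel_size, frame_interval = frame_interval,
      duration = duration, shape = as.integer(shape), seed = as.integer(seed))
}

# intensity profiles as functions of the along-direction coordinate u
# (physical units), with the CEN leading peak at u = u_lead
.cen_profile <- function(u, u_lead, spec) {
  w <- spec@cen_peak_width / 2.355          # FWHM -> sd
  sep <- spec@cen_peak_separation
  lead <- exp(-(u - u_lead)^2 / (2 * w^2))
  trail <- 0.7 * exp(-(u - (u_lead - sep))^2 / (2 * w^2))
  # intermediate-intensity plateau strictly between the two peaks
  mid <- spec@cen_mid_dip_fraction *
    (u < u_lead - spec@cen_peak_width & u > u_lead - sep + spec@cen_peak_width)
  pmax(pmax(lead, trail), mid)
}

.sten_profile <- function(u, u_lead, spec) {
  w <- spec@sten_band_width / 2.355
  centre <- u_lead + spec@channel_offset
  exp(-(u - centre)^2 / (2 * w^2))
}

#' Synthetic two-channel line scan with ground truth
#'
#' One-dimensional intensity profiles across a wave: channel 1 the
#' diffuse one-peak STEN-like band, channel 2 the sharp two-peak
#' CEN-like band with an intermediate-intensity mid-dip.  The STEN peak
#' sits `channel_offset` ahead of the CEN leading peak.
#'
#' @param spec a [SyntheticWaveSpec-class].
#' @param n_px profile length in pixels.
#' @return list with `sten`, `cen` (numeric profiles), `pixel_size` and
#'   `truth` (list with the programmed `offset` and peak positions).
#' @export
synthLinescanPair <- function(spec, n_px = 200L) {
  u <- (seq_len(n_px) - 1) * spec@pixel_size
  u_lead <- u[n_px] * 0.6
  sten <- .sten_profile(u, u_lead, spec)
  cen <- .cen_profile(u, u_lead, spec)
  if (spec@noise_sd > 0) {
    noise <- .with_seed(spec@seed,
                        matrix(stats::rnorm(2L * n_px, 0, spec@noise_sd), 2L))
    sten <- sten + noise[1L, ]
    cen <- cen + noise[2L, ]
  }
  list(sten = sten, cen = cen, pixel_size = spec@pixel_size,
       truth = list(offset = spec@channel_offset,
                    cen_lead = u_lead, sten_peak = u_lead + spec@channel_offset))
}

#' Synthetic two-channel wave movie with ground truth
#'
#' A planar wave (STEN band + two-peak CEN band) translating at the
#' programmed speed and direction, optionally decelerating to a stop,
#' with trailing short-lived CEN puncta (spatio-temporal Poisson
#' births, exponential lifetimes) and additive Gaussian noise.
#'
#' @param spec a [SyntheticWaveSpec-class].
#' @param stop_time optional time (s) at which the wave speed starts
#'   ramping linearly to zero over `stop_ramp` seconds.
#' @param stop_ramp ramp duration of the optional stop (s).
#' @return list with `movie` (a [WaveMovie-class], channels
#'   `"sten", "cen"`) and `truth` (programmed speed, offset, puncta
#'   records, per-frame wave position).
#' @export
synthWaveMovie <- function(spec, stop_time = NULL, stop_ramp = 30) {
  ny <- spec@shape[1L]; nx <- spec@shape[2L]
  nt <- max(2L, floor(spec@duration / spec@frame_interval) + 1L)
  times <- (seq_len(nt) - 1L) * spec@frame_interval
  # along-direction coordinate of each pixel (physical units)
  xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE) * spec@pixel_size
  yg <- matrix(seq_len(ny), ny, nx) * spec@pixel_size
  u <- xg * spec@direction[1L] + yg * spec@direction[2L]
  # wave position over time (possibly decelerating)
  vel <- rep(spec@speed, nt)
  if (!is.null(stop_time))
    vel <- spec@speed * pmax(0, pmin(1, 1 - (times - stop_time) / stop_ramp))
  u0 <- min(u) + 0.2 * (max(u) - min(u))
  pos <- u0 + c(0, cumsum((vel[-1L] + vel[-nt]) / 2 * diff(times)))

  .with_seed(spec@seed, {
    px <- array(0, c(ny, nx, nt, 2L))
    # trailing puncta: births behind the CEN trailing peak
    records <- NULL
    if (spec@puncta_rate > 0) {
      area <- ny * nx * spec@pixel_size^2
      n_birth <- stats::rpois(1L, spec@puncta_rate * area * spec@duration)
      if (n_birth > 0) {
        records <- data.frame(
          x = stats::runif(n_birth, 1, nx), y = stats::runif(n_birth, 1, ny),
          birth = stats::runif(n_birth, 0, spec@duration))
        records$death <- records$birth +
          stats::rexp(n_birth, 1 / spec@puncta_lifetime_mean)
      }
    }
    for (i in seq_len(nt)) {
      px[, , i, 1L] <- .sten_profile(u, pos[i], spec)
      cen <- .cen_profile(u, pos[i], spec)
      if (!is.null(records)) {
        live <- which(records$birth <= times[i] & records$death > times[i])
        for (j in live) {
          pu <- records$x[j] * spec@pixel_size * spec@direction[1L] +
            records$y[j] * spec@pixel_size * spec@direction[2L]
          # render only in the wake of the wave
          if (pu < pos[i] - spec@cen_peak_separation) {
            r2 <- (xg / spec@pixel_size - records$x[j])^2 +
              (yg / spec@pixel_size - records$y[j])^2
            cen <- pmax(cen, exp(-r2 / (2 * 1.5^2)))
          }
        }
      }
      px[, , i, 2L] <- cen
    }
    if (spec@noise_sd > 0)
      px <- px + array(stats::rnorm(length(px), 0, spec@noise_sd), dim(px))
    movie <- new("WaveMovie", pixels = px, pixel_size = spec@pixel_size,
                 frame_interval = spec@frame_interval,
                 channels = c("sten", "cen"))
    list(movie = movie,
         truth = list(speed = spec@speed, offset = spec@channel_offset,
                      position = pos, times = times, puncta = records))
  })
}

#' Synthetic stopping-wave kymograph with ground truth
#'
#' A bright stripe whose position integrates a decelerating speed
#' profile \eqn{v(t) = \max(0, v_0 - a t)}: the stripe's slope curves
#' and the trace terminates at the stop position.
#'
#' @param initial_speed stripe speed at t = 0 (pixels/frame).
#' @param deceleration speed loss per frame (pixels/frame^2); 0 gives a
#'   straight stripe.
#' @param n_x,n_t kymograph dimensions (space samples, frames).
#' @param stripe_width Gaussian stripe sd (pixels).
#' @param noise_sd additive noise.
#' @param seed integer seed.
#' @return list with `kymo` (space-by-time matrix) and `truth`
#'   (`stop_position`, pixels; `position` per frame).
#' @export
synthStoppingKymograph <- function(initial_speed, deceleration = 0,
                                   n_x = 200L, n_t = 100L,
                                   stripe_width = 2, noise_sd = 0,
                                   seed = 1L) {
  t <- seq_len(n_t) - 1L
  v <- pmax(0, initial_speed - deceleration * t)
  pos <- 5 + c(0, cumsum((v[-1L] + v[-n_t]) / 2))
  x <- seq_len(n_x)
  kym <- vapply(seq_len(n_t), function(i) {
    col <- exp(-(x - pos[i])^2 / (2 * stripe_width^2))
    if (v[i] == 0 && deceleration > 0)
      col <- col * max(0, 1 - (t[i] - t[which(v == 0)[1L]]) / 10)
    col
  }, numeric(n_x))
  if (noise_sd > 0)
    kym <- kym + .with_seed(seed,
                            matrix(stats::rnorm(length(kym), 0, noise_sd),
                                   n_x, n_t))
  list(kymo = kym,
       truth = list(stop_position = max(pos), position = pos, speed = v))
}

#' Synthetic puncta-only movie with per-punctum records
#'
#' Spatio-temporal Poisson births of small Gaussian discs with
#' exponential lifetimes on a dark background.
#'
#' @param rate births per um^2 per s.
#' @param lifetime_mean mean lifetime (s).
#' @param size punctum Gaussian sd (pixels).
#' @param shape frame shape `c(n_y, n_x)`.
#' @param duration movie length (s).
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `movie` (single-channel [WaveMovie-class]) and
#'   `records` (data frame `x, y, birth, death`).
#' @export
synthPunctaMovie <- function(rate, lifetime_mean, size = 1.5,
                             shape = c(128L, 128L), duration = 100,
                             pixel_size = 0.5, frame_interval = 1,
                             noise_sd = 0, seed = 1L) {
  ny <- shape[1L]; nx <- shape[2L]
  nt <- max(2L, floor(duration / frame_interval) + 1L)
  times <- (seq_len(nt) - 1L) * frame_interval
  .with_seed(seed, {
    area <- ny * nx * pixel_size^2
    n_birth <- stats::rpois(1L, rate * area * duration)
    records <- if (n_birth > 0) {
      r <- data.frame(x = stats::runif(n_birth, 4, nx - 3),
                      y = stats::runif(n_birth, 4, ny - 3),
                      birth = stats::runif(n_birth, 0, duration))
      r$death <- r$birth + stats::rexp(n_birth, 1 / lifetime_mean)
      r
    } else data.frame(x = numeric(0), y = numeric(0), birth = numeric(0),
                      death = numeric(0))
    xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    yg <- matrix(seq_len(ny), ny, nx)
    px <- array(0, c(ny, nx, nt, 1L))
    for (i in seq_len(nt)) {
      fr <- matrix(0, ny, nx)
      live <- which(records$birth <= times[i] & records$death > times[i])
      for (j in live) {
        r2 <- (xg - records$x[j])^2 + (yg - records$y[j])^2
        fr <- pmax(fr, exp(-r2 / (2 * size^2)))
      }
      if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(ny * nx, 0, noise_sd),
                                          ny, nx)
      px[, , i, 1L] <- fr
    }
    movie <- new("WaveMovie", pixels = px, pixel_size = pixel_size,
                 frame_interval = frame_interval, channels = "puncta")
    list(movie = movie, records = records)
  })
}

.SPEC_KEYS <- c("speed", "direction_x", "direction_y", "sten_band_width",
                "cen_peak_width", "cen_peak_separation",
                "cen_mid_dip_fraction", "channel_offset", "puncta_rate",
                "puncta_lifetime_mean", "noise_sd", "pixel_size",
                "frame_interval", "duration", "shape_y", "shape_x", "seed")

#' Serialise and restore synthetic wave specifications
#'
#' Flat `key = value` text format, mirroring the model configuration
#' serialiser; round-trips exactly.
#'
#' @param spec a [SyntheticWaveSpec-class].
#' @param path file path.
#' @return `writeWaveSpec`: `path` invisibly; `readWaveSpec`: the
#'   restored [SyntheticWaveSpec-class].
#' @export
writeWaveSpec <- function(spec, path) {
  v <- c(spec@speed, spec@direction, spec@sten_band_width,
         spec@cen_peak_width, spec@cen_peak_separation,
         spec@cen_mid_dip_fraction, spec@channel_offset, spec@puncta_rate,
         spec@puncta_lifetime_mean, spec@noise_sd, spec@pixel_size,
         spec@frame_interval, spec@duration, spec@shape, spec@seed)
  writeLines(sprintf("%s = %.17g", .SPEC_KEYS, v), path)
  invisible(path)
}

#' @rdname writeWaveSpec
#' @export
readWaveSpec <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  if (!setequal(keys, .SPEC_KEYS)) stop("invalid wave-spec file")
  g <- function(k) vals[match(k, keys)]
  syntheticWaveSpec(
    speed = g("speed"), direction = c(g("direction_x"), g("direction_y")),
    sten_band_width = g("sten_band_width"),
    cen_peak_width = g("cen_peak_width"),
    cen_peak_separation = g("cen_peak_separation"),
    cen_mid_dip_fraction = g("cen_mid_dip_fraction"),
    channel_offset = g("channel_offset"), puncta_rate = g("puncta_rate"),
    puncta_lifetime_mean = g("puncta_lifetime_mean"),
    noise_sd = g("noise_sd"), pixel_size = g("pixel_size"),
    frame_interval = g("frame_interval"), duration = g("duration"),
    shape = c(g("shape_y"), g("shape_x")), seed = g("seed"))
}

#' Named synthetic and model fixtures
#'
#' Versioned, fully reproducible configurations used throughout the
#' examples and tests: `"fig1-linescan"` (offset line-scan pair),
#' `"fig2-movie"` (two-channel travelling wave with trailing puncta),
#' `"fig3-kymo"` (decelerating stopping-wave kymograph), and the model
#' presets of [perturbationPreset()].
#'
#' @return named list; synthetic entries are
#'   [SyntheticWaveSpec-class]s or argument lists, model entries are
#'   preset configurations.
#' @export
presetConfigs <- function() {
  list(
    "fig1-linescan" = syntheticWaveSpec(channel_offset = 4, noise_sd = 0.05,
                                        pixel_size = 0.1, seed = 11L),
    "fig2-movie" = syntheticWaveSpec(puncta_rate = 2e-4, noise_sd = 0.02,
                                     seed = 12L),
    "fig3-kymo" = list(initial_speed = 2, deceleration = 0.02, seed = 13L),
    "model-default" = list(params = modelParams(),
                           grid = gridSpec(c(100, 100)), schedule = NULL),
    "model-inp54p" = perturbationPreset("inp54p"),
    "model-pkba" = perturbationPreset("pkba"),
    "model-racgef1" = perturbationPreset("racgef1"),
    "model-lata" = perturbationPreset("lata"),
    "model-fig3" = perturbationPreset("fig3-wave-stopping"))
}
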