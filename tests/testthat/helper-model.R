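# Shared fixtures: quiet (deterministic) parameter sets and small
# triggered-run helpers used across test files.

quiet_params <- function(...) modelParams(u_b = 0, sigma_c = 0, s_c = 0, ...)

# 1D triggered run of the deterministic STEN on a fine grid; returns the
# trajectory of F_S frames.
triggered_run_1d <- function(p = quiet_params(), n = 200, spacing = 0.25,
                             duration = 80, amplitude = 2, location = 5,
                             save_interval = 2) {
  g <- gridSpec(n, spacing = spacing)
  st <- initialState(p, g, seed = 1L)
  st <- triggerWave(st, location, amplitude, radius = 4)
  runSimulation(p, g, duration, save_interval, seed = 1L, init = st,
                save_fields = "F_S")
}

# planar 2D wave triggered along the left edge after a short burn-in of
# the full stochastic model
planar_wave_run <- function(p, shape = c(200, 50), duration = 40,
                            seed = 3L, save_interval = 4) {
  g <- gridSpec(shape)
  pre <- runSimulation(p, g, duration = 30, save_interval = 30, seed = seed,
                       burn_in = 20)
  fl <- pre@frames[[length(pre@frames)]]
  fl$F_S[, 1:4] <- fl$F_S[, 1:4] + 2
  st <- initialState(p, g, seed)
  st <- new("FieldState", t = 0, fields = fl, grid = g,
            rng_state = st@rng_state)
  runSimulation(p, g, duration, save_interval, seed = seed + 1L, init = st)
}

# furthest grid index with activator above a level, per frame
front_trace <- function(traj, level) {
  vapply(traj@frames, function(fr) {
    f <- fr$F_S
    prof <- if (is.matrix(f)) colMeans(f) else f
    ix <- which(prof >= level)
    if (length(ix)) max(ix) else 0L
  }, numeric(1))
}

# render a band movie translating at a per-frame displacement sequence
# (pixels); returns a WaveMovie with one channel
band_movie <- function(disp_px, n_x = 200, n_y = 40, width = 4,
                       start = 10, pixel_size = 1, frame_interval = 1) {
  pos <- start + c(0, cumsum(disp_px))
  nt <- length(pos)
  px <- array(0, c(n_y, n_x, nt, 1L))
  x <- seq_len(n_x)
  for (i in seq_len(nt)) {
    prof <- exp(-(x - pos[i])^2 / (2 * width^2))
    px[, , i, 1L] <- matrix(prof, n_y, n_x, byrow = TRUE)
  }
  new("WaveMovie", pixels = px, pixel_size = pixel_size,
      frame_interval = frame_interval, channels = "band")
}
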