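# Stochastic reaction-diffusion integration of the coupled system.
# Internals work on plain numeric vectors/matrices for speed; the S4
# FieldState/Trajectory wrappers carry metadata and the RNG contract.

.shift1 <- function(x, by, boundary) {
  n <- length(x)
  if (boundary == "periodic") {
    if (by == 1L) c(x[n], x[-n]) else c(x[-1L], x[1L])
  } else {                      # no-flux: reflect the edge value
    if (by == 1L) c(x[1L], x[-n]) else c(x[-1L], x[n])
  }
}

.lap1 <- function(x, h, boundary)
  (.shift1(x, 1L, boundary) + .shift1(x, -1L, boundary) - 2 * x) / h^2

.lap2 <- function(m, h, boundary) {
  nr <- nrow(m); nc <- ncol(m)
  if (boundary == "periodic") {
    up <- m[c(nr, seq_len(nr - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(nr - 1L) + 1L, 1L), , drop = FALSE]
    lf <- m[, c(nc, seq_len(nc - 1L)), drop = FALSE]
    rt <- m[, c(seq_len(nc - 1L) + 1L, 1L), drop = FALSE]
  } else {
    up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
    dn[nr, ] <- m[nr - 1L, ]
    lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
    rt[, nc] <- m[, nc - 1L]
  }
  (up + dn + lf + rt - 4 * m) / h^2
}

#' Discrete Laplacian on a simulation grid
#'
#' Central-difference stencil: 3-point in 1D, 5-point in 2D, divided by
#' the squared grid spacing.  `"no-flux"` boundaries mirror the edge
#' value (zero normal derivative); `"periodic"` wraps.
#'
#' @param field numeric vector (1D grid) or matrix (2D grid).
#' @param grid a [GridSpec-class]; its shape must match `field`.
#' @return array of the same shape.
#' @examples
#' g <- gridSpec(8)
#' laplacianField(rep(1, 8), g)   # constant field -> all zeros
#' @export
laplacianField <- function(field, grid) {
  stopifnot(is(grid, "GridSpec"))
  if (length(grid@shape) == 1L) {
    if (!is.null(dim(field)) || length(field) != grid@shape)
      stop("field shape does not match grid")
    .lap1(field, grid@spacing, grid@boundary)
  } else {
    if (is.null(dim(field)) ||
        !all(dim(field) == c(grid@shape[2L], grid@shape[1L])))
      stop("field shape does not match grid")   # fields are [y, x]
    .lap2(field, grid@spacing, grid@boundary)
  }
}

.lap <- function(field, grid) {
  if (length(grid@shape) == 1L) .lap1(field, grid@spacing, grid@boundary)
  else .lap2(field, grid@spacing, grid@boundary)
}

.max_finite_diff <- function(p) {
  d <- c(p@sten@d_fs, p@sten@d_rs, p@cen@d_fc, p@cen@d_rc,
         p@feedback@d_zc, p@feedback@d_wc)
  max(d[is.finite(d)], 0)
}

#' Largest stable integration step
#'
#' Explicit-scheme diffusion stability bound
#' \eqn{dt \le h^2 / (4 \max D)} over all finite diffusion
#' coefficients (a spatially-uniform global species with `d_wc = Inf`
#' is mixed exactly and does not constrain the step).
#'
#' @param p a [ModelParams-class].
#' @param grid a [GridSpec-class].
#' @return the bound (Inf for a diffusion-free model).
#' @export
stableStep <- function(p, grid) {
  dmax <- .max_finite_diff(p)
  if (dmax == 0) Inf else grid@spacing^2 / (4 * dmax)
}

# One Euler-Maruyama step on a plain list of fields.  `clamp_r_s`
# freezes the STEN inhibitor (phase-plane experiments).
.step_raw <- function(fl, p, dt, grid, clamp_r_s = NULL, s_in_extra = NULL) {
  s <- p@sten; cc <- p@cen; fb <- p@feedback
  s_in <- cc@s_c * (fl$R_S - s@r0)
  if (!is.null(s_in_extra)) s_in <- s_in + s_in_extra
  kS <- list(a1 = s@a1s, a2 = s@a2s, a3 = s@a3s, a4 = s@a4s, a5 = s@a5s)
  kC <- list(a1 = cc@a1c, a2 = cc@a2c, a3 = cc@a3c, a4 = cc@a4c, a5 = cc@a5c)
  n <- length(fl$F_S)

  sig <- pmax(0, s@u_b + fl$Z_C - fl$W_C)
  dF_S <- .act_rate(fl$F_S, fl$R_S, kS) + s@d_fs * .lap(fl$F_S, grid)
  noiseS <- if (any(sig > 0)) sig * (sqrt(dt) * stats::rnorm(n)) else 0
  dF_C <- .act_rate(fl$F_C, fl$R_C - s_in, kC) + cc@d_fc * .lap(fl$F_C, grid)
  noiseC <- if (cc@sigma_c > 0) cc@sigma_c * sqrt(dt) * stats::rnorm(n) else 0

  out <- fl
  out$F_S <- pmax(fl$F_S + dt * dF_S + noiseS, 0)
  out$F_C <- pmax(fl$F_C + dt * dF_C + noiseC, 0)
  out$R_S <- if (is.null(clamp_r_s))
    pmax(fl$R_S + dt * (s@eps_s * (-fl$R_S + s@c1s * fl$F_S) +
                          s@d_rs * .lap(fl$R_S, grid)), 0)
  else fl$R_S
  out$R_C <- pmax(fl$R_C + dt * (cc@eps_c * (-fl$R_C + cc@c1c * fl$F_C) +
                                   cc@d_rc * .lap(fl$R_C, grid)), 0)
  out$Z_C <- pmax(fl$Z_C + dt * (-fb@p1 * fl$Z_C + fb@p2 * fl$F_C +
                                   fb@d_zc * .lap(fl$Z_C, grid)), 0)
  out$W_C <- if (is.infinite(fb@d_wc)) {
    # global species: exact instantaneous mixing, scalar dynamics on the
    # spatial mean of its drive
    w <- mean(fl$W_C)
    0 * fl$W_C + pmax(0, w + dt * (-fb@p3 * w + fb@p4 * mean(fl$F_C)))
  } else {
    pmax(fl$W_C + dt * (-fb@p3 * fl$W_C + fb@p4 * fl$F_C +
                          fb@d_wc * .lap(fl$W_C, grid)), 0)
  }
  out
}

.empty_fields <- function(grid, vals) {
  shp <- grid@shape
  mk <- function(v) if (length(shp) == 1L) rep(v, shp) else
    matrix(v, shp[2L], shp[1L])   # rows = y, cols = x
  lapply(vals, mk)
}

#' Deterministic resting state of the coupled model
#'
#' All six fields at their reaction equilibrium (STEN and CEN at rest,
#' feedback species at their steady-state gain times the CEN activator
#' rest level).
#'
#' @param p a [ModelParams-class].
#' @param grid a [GridSpec-class].
#' @param seed integer used to initialise the state's RNG token.
#' @return a [FieldState-class] at `t = 0`.
#' @export
initialState <- function(p, grid, seed = 1L) {
  eqS <- equilibriumState(p@sten)
  eqC <- equilibriumState(p@cen)
  fb <- p@feedback
  vals <- list(F_S = eqS[["F"]], R_S = eqS[["R"]],
               F_C = eqC[["F"]], R_C = eqC[["R"]],
               Z_C = fb@p2 / fb@p1 * eqC[["F"]],
               W_C = fb@p4 / fb@p3 * eqC[["F"]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rs <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  new("FieldState", t = 0, fields = .empty_fields(grid, vals), grid = grid,
      rng_state = rs)
}

#' Advance the coupled fields by one Euler--Maruyama step
#'
#' Deterministic part: reaction rates plus central-difference diffusion.
#' Stochastic part: independent per-site Gaussian increments with
#' standard deviation \eqn{\sigma_N \sqrt{dt}} added to the STEN
#' activator and \eqn{\sigma_c \sqrt{dt}} to the CEN activator.  Fields
#' are floored at zero (concentrations).  The step restores the state's
#' RNG token before drawing, so stepping equal states is bit-identical.
#'
#' @param state a [FieldState-class].
#' @param p a [ModelParams-class].
#' @param dt time step; must satisfy [stableStep()].
#' @return the advanced [FieldState-class].
#' @export
stepFields <- function(state, p, dt) {
  stopifnot(is(state, "FieldState"), is(p, "ModelParams"))
  if (dt > stableStep(p, state@grid) * (1 + 1e-12))
    stop("dt exceeds the diffusion stability bound dt <= h^2/(4 max D)")
  if (!all(vapply(state@fields, function(f) all(is.finite(f)), logical(1))))
    stop("non-finite field state")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state@rng_state, globalenv())
  fl <- .step_raw(state@fields, p, dt, state@grid)
  rs <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  new("FieldState", t = state@t + dt, fields = fl, grid = state@grid,
      rng_state = rs)
}

.region_index <- function(grid, location, radius = 0) {
  shp <- grid@shape
  if (length(shp) == 1L) {
    idx <- seq(max(1L, round(location[1L]) - radius),
               min(shp, round(location[1L]) + radius))
    if (location[1L] < 1 || location[1L] > shp) stop("trigger location outside grid")
    idx
  } else {
    nx <- shp[1L]; ny <- shp[2L]
    if (location[1L] < 1 || location[1L] > nx ||
        location[2L] < 1 || location[2L] > ny)
      stop("trigger location outside grid")
    xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    yg <- matrix(seq_len(ny), ny, nx)
    which((xg - location[1L])^2 + (yg - location[2L])^2 <= max(radius, 0.5)^2)
  }
}

#' Deterministically trigger the STEN
#'
#' Adds `amplitude` to the STEN activator over a point, interval or
#' disc; nothing else changes.
#'
#' @param state a [FieldState-class].
#' @param location grid index (1D) or `c(x, y)` centre (2D).
#' @param amplitude concentration added to `F_S`.
#' @param radius half-width (1D, grid points) or disc radius (2D).
#' @return the perturbed [FieldState-class].
#' @export
triggerWave <- function(state, location, amplitude, radius = 2) {
  idx <- .region_index(state@grid, location, radius)
  fl <- state@fields
  fl$F_S[idx] <- fl$F_S[idx] + amplitude
  initializeFrom(state, fl)
}

initializeFrom <- function(state, fields)
  new("FieldState", t = state@t, fields = fields, grid = state@grid,
      rng_state = state@rng_state)

#' Perturbation schedule constructor
#'
#' @param path parameter paths (see [modelParam()]).
#' @param start ramp start times.
#' @param target target values.
#' @param duration ramp durations (default 10 time units).
#' @return a data frame with one row per scheduled ramp.
#' @export
perturbationSchedule <- function(path, start, target, duration = 10) {
  stopifnot(all(duration > 0))
  sch <- data.frame(path = path, start = start, target = target,
                    duration = duration, stringsAsFactors = FALSE)
  vapply(sch$path, .split_path, character(2))  # validates
  sch
}

#' Apply scheduled parameter ramps at a time point
#'
#' Each scheduled parameter moves linearly from its value in `p` to the
#' target over `[start, start + duration]` and stays at the target
#' afterwards.
#'
#' @param p the pre-ramp [ModelParams-class].
#' @param schedule a data frame from [perturbationSchedule()].
#' @param t current simulation time.
#' @return the [ModelParams-class] in force at time `t`.
#' @export
rampParameter <- function(p, schedule, t) {
  if (is.null(schedule) || !nrow(schedule)) return(p)
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    v0 <- modelParam(p, row$path)
    frac <- min(1, max(0, (t - row$start) / row$duration))
    if (frac > 0)
      modelParam(p, row$path) <- v0 + frac * (row$target - v0)
  }
  p
}

#' Named perturbation presets
#'
#' Complete runnable configurations emulating acute recruitment and
#' pharmacological perturbations, as scheduled parameter ramps on top of
#' the default model:
#' \describe{
#'   \item{inp54p}{large increase of the STEN autocatalytic feedback
#'     `a3s` (threshold drops, waves speed up and widen).}
#'   \item{ras}{small increase of `a3s` (modest speed-up).}
#'   \item{pkba}{raises the STEN threshold (`c1s` up) while lowering the
#'     CEN threshold (`a3c` up): slower, fragmented waves, more and
#'     smaller patches.}
#'   \item{racgef1}{strong CEN positive feedback (`a3c` up, `a1c` down,
#'     `c1c` down) driving CEN to a high stable state; the global
#'     negative feedback W_C then suppresses STEN after a transient
#'     rise.}
#'   \item{lata}{cytoskeleton silenced: CEN noise, coupling and feedback
#'     production ramp to zero; only the basal drive `u_b` remains.}
#'   \item{fig3-wave-stopping}{deterministic 1D wave-theory
#'     configuration: slow inhibitor (`eps_s = 0.03`), activator
#'     diffusion 0.1, inhibitor diffusion 1.0, all noise and coupling
#'     off; meant for a 3000-point 1D grid.}
#' }
#'
#' @param name preset name.
#' @param start ramp start time (default 100).
#' @return list with elements `params` (starting [ModelParams-class]),
#'   `schedule` (data frame or NULL) and `grid` (suggested
#'   [GridSpec-class]).
#' @export
perturbationPreset <- function(name = c("inp54p", "ras", "pkba", "racgef1",
                                        "lata", "fig3-wave-stopping"),
                               start = 100) {
  name <- match.arg(name)
  p <- modelParams()
  switch(name,
    "inp54p" = list(
      params = p,
      schedule = perturbationSchedule("sten.a3s", start, 5.6),
      grid = gridSpec(c(100, 100))),
    "ras" = list(
      params = p,
      schedule = perturbationSchedule("sten.a3s", start, 4.5),
      grid = gridSpec(c(100, 100))),
    "pkba" = list(
      params = p,
      schedule = perturbationSchedule(c("sten.c1s", "cen.a3c"), start,
                                      c(7.5, 6)),
      grid = gridSpec(c(100, 100))),
    "racgef1" = list(
      params = p,
      schedule = perturbationSchedule(c("cen.a3c", "cen.a1c", "cen.c1c"),
                                      start, c(8, 0.2, 1.5)),
      grid = gridSpec(c(100, 100))),
    "lata" = list(
      params = p,
      schedule = perturbationSchedule(
        c("cen.sigma_c", "cen.s_c", "feedback.p2", "feedback.p4"),
        start, c(0, 0, 0, 0)),
      grid = gridSpec(c(100, 100))),
    "fig3-wave-stopping" = list(
      params = modelParams(eps_s = 0.03, d_fs = 0.1, d_rs = 1.0, u_b = 0,
                           sigma_c = 0, s_c = 0),
      schedule = NULL,
      grid = gridSpec(3000)))
}

#' Run a full stochastic simulation
#'
#' Integrates the coupled model with [stepFields()]'s scheme, applying
#' scheduled ramps, and saves frames at a fixed interval.  The state is
#' initialised at the deterministic rest state and burnt in before
#' `t = 0` so that measurements start from stationary fluctuations.
#' Fully reproducible from `seed`.
#'
#' @param p a [ModelParams-class].
#' @param grid a [GridSpec-class].
#' @param duration simulated time after burn-in.
#' @param save_interval time between saved frames.
#' @param seed integer RNG seed.
#' @param schedule optional data frame from [perturbationSchedule()].
#' @param dt integration step; default 0.4 times the stability bound.
#' @param burn_in burn-in time before measurements (default 20).
#' @param save_fields which fields to keep per frame.
#' @param init optional [FieldState-class] overriding the rest state.
#' @param clamp_r_s optional value freezing the STEN inhibitor field.
#' @param s_in_fn optional `function(t)` returning an extra CEN input
#'   profile (scalar or grid-shaped) added to the STEN-derived coupling
#'   at every step -- a hook for driving the CEN with arbitrary rise and
#'   decay dynamics.
#' @param progress print progress lines every ~10% of the run.
#' @return a [Trajectory-class].
#' @export
runSimulation <- function(p, grid, duration, save_interval = 1, seed = 1L,
                          schedule = NULL, dt = NULL, burn_in = 20,
                          save_fields = c("F_S", "R_S", "F_C", "R_C",
                                          "Z_C", "W_C"),
                          init = NULL, clamp_r_s = NULL, s_in_fn = NULL,
                          progress = FALSE) {
  bound <- stableStep(p, grid)
  if (is.null(dt)) dt <- if (is.finite(bound)) 0.4 * bound else 0.1
  if (dt > bound * (1 + 1e-12)) stop("dt exceeds the stability bound")
  state <- if (is.null(init)) initialState(p, grid, seed) else init
  fl <- state@fields
  if (!is.null(clamp_r_s)) fl$R_S[] <- clamp_r_s
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  assign(".Random.seed", state@rng_state, globalenv())

  n_burn <- if (is.null(init)) ceiling(burn_in / dt) else 0L
  for (i in seq_len(n_burn))
    fl <- .step_raw(fl, p, dt, grid, clamp_r_s,
                    if (is.null(s_in_fn)) NULL else s_in_fn(0))

  n_steps <- ceiling(duration / dt)
  every <- max(1L, round(save_interval / dt))
  times <- 0
  frames <- list(fl[save_fields])
  t <- 0
  pr <- p
  for (i in seq_len(n_steps)) {
    if (!is.null(schedule)) pr <- rampParameter(p, schedule, t)
    fl <- .step_raw(fl, pr, dt, grid, clamp_r_s,
                    if (is.null(s_in_fn)) NULL else s_in_fn(t))
    t <- i * dt
    if (i %% every == 0L) {
      frames[[length(frames) + 1L]] <- fl[save_fields]
      times <- c(times, t)
    }
    if (progress && n_steps >= 10L && i %% (n_steps %/% 10L) == 0L)
      message(sprintf("  t = %.1f / %.1f", t, n_steps * dt))
  }
  norm <- lapply(save_fields, function(nm) {
    rng <- range(vapply(frames, function(fr) range(fr[[nm]]),
                        numeric(2)))
    list(lo = rng[1L], hi = rng[2L])
  })
  names(norm) <- save_fields
  new("Trajectory", times = times, frames = frames, grid = grid, params = p,
      norm = norm, seed = as.integer(seed))
}

#' Extract normalised readouts from a trajectory
#'
#' The model's observable readouts are the two inhibitors, `R_S` (STEN,
#' PIP3-sensor-like) and `R_C` (CEN, F-actin-sensor-like), min--max
#' scaled by fixed per-run constants stored in the trajectory (so
#' before/after comparisons stay meaningful, and the scaling is exactly
#' invertible from the recorded constants).
#'
#' @param traj a [Trajectory-class].
#' @param channels saved field names to use as channels.
#' @param line optional `c(x0, y0, x1, y1)` (2D) or `c(i0, i1)` (1D):
#'   return a space-by-time kymograph along that line for the first
#'   channel instead of a movie.
#' @param n_line number of sample points along the line.
#' @param pixel_size,frame_interval physical calibration attached to the
#'   returned movie (defaults: grid spacing, save interval).
#' @return a [WaveMovie-class], or a space-by-time matrix when `line`
#'   is given.
#' @export
extractReadout <- function(traj, channels = c("R_S", "R_C"), line = NULL,
                           n_line = 200, pixel_size = NULL,
                           frame_interval = NULL) {
  if (!length(traj@frames)) stop("empty trajectory")
  stopifnot(all(channels %in% names(traj@frames[[1L]])))
  normed <- function(nm, fr) {
    n <- traj@norm[[nm]]
    span <- max(n$hi - n$lo, .Machine$double.eps)
    (fr[[nm]] - n$lo) / span
  }
  if (!is.null(line)) {
    one_d <- length(traj@grid@shape) == 1L
    mats <- lapply(traj@frames, function(fr) {
      f <- normed(channels[1L], fr)
      if (one_d) f[seq(line[1L], line[2L])]
      else .sample_line(f, line, n_line)
    })
    return(do.call(cbind, mats))
  }
  one_d <- length(traj@grid@shape) == 1L
  if (one_d) stop("movie extraction needs a 2D grid; use 'line' for 1D")
  nt <- length(traj@frames)
  d <- dim(traj@frames[[1L]][[channels[1L]]])
  px <- array(0, c(d[1L], d[2L], nt, length(channels)))
  for (k in seq_along(channels))
    for (i in seq_len(nt))
      px[, , i, k] <- normed(channels[k], traj@frames[[i]])
  if (is.null(pixel_size)) pixel_size <- traj@grid@spacing
  if (is.null(frame_interval))
    frame_interval <- if (nt > 1L) traj@times[2L] - traj@times[1L] else 1
  new("WaveMovie", pixels = px, pixel_size = pixel_size,
      frame_interval = frame_interval, channels = channels)
}

# bilinear sampling of a matrix along the segment (x0,y0)-(x1,y1)
.sample_line <- function(m, line, n) {
  xs <- seq(line[1L], line[3L], length.out = n)
  ys <- seq(line[2L], line[4L], length.out = n)
  nr <- nrow(m); nc <- ncol(m)
  if (any(xs < 1 | xs > nc | ys < 1 | ys > nr)) stop("line outside frame")
  x0 <- pmin(floor(xs), nc - 1L); y0 <- pmin(floor(ys), nr - 1L)
  fx <- xs - x0; fy <- ys - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    m[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames on %s grid, t in [%g, %g], seed %d\n",
              length(object@frames),
              paste(object@grid@shape, collapse = "x"),
              min(object@times), max(object@times), object@seed))
})

setMethod("show", "FieldState", function(object) {
  cat(sprintf("FieldState at t = %g on %s grid; mean F_S = %.4g, F_C = %.4g\n",
              object@t, paste(object@grid@shape, collapse = "x"),
              mean(object@fields$F_S), mean(object@fields$F_C)))
})
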