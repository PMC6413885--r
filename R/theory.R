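# Phase-plane and singular-perturbation wave theory for one excitable
# pair: threshold geometry, the net-area wave-speed proxy, the stopping
# level R_stop, and measured speed/range scans against 1D simulations.

#' Signed excitation threshold
#'
#' \eqn{th = r_0 - R_{min}}: the gap between the operating inhibition
#' level and the inhibitor level at the local minimum (fold) of the
#' cubic activator nullcline.  Larger values are harder to excite.
#'
#' @param p a [STENParams-class] or [CENParams-class].
#' @param r0 inhibition level; defaults to the resting equilibrium.
#' @param s_in coupling offset (CEN only).
#' @return signed threshold.
#' @export
thresholdLevel <- function(p, r0 = NULL, s_in = 0) {
  cm <- .cubic_minimum(p, s_in)    # errors if no fold
  if (is.null(r0)) r0 <- equilibriumState(p, s_in)[["R"]]
  r0 - cm[["R"]]
}

#' Net area under the activator rate between its outer roots
#'
#' At clamped inhibition \eqn{r_0} with three activator roots
#' \eqn{F_- < F_0 < F_+}, the signed area
#' \eqn{A(r_0) = \int_{F_-}^{F_+} f(F, r_0)\,dF} of the reaction rate.
#' In the singular limit the front speed of the bistable activator
#' equation is proportional to this area: positive area means the
#' excited state invades, zero is the stall (Maxwell) point.
#'
#' @param r0 clamped inhibitor level.
#' @inheritParams thresholdLevel
#' @return signed area.
#' @export
netArea <- function(r0, p, s_in = 0) {
  rts <- nullclineRoots(r0, p, s_in)
  if (length(rts) < 3L)
    stop("inhibition level outside the bistable window (",
         length(rts), " root(s))", call. = FALSE)
  k <- .canon(p)
  stats::integrate(function(f) .act_rate(f, r0 - s_in, k),
                   rts[1L], rts[3L], abs.tol = 1e-10,
                   subdivisions = 400L)$value
}

#' Bistable window of clamped inhibition
#'
#' The interval of inhibitor levels over which the activator rate has
#' three roots: between the fold minimum and the local maximum of the
#' activator nullcline.
#'
#' @inheritParams thresholdLevel
#' @return numeric `c(R_low, R_high)`.
#' @export
bistableWindow <- function(p, s_in = 0) {
  cm <- .cubic_minimum(p, s_in)
  nf <- function(f) activatorNullcline(f, p, s_in)
  fg <- exp(seq(log(cm[["F"]]), log(50), length.out = 4000))
  v <- nf(fg)
  i <- which.max(v)
  if (i %in% c(1L, length(fg))) stop("no local maximum found")
  opt <- stats::optimize(nf, c(fg[i - 1L], fg[i + 1L]), maximum = TRUE,
                         tol = 1e-12)
  c(R_low = cm[["R"]], R_high = opt$objective)
}

#' Wave-stopping inhibition level
#'
#' The inhibitor level at which [netArea()] vanishes (the two lobes of
#' the activator rate balance) and front propagation stops; found by
#' bisection inside the bistable window to 1e-9.
#'
#' @inheritParams thresholdLevel
#' @return the stopping level.
#' @export
rStop <- function(p, s_in = 0) {
  win <- bistableWindow(p, s_in)
  eps <- 1e-6 * diff(win)
  stats::uniroot(function(r) netArea(r, p, s_in),
                 c(win[1L] + eps, win[2L] - eps), tol = 1e-9)$root
}

#' Molecular dispersion length
#'
#' \eqn{\sqrt{D \tau}}: how far a species spreads within its lifetime.
#' Finite-range waves require the inhibitor to out-disperse the
#' activator.  The package's lifetime convention is the leading-order
#' decay rate: activator lifetime `1/a1`, inhibitor lifetime `1/eps`.
#'
#' @param diff_coef diffusion coefficient (space^2/time), >= 0.
#' @param lifetime species lifetime (time), >= 0.
#' @return dispersion length.
#' @examples
#' molecularDispersion(4, 9)  # 6
#' @export
molecularDispersion <- function(diff_coef, lifetime) {
  if (any(!is.finite(c(diff_coef, lifetime))) ||
      any(c(diff_coef, lifetime) < 0))
    stop("'diff_coef' and 'lifetime' must be finite and >= 0")
  sqrt(diff_coef * lifetime)
}

#' Full phase-plane report
#'
#' Samples both nullclines, locates the equilibrium and the fold,
#' computes the threshold, the net-area curve over the bistable window
#' and the stopping level, and classifies the regime.
#'
#' @inheritParams thresholdLevel
#' @param n_samples points per sampled curve.
#' @return a [PhasePlaneReport-class].
#' @export
phasePlane <- function(p, r0 = NULL, s_in = 0, n_samples = 400) {
  cm <- .cubic_minimum(p, s_in)
  eq <- equilibriumState(p, s_in)
  if (is.null(r0)) r0 <- eq[["R"]]
  win <- bistableWindow(p, s_in)
  k <- .canon(p)
  f_hi <- max(nullclineRoots(win[1L] + 1e-6 * diff(win), p, s_in)) * 1.3
  fs <- seq(1e-3, f_hi, length.out = n_samples)
  act <- cbind(F = fs, R = activatorNullcline(fs, p, s_in))
  inh <- cbind(F = fs, R = k$c1 * fs)
  rg <- seq(win[1L] + 0.01 * diff(win), win[2L] - 0.01 * diff(win),
            length.out = n_samples)
  av <- vapply(rg, function(r) netArea(r, p, s_in), numeric(1))
  rs <- rStop(p, s_in)
  th <- r0 - cm[["R"]]
  cls <- if (th <= 0) "synchronous-oscillation"
         else if (r0 >= rs) "no-spread" else "excitable-waves"
  new("PhasePlaneReport",
      activator_nullcline = act, inhibitor_nullcline = inh,
      equilibrium = unname(eq), cubic_minimum = unname(cm),
      threshold = th, net_area_curve = cbind(r0 = rg, A = av),
      r_stop = rs, window = unname(win), speed_class = cls)
}

setMethod("show", "PhasePlaneReport", function(object) {
  cat("PhasePlaneReport\n")
  cat(sprintf("  equilibrium (F*, R*) = (%.4g, %.4g)\n",
              object@equilibrium[1L], object@equilibrium[2L]))
  cat(sprintf("  fold minimum (F, R) = (%.4g, %.4g); threshold th = %.4g\n",
              object@cubic_minimum[1L], object@cubic_minimum[2L],
              object@threshold))
  cat(sprintf("  bistable window [%.4g, %.4g]; R_stop = %.4g\n",
              object@window[1L], object@window[2L], object@r_stop))
  cat("  regime:", object@speed_class, "\n")
})

# ---- measured 1D front kinematics -----------------------------------

# Deterministic STEN-only parameter stripping: noise and coupling off.
.quiet <- function(p) {
  modelParams(sten = p@sten, cen = p@cen, feedback = p@feedback,
              u_b = 0, sigma_c = 0, s_c = 0)
}

# Clamped-inhibitor 1D run triggered at the left edge; returns the
# trajectory of F_S frames plus times.
.clamped_run <- function(p, r0, n = 600, spacing = 0.25, duration = 250,
                         save_interval = 2, amplitude = NULL) {
  grid <- gridSpec(n, spacing = spacing)
  pq <- .quiet(p)
  # the clamped inhibitor never diffuses, so its (large) diffusion
  # coefficient must not throttle the stable step
  modelParam(pq, "sten.d_rs") <- modelParam(pq, "sten.d_fs")
  rts <- nullclineRoots(r0, pq@sten)
  if (length(rts) < 3L) stop("r0 outside bistable window")
  if (is.null(amplitude)) amplitude <- (rts[3L] - rts[1L]) * 1.1
  st <- initialState(pq, grid, seed = 1L)
  st@fields$F_S[] <- rts[1L]
  st@fields$R_S[] <- r0
  st <- triggerWave(st, 3, amplitude, radius = 4)
  runSimulation(pq, grid, duration, save_interval, seed = 1L, init = st,
                clamp_r_s = r0, save_fields = "F_S")
}

# Half-maximum front position per frame (grid index; 0 if below level).
.front_positions <- function(traj, level) {
  vapply(traj@frames, function(fr) {
    ix <- which(fr$F_S >= level)
    if (length(ix)) max(ix) else 0L
  }, numeric(1))
}

# Front speed by linear regression of half-max crossings over the
# middle 60% of the transit (robust to start-up and stall transients).
.front_speed <- function(pos, times, spacing, n) {
  travel <- pos - pos[1L]
  total <- max(travel)
  if (total < 10) return(0)              # no appreciable spread
  keep <- which(travel >= 0.2 * total & travel <= 0.8 * total &
                  pos < n - 5)
  if (length(keep) < 3L) return(0)
  unname(stats::coef(stats::lm(pos[keep] * spacing ~ times[keep]))[2L])
}

#' Measured speed and range against clamped inhibition
#'
#' For each level in `r0_grid`, runs a deterministic 1D simulation with
#' the STEN inhibitor clamped at that level, triggers a wave at the left
#' edge, and measures the front speed (half-maximum crossing position
#' regressed on time over the middle 60% of the transit) and the range
#' (distance from the trigger to the last point whose peak activation
#' reached 10% of the global peak).  Entries outside the bistable
#' window, or beyond the stopping level, report speed 0.
#'
#' @param p a [ModelParams-class] (its STEN is scanned; noise and
#'   coupling are switched off for the scan).
#' @param r0_grid inhibition levels to scan.
#' @param n 1D grid size.
#' @param spacing 1D grid step; theory runs use a fine grid (0.25) so
#'   that slow fronts are not pinned by the lattice.
#' @param duration simulated time per level.
#' @return data frame with columns `r0`, `speed`, `range`, `class`.
#' @export
speedThresholdScan <- function(p, r0_grid, n = 600, spacing = 0.25,
                               duration = 250) {
  stopifnot(is(p, "ModelParams"))
  cm <- .cubic_minimum(p@sten)
  rs <- rStop(p@sten)
  out <- lapply(r0_grid, function(r0) {
    rts <- tryCatch(nullclineRoots(r0, p@sten), error = function(e) numeric(0))
    if (length(rts) < 3L) {
      cls <- if (r0 < cm[["R"]]) "synchronous-oscillation" else "no-spread"
      return(data.frame(r0 = r0, speed = 0, range = 0, class = cls))
    }
    traj <- .clamped_run(p, r0, n = n, spacing = spacing, duration = duration)
    level <- (rts[1L] + rts[3L]) / 2
    pos <- .front_positions(traj, level)
    spd <- .front_speed(pos, traj@times, traj@grid@spacing, n)
    peak <- do.call(pmax, lapply(traj@frames, `[[`, "F_S"))
    gpk <- max(peak)
    rng_ix <- which(peak >= 0.1 * gpk)
    rng <- if (length(rng_ix)) (max(rng_ix) - 3) * traj@grid@spacing else 0
    cls <- if (spd > 0) "excitable-waves" else "no-spread"
    data.frame(r0 = r0, speed = max(0, spd), range = max(0, rng), class = cls)
  })
  do.call(rbind, out)
}

#' Simulated stall level of a clamped 1D front
#'
#' Bisection over the clamped inhibition level of the sign of the
#' measured front displacement: above the stall level the triggered
#' excitation retreats, below it the front advances.  This is the
#' simulation-side counterpart of the analytic [rStop()].
#'
#' @param p a [ModelParams-class].
#' @param n 1D grid size.
#' @param spacing 1D grid step.
#' @param duration observation time per probe run.
#' @param tol bisection tolerance on the inhibition level.
#' @return the stall level.
#' @export
simulatedStallLevel <- function(p, n = 600, spacing = 0.25, duration = 150,
                                tol = NULL) {
  win <- bistableWindow(p@sten)
  if (is.null(tol)) tol <- 0.005 * diff(win)
  advances <- function(r0) {
    traj <- .clamped_run(p, r0, n = n, spacing = spacing,
                         duration = duration,
                         save_interval = duration / 10)
    rts <- nullclineRoots(r0, p@sten)
    level <- (rts[1L] + rts[3L]) / 2
    pos <- .front_positions(traj, level)
    tail(pos, 1L) - pos[2L] > 5      # net forward motion of the front
  }
  lo <- win[1L] + 0.02 * diff(win)
  hi <- win[2L] - 0.02 * diff(win)
  if (!advances(lo)) stop("front does not advance even at low inhibition")
  if (advances(hi)) return(unname(hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (advances(mid)) lo <- mid else hi <- mid
  }
  unname((lo + hi) / 2)
}
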