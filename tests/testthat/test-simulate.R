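test_that("discrete Laplacian reproduces its stencil identities", {
  g1 <- gridSpec(12)
  expect_equal(laplacianField(rep(3.7, 12), g1), rep(0, 12))
  x <- (1:12)^2
  expect_equal(laplacianField(x, g1)[2:11], rep(2, 10))
  # periodic sine mode is an eigenvector with eigenvalue -(2 - 2 cos k)/h^2
  n <- 32; k <- 2 * pi * 3 / n
  gp <- gridSpec(n, boundary = "periodic")
  s <- sin(k * (0:(n - 1)))
  expect_equal(laplacianField(s, gp), -(2 - 2 * cos(k)) * s,
               tolerance = 1e-12)
  g2 <- gridSpec(c(6, 5))
  expect_equal(laplacianField(matrix(1, 5, 6), g2), matrix(0, 5, 6))
  expect_error(laplacianField(matrix(1, 4, 4), g2), "shape")
  # 2D quadratic: interior Laplacian of x^2 + y^2 is 4
  xg <- matrix(1:6, 5, 6, byrow = TRUE); yg <- matrix(1:5, 5, 6)
  l <- laplacianField(xg^2 + yg^2, g2)
  expect_equal(l[2:4, 2:5], matrix(4, 3, 4))
})

test_that("stability bound excludes the globally-mixed species", {
  p <- modelParams()
  g <- gridSpec(c(10, 10))
  expect_equal(stableStep(p, g), 1 / (4 * p@sten@d_rs))
  expect_error(stepFields(initialState(p, g), p, 1), "stability")
})

test_that("noise-free stepping holds the resting state and equal RNG
          tokens reproduce bit-identical trajectories", {
  p <- quiet_params()
  g <- gridSpec(c(8, 8))
  st <- initialState(p, g, seed = 4L)
  s1 <- stepFields(st, p, 0.05)
  for (nm in names(st@fields))
    expect_equal(s1@fields[[nm]], st@fields[[nm]], tolerance = 1e-9)
  # stochastic model: identical rng_state => identical update
  pn <- modelParams()
  a <- stepFields(stepFields(st, pn, 0.05), pn, 0.05)
  b <- stepFields(stepFields(st, pn, 0.05), pn, 0.05)
  expect_identical(a@fields, b@fields)
})

test_that("mean stochastic increment matches the deterministic rate", {
  # a 1D grid of iid sites at a common state gives 10^4 replicates of
  # one Euler-Maruyama increment in a single step
  p <- modelParams(d_fs = 0, d_rs = 0, d_fc = 0, d_rc = 0, d_zc = 0)
  n <- 10000L
  g <- gridSpec(n)
  st <- initialState(p, g, seed = 9L)
  f0 <- 0.8; r0 <- 0.4
  st@fields$F_S[] <- f0
  st@fields$R_S[] <- r0
  dt <- 0.05
  s1 <- stepFields(st, p, dt)
  inc <- s1@fields$F_S - f0
  det <- stenRates(f0, r0, 0, p@sten)$df * dt
  sig <- noiseSigma(st@fields$Z_C[1L], st@fields$W_C[1L], p@sten)
  se <- sig * sqrt(dt) / sqrt(n)
  expect_lt(abs(mean(inc) - det), 3 * se)
})

test_that("triggering is all-or-nothing in a quiet 1D medium", {
  p <- quiet_params()
  eq <- equilibriumState(p@sten)
  rts <- nullclineRoots(eq[["R"]], p@sten)
  th_amp <- rts[2L] - eq[["F"]]
  # sub-threshold: activity decays, nothing propagates
  sub <- triggered_run_1d(p, n = 200, amplitude = 0.5 * th_amp,
                          duration = 60)
  peaks <- vapply(sub@frames, function(fr) max(fr$F_S), numeric(1))
  expect_lt(max(peaks[-1L]), eq[["F"]] + th_amp)
  expect_equal(max(front_trace(sub, 1)), 0)
  # supra-threshold: the front crosses at least half the domain
  sup <- triggered_run_1d(p, n = 200, amplitude = 2, duration = 120)
  expect_gte(max(front_trace(sup, 1)), 100)
})

test_that("colliding fronts annihilate", {
  p <- quiet_params()
  g <- gridSpec(300, spacing = 0.25)
  st <- initialState(p, g, seed = 1L)
  st <- triggerWave(st, 50, 2, radius = 4)
  st <- triggerWave(st, 250, 2, radius = 4)
  tr <- runSimulation(p, g, duration = 120, save_interval = 2, seed = 1L,
                      init = st, save_fields = "F_S")
  peaks <- vapply(tr@frames, function(fr) max(fr$F_S), numeric(1))
  pulse_peak <- max(peaks)
  expect_gt(pulse_peak, 1.5)
  # after the collision the medium is refractory and activity is gone
  expect_lt(min(peaks[-1L]), 0.1 * pulse_peak)
  expect_lt(max(peaks[(length(peaks) - 5L):length(peaks)]), 0.1 * pulse_peak)
})

test_that("a site is refractory right after a pulse and recovers later", {
  p <- quiet_params()
  g <- gridSpec(1)                       # reaction-only single site
  eq <- equilibriumState(p@sten)
  rts <- nullclineRoots(eq[["R"]], p@sten)
  run_from <- function(st, dur) {
    tr <- runSimulation(p, g, dur, save_interval = 0.5, seed = 1L, init = st,
                        save_fields = c("F_S", "R_S"))
    tr
  }
  st <- initialState(p, g, seed = 1L)
  st <- triggerWave(st, 1, 2, radius = 0)
  tr1 <- run_from(st, 30)
  last <- tr1@frames[[length(tr1@frames)]]
  # within the refractory window: re-trigger fails to fire
  st2 <- new("FieldState", t = 0, fields = list(
    F_S = last$F_S + 2, R_S = last$R_S,
    F_C = st@fields$F_C, R_C = st@fields$R_C,
    Z_C = st@fields$Z_C, W_C = st@fields$W_C), grid = g,
    rng_state = st@rng_state)
  tr2 <- run_from(st2, 40)
  peaks2 <- vapply(tr2@frames[-1L], function(fr) max(fr$F_S), numeric(1))
  expect_lt(max(peaks2), last$F_S[1L] + 2.5)   # no regenerative excursion
  # after full recovery the same trigger fires again
  tr3 <- run_from(st2, 200)
  lastr <- tr3@frames[[length(tr3@frames)]]
  expect_lt(abs(lastr$R_S[1L] - eq[["R"]]), 0.01)
  st4 <- new("FieldState", t = 0, fields = list(
    F_S = lastr$F_S + 2, R_S = lastr$R_S,
    F_C = st@fields$F_C, R_C = st@fields$R_C,
    Z_C = st@fields$Z_C, W_C = st@fields$W_C), grid = g,
    rng_state = st@rng_state)
  tr4 <- run_from(st4, 40)
  peaks4 <- vapply(tr4@frames[-1L], function(fr) max(fr$F_S), numeric(1))
  # regenerative excursion: activity grows well beyond the trigger
  expect_gt(max(peaks4), lastr$F_S[1L] + 2 + 0.5)
})

test_that("parameter ramps interpolate linearly over their window", {
  p <- modelParams()
  sch <- perturbationSchedule("sten.a3s", start = 50, target = 6)
  v0 <- modelParam(p, "sten.a3s")
  expect_equal(modelParam(rampParameter(p, sch, 10), "sten.a3s"), v0)
  expect_equal(modelParam(rampParameter(p, sch, 55), "sten.a3s"),
               (v0 + 6) / 2)
  expect_equal(modelParam(rampParameter(p, sch, 61), "sten.a3s"), 6)
  expect_equal(modelParam(rampParameter(p, sch, 1e6), "sten.a3s"), 6)
  expect_error(perturbationSchedule("sten.bogus", 0, 1), "unknown")
  expect_error(perturbationSchedule("sten.a3s", 0, 1, duration = 0))
})

test_that("presets are complete runnable configurations", {
  for (nm in c("inp54p", "ras", "pkba", "racgef1", "lata",
               "fig3-wave-stopping")) {
    pr <- perturbationPreset(nm)
    expect_s4_class(pr$params, "ModelParams")
    expect_s4_class(pr$grid, "GridSpec")
    if (!is.null(pr$schedule))
      expect_true(all(c("path", "start", "target", "duration") %in%
                        names(pr$schedule)))
  }
  fig3 <- perturbationPreset("fig3-wave-stopping")
  expect_equal(fig3$params@sten@eps_s, 0.03)
  expect_equal(fig3$grid@shape, 3000L)
  expect_error(perturbationPreset("nope"))
})

test_that("runs are reproducible, duration 0 returns the initial state,
          and the global inhibitor stays spatially uniform", {
  p <- modelParams()
  g <- gridSpec(c(24, 24))
  t1 <- runSimulation(p, g, duration = 10, save_interval = 2, seed = 7L)
  t2 <- runSimulation(p, g, duration = 10, save_interval = 2, seed = 7L)
  expect_identical(t1@frames, t2@frames)
  t3 <- runSimulation(p, g, duration = 10, save_interval = 2, seed = 8L)
  expect_false(identical(t1@frames, t3@frames))
  t0 <- runSimulation(p, g, duration = 0, save_interval = 1, seed = 7L)
  expect_length(t0@frames, 1L)
  for (fr in t1@frames) {
    w <- fr$W_C
    expect_lt(max(w) - min(w), 0.01 * max(mean(w), 1e-12))
  }
})

test_that("decoupling the networks leaves CEN with only short-range
          noise-driven firings", {
  p <- modelParams(s_c = 0)
  g <- gridSpec(c(60, 60))
  tr <- runSimulation(p, g, duration = 60, save_interval = 3, seed = 21L)
  # spatial autocorrelation length of the CEN activator fluctuations
  corr_at_lag <- function(m, lag) {
    a <- m - mean(m)
    nc <- ncol(a)
    num <- mean(a[, 1:(nc - lag)] * a[, (1 + lag):nc])
    num / mean(a^2)
  }
  lags <- 1:6
  ac <- sapply(tr@frames[-(1:2)], function(fr)
    vapply(lags, function(l) corr_at_lag(fr$F_C, l), numeric(1)))
  mean_ac <- rowMeans(ac)
  corr_len <- lags[which(mean_ac < exp(-1))][1L]
  expect_lt(corr_len, 3)
  # and CEN activity is present but spatially confined
  expect_gt(max(vapply(tr@frames, function(fr) max(fr$F_C), numeric(1))), 1)
})

test_that("readout normalisation is invertible and a stalling wave
          kymograph decelerates", {
  p <- modelParams()
  g <- gridSpec(c(30, 20))
  tr <- runSimulation(p, g, duration = 20, save_interval = 4, seed = 3L)
  m <- extractReadout(tr, channels = c("R_S", "R_C"))
  n <- tr@norm$R_S
  raw <- m@pixels[, , 2, 1] * (n$hi - n$lo) + n$lo
  expect_equal(raw, tr@frames[[2]]$R_S, tolerance = 1e-12)
  # 1D triggered wave: the front advance per save interval shrinks as it
  # approaches its finite range (curving kymograph trace)
  tr1 <- triggered_run_1d(quiet_params(), n = 300, spacing = 1,
                          duration = 250, save_interval = 10)
  fp <- front_trace(tr1, 1)
  adv <- diff(fp[fp > 0])
  expect_gt(adv[1L], tail(adv, 1L))        # the front decelerates
  expect_equal(tail(fp, 1L), 0)            # and the pulse terminates
  # kymograph extraction along the 1D line matches the saved fields
  k <- extractReadout(tr1, channels = "F_S", line = c(1, 300))
  expect_equal(dim(k), c(300L, length(tr1@times)))
})

test_that("the CEN input-profile hook drives CEN without STEN", {
  p <- modelParams(u_b = 0, sigma_c = 0, s_c = 0)
  g <- gridSpec(c(20, 20))
  base <- runSimulation(p, g, duration = 15, save_interval = 3, seed = 2L)
  fc0 <- max(vapply(base@frames, function(fr) max(fr$F_C), numeric(1)))
  drv <- runSimulation(p, g, duration = 15, save_interval = 3, seed = 2L,
                       s_in_fn = function(t) if (t > 2) 1.5 else 0)
  fc1 <- max(vapply(drv@frames, function(fr) max(fr$F_C), numeric(1)))
  expect_lt(fc0, 0.1)
  expect_gt(fc1, 0.5)                      # the hook fires the CEN
})
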