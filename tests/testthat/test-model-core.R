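test_that("STEN and CEN reaction rates match an independent term-by-term
          re-derivation at random points", {
  set.seed(42)
  ps <- stenParams()
  pc <- cenParams()
  for (i in 1:1000) {
    f <- runif(1, 0, 5); r <- runif(1, 0, 3); u <- rnorm(1)
    got <- stenRates(f, r, u, ps)
    # independent form: decay, Hill and source terms computed separately
    hill <- ps@a3s / (1 + (ps@a4s / f)^2)
    exp_df <- ps@a5s + hill - ps@a1s * f - ps@a2s * r * f + u
    exp_dr <- ps@eps_s * ps@c1s * f - ps@eps_s * r
    expect_lt(abs(got$df - exp_df), 1e-10 * max(1, abs(exp_df)))
    expect_lt(abs(got$dr - exp_dr), 1e-10 * max(1, abs(exp_dr)))
    s_in <- rnorm(1)
    gotc <- cenRates(f, r, s_in, pc)
    hillc <- pc@a3c / (1 + (pc@a4c / f)^2)
    exp_dfc <- pc@a5c + hillc - pc@a1c * f - pc@a2c * (r - s_in) * f
    expect_lt(abs(gotc$df - exp_dfc), 1e-10 * max(1, abs(exp_dfc)))
  }
})

test_that("rate functions honour their boundary examples", {
  ps <- stenParams()
  expect_equal(stenRates(0, 0, 0, ps), list(df = ps@a5s, dr = 0))
  r <- stenRates(ps@a4s, 0, 0, ps)
  expect_equal(r$df, -ps@a1s * ps@a4s + ps@a3s / 2 + ps@a5s)
  expect_equal(r$dr, ps@eps_s * ps@c1s * ps@a4s)
  pc <- cenParams()
  expect_equal(cenRates(0, 0, 0, pc)$df, pc@a5c)
  # only the difference R_C - s_in enters the activator rate
  expect_equal(cenRates(1.3, 0.7, 0.7, pc)$df, cenRates(1.3, 0, 0, pc)$df)
  expect_error(stenRates(NaN, 0, 0, ps), "non-finite")
  expect_error(cenRates(0, Inf, 0, pc), "non-finite")
})

test_that("resting equilibrium of the defaults is a genuine fixed point", {
  ps <- stenParams()
  eq <- equilibriumState(ps)
  r <- stenRates(eq[["F"]], eq[["R"]], 0, ps)
  expect_lt(abs(r$df), 1e-9)
  expect_lt(abs(r$dr), 1e-9)
  # the shipped r0 is that equilibrium inhibition level
  expect_equal(ps@r0, eq[["R"]], tolerance = 1e-9)
})

test_that("feedback kinetics: steady states, gain ratio and pure decay", {
  p <- feedbackParams()
  f_c <- 1.7
  expect_equal(feedbackRates(p@p2 / p@p1 * f_c, 1, f_c, p)$dz, 0)
  # constant F_C = 1: integrate both loops to steady state and compare
  z <- 0; w <- 0; dt <- 0.01
  for (i in 1:40000) {
    rr <- feedbackRates(z, w, 1, p)
    z <- z + dt * rr$dz; w <- w + dt * rr$dw
  }
  expect_equal(w / z, 2, tolerance = 1e-3)
  r <- feedbackRates(0.5, 0.8, 0, p)
  expect_lt(r$dz, 0)
  expect_lt(r$dw, 0)
})

test_that("shipped defaults satisfy the structural ratios and are excitable", {
  p <- modelParams()
  expect_identical(p@cen@eps_c / p@sten@eps_s, 8)
  expect_identical((p@feedback@p4 / p@feedback@p3) /
                     (p@feedback@p2 / p@feedback@p1), 2)
  expect_true(isExcitable(p@sten))
  expect_true(isExcitable(p@cen))
})

test_that("supra-threshold perturbation produces a large excursion that
          returns to rest (reaction-only dynamics)", {
  ps <- stenParams()
  eq <- equilibriumState(ps)
  rts <- nullclineRoots(eq[["R"]], ps)
  expect_length(rts, 3L)
  dF <- 1.5 * (rts[2L] - eq[["F"]])       # safely supra-threshold
  f <- eq[["F"]] + dF; r <- eq[["R"]]; peak <- f
  dt <- 2e-3
  for (i in seq_len(400 / dt)) {
    rr <- stenRates(f, r, 0, ps)
    f <- f + dt * rr$df; r <- r + dt * rr$dr
    peak <- max(peak, f)
  }
  expect_gt((peak - eq[["F"]]) / dF, 5)
  expect_lt(abs(f - eq[["F"]]), 1e-3)
  # sub-threshold decays monotonically back without an excursion
  f <- eq[["F"]] + 0.5 * (rts[2L] - eq[["F"]]); r <- eq[["R"]]; peak <- f
  for (i in seq_len(100 / dt)) {
    rr <- stenRates(f, r, 0, ps)
    f <- f + dt * rr$df; r <- r + dt * rr$dr
    peak <- max(peak, f)
  }
  expect_lt(peak, eq[["F"]] + 1.01 * 0.5 * (rts[2L] - eq[["F"]]))
})

test_that("coupling drive is the stated linear map", {
  pc <- cenParams()
  r0 <- stenParams()@r0
  expect_equal(couplingInput(r0, pc, r0), 0)
  expect_equal(couplingInput(r0 + 1, cenParams(s_c = 0.5), r0), 0.5)
  expect_equal(couplingInput(c(0, 5, 9), cenParams(s_c = 0), r0), c(0, 0, 0))
})

test_that("noise amplitude is u_b + Z - W clamped at zero", {
  expect_equal(noiseSigma(0.7, 0.7, stenParams(u_b = 0.3)), 0.3)
  expect_equal(noiseSigma(0.5, 0.3, stenParams(u_b = 0.2)), 0.4)
  expect_equal(noiseSigma(0, 0.5, stenParams(u_b = 0.1)), 0)
  expect_equal(noiseSigma(c(0, 1), c(0.5, 0), stenParams(u_b = 0.1)),
               c(0, 1.1))
})

test_that("nullcline roots agree with a brute-force sign-change scan", {
  ps <- stenParams()
  win <- bistableWindow(ps)
  scan_roots <- function(r, p) {
    k <- list(a1 = p@a1s, a2 = p@a2s, a3 = p@a3s, a4 = p@a4s, a5 = p@a5s)
    fg <- seq(1e-6, 10, by = 1e-4)
    v <- -(k$a1 + k$a2 * r) * fg + k$a3 * fg^2 / (k$a4^2 + fg^2) + k$a5
    ix <- which(diff(sign(v)) != 0)
    (fg[ix] + fg[ix + 1L]) / 2
  }
  for (r in c(0.1, 0.3, 0.8, 1.2, 1.49, 2, 4)) {
    got <- nullclineRoots(r, ps)
    ref <- scan_roots(r, ps)
    expect_length(got, length(ref))
    if (length(got)) expect_lt(max(abs(got - ref)), 2e-4)
    # each root is a true zero of the rate
    for (f in got) expect_lt(abs(stenRates(f, r, 0, ps)$df), 1e-8)
  }
  expect_length(nullclineRoots(10, ps), 1L)   # far above the fold
  rmid <- mean(win)
  expect_length(nullclineRoots(rmid, ps), 3L)
})

test_that("configuration files round-trip and reject unknown keys", {
  p <- modelParams(a3s = 4.7, sigma_c = 0.31)
  f <- tempfile(fileext = ".cfg")
  writeModelConfig(p, f)
  q <- readModelConfig(f)
  expect_equal(modelParam(q, "sten.a3s"), 4.7)
  expect_equal(modelParam(q, "cen.sigma_c"), 0.31)
  expect_equal(q@feedback@d_wc, p@feedback@d_wc)
  writeLines(c("a3s = 4", "bogus_key = 1"), f)
  expect_error(readModelConfig(f), "unknown parameter")
  writeLines(c("a3s = not_a_number"), f)
  expect_error(readModelConfig(f), "non-numeric")
})

test_that("parameter paths resolve and validate", {
  p <- modelParams()
  expect_equal(modelParam(p, "sten.a3s"), modelParam(p, "a3s"))
  modelParam(p, "cen.a3c") <- 6
  expect_equal(p@cen@a3c, 6)
  expect_error(modelParam(p, "sten.nope"), "unknown parameter")
  expect_error(modelParam(p, "cen.a3s"), "unknown parameter")
  expect_error({modelParam(p, "sten.eps_s") <- -1})
})
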