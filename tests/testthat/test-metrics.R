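test_that("moving-average smoothing: constant, impulse, identity and
          argument validation", {
  expect_equal(smoothProfile(rep(2, 40)), rep(2, 40))
  imp <- c(rep(0, 30), 1, rep(0, 30))
  sm <- smoothProfile(imp, 19L)
  expect_equal(sm[(31 - 9):(31 + 9)], rep(1 / 19, 19))
  expect_equal(sm[31 + 10], 0)
  x <- rnorm(25)
  expect_equal(smoothProfile(x, 1L), x)
  expect_error(smoothProfile(x, 4L), "odd")
  expect_error(smoothProfile(x, 27L), "odd|length")
})

test_that("peak distance recovers constructed offsets with the stated
          sign convention and is antisymmetric", {
  x <- 1:100
  a <- dnorm(x, 50, 5); b <- dnorm(x, 45, 5)
  expect_equal(peakDistance(a, a, 0.5), 0)
  expect_equal(peakDistance(a, b, 0.5, direction = 1), 2.5)
  expect_equal(peakDistance(a, b, 0.5, direction = -1), -2.5)
  set.seed(1)
  for (i in 1:20) {
    u <- runif(80); v <- runif(80)
    expect_equal(peakDistance(u, v, 1), -peakDistance(v, u, 1))
  }
  expect_warning(peakDistance(rep(1, 50), rep(2, 50), 1), "flat")
  expect_error(peakDistance(a, b[1:50], 1), "equal length")
})

test_that("wave-front segmentation thresholds, filters small objects and
          labels with 8-connectivity", {
  expect_equal(max(segmentWavefronts(matrix(0.5, 20, 20) +
                                       matrix(rnorm(400, 0, 1e-3), 20))), 0L)
  fr <- matrix(0, 40, 40)
  fr[5:10, 5:20] <- 1       # band 1
  fr[25:30, 10:30] <- 1     # band 2
  lab <- segmentWavefronts(fr)
  expect_equal(max(lab), 2L)
  # diagonal-touching blocks are one 8-connected object
  dg <- matrix(0, 20, 20)
  dg[2:5, 2:5] <- 1
  dg[6:9, 6:9] <- 1
  expect_equal(max(segmentWavefronts(dg, min_size = 1L)), 1L)
  # objects below min_size are removed
  sp <- matrix(0, 30, 30); sp[3:4, 3:4] <- 1; sp[20:25, 20:25] <- 1
  expect_equal(max(segmentWavefronts(sp, min_size = 9L)), 1L)
  # area of a synthetic band is recovered within 10%
  band <- matrix(0, 60, 60)
  band[20:29, 10:49] <- 1   # 10 x 40 = 400 px
  lab <- segmentWavefronts(band)
  expect_lt(abs(sum(lab > 0) - 400) / 400, 0.1)
})

test_that("patch statistics count and measure components", {
  empty <- matrix(0L, 10, 10)
  ps <- patchStats(list(empty))
  expect_equal(ps$count, 0)
  expect_true(is.nan(ps$mean_area[1L]))
  m <- matrix(0L, 20, 20)
  m[1:2, 1:5] <- 1L          # 10 px
  m[5:8, 1:5] <- 2L          # 20 px
  m[12:17, 1:5] <- 3L        # 30 px
  ps <- patchStats(list(m))
  expect_equal(ps$count, 3)
  expect_equal(ps$mean_area, 20)
  # agreement with direct enumeration on random rectangles
  set.seed(7)
  for (i in 1:5) {
    mm <- matrix(0L, 50, 50)
    n_rect <- sample(2:5, 1)
    areas <- integer(0)
    for (j in seq_len(n_rect)) {
      r0 <- 1 + 12 * (j - 1); w <- sample(2:4, 1); h <- sample(3:6, 1)
      mm[r0:(r0 + w - 1), 5:(5 + h - 1)] <- j
      areas <- c(areas, w * h)
    }
    ps <- patchStats(list(mm))
    expect_equal(ps$count, n_rect)
    expect_equal(ps$mean_area, mean(areas))
  }
})

test_that("wave speed: static bands report zero, uniform translation is
          measured exactly, and intensity rescaling changes nothing", {
  static <- band_movie(rep(0, 20), frame_interval = 15)
  sr <- waveSpeed(static)
  expect_equal(sum(sr@accepted_count), 0)
  expect_equal(sr@video_mean_speed, 0)
  mv <- band_movie(rep(2, 30), n_x = 200, frame_interval = 15)
  sr <- waveSpeed(mv)
  expect_equal(sr@video_mean_speed, 2 / 15, tolerance = 1e-9)
  expect_true(all(abs(sr@mean_speed - 2 / 15) < 1e-9))
  mv2 <- mv
  mv2@pixels <- mv2@pixels * 37 + 0
  sr2 <- waveSpeed(mv2)
  expect_equal(sr2@video_mean_speed, sr@video_mean_speed)
  expect_equal(sr2@fraction_fastest, sr@fraction_fastest)
  expect_error(waveSpeed(band_movie(numeric(0))), "2 frames")
})

test_that("fraction of fastest pixels matches the ground-truth tail of a
          jittered displacement sequence", {
  set.seed(5)
  disp <- pmax(1, pmin(4, round(rnorm(120, 2.4, 0.8))))
  mv <- band_movie(disp, n_x = 420)
  sr <- waveSpeed(mv)
  expect_gte(sr@fraction_fastest, 0)
  expect_lte(sr@fraction_fastest, 1)
  # oracle: per-frame edge displacements are the programmed ones; the
  # edge pixel counts are equal per frame, so the pixel-weighted tail
  # equals the frame-weighted tail of the programmed sequence
  realised <- diff(round(10 + c(0, cumsum(disp))))
  tail_frac <- mean(realised >= mean(realised) + sd(realised))
  expect_lt(abs(sr@fraction_fastest - tail_frac), 0.06)
  # and the speed recovers the mean programmed displacement
  expect_equal(sr@video_mean_speed, mean(realised), tolerance = 0.05)
})

test_that("before/after reports window correctly and detect a speed
          doubling", {
  disp <- c(rep(1.5, 34), rep(3, 70))
  mv <- band_movie(disp, n_x = 420)
  rep <- beforeAfterReport(mv, event_frame = 35)
  ratio <- rep$after@video_mean_speed / rep$before@video_mean_speed
  expect_lt(abs(ratio - 2), 0.3)
  # stationary statistics: both windows agree
  mv2 <- band_movie(rep(2, 104), n_x = 420)
  rep2 <- beforeAfterReport(mv2, event_frame = 35)
  expect_equal(rep2$before@video_mean_speed, rep2$after@video_mean_speed,
               tolerance = 1e-9)
  expect_error(beforeAfterReport(mv, event_frame = 10), "insufficient")
})

test_that("puncta lifetimes: deterministic tracks measured exactly", {
  n_t <- 30
  px <- array(0, c(40, 40, n_t, 1))
  xg <- matrix(1:40, 40, 40, byrow = TRUE); yg <- matrix(1:40, 40, 40)
  blob <- function(x, y) exp(-((xg - x)^2 + (yg - y)^2) / (2 * 1.5^2))
  for (i in 5:15) px[, , i, 1] <- pmax(px[, , i, 1], blob(10, 10))
  for (i in 12:12) px[, , i, 1] <- pmax(px[, , i, 1], blob(30, 30))
  mv <- new("WaveMovie", pixels = px, pixel_size = 1, frame_interval = 1,
            channels = "puncta")
  lt <- punctaLifetime(mv, link_dist = 2)
  expect_setequal(lt, c(11, 1))
  mv@frame_interval <- 2.5
  expect_setequal(punctaLifetime(mv, link_dist = 2), c(27.5, 2.5))
})

test_that("kymograph extraction samples lines faithfully", {
  px <- array(0, c(20, 30, 4, 1))
  for (i in 1:4) px[, , i, 1] <- matrix(seq_len(30) + i, 20, 30,
                                        byrow = TRUE)
  mv <- new("WaveMovie", pixels = px, pixel_size = 1, frame_interval = 1,
            channels = "c")
  k <- kymograph(mv, c(1, 7, 30, 7), n_samples = 30)
  expect_equal(k[, 2], 2 + 1:30)
  const <- mv; const@pixels[] <- 3.3
  kc <- kymograph(const, c(2, 2, 28, 17))
  expect_true(all(abs(kc - 3.3) < 1e-12))
  # a translating band appears as a stripe of the programmed slope
  mvb <- band_movie(rep(2, 25), n_x = 120, n_y = 10)
  kb <- kymograph(mvb, c(1, 5, 120, 5), n_samples = 120)
  pos <- apply(kb, 2, which.max)
  expect_equal(unname(diff(pos)), rep(2, 25))
  expect_error(kymograph(mv, c(0, 5, 31, 5)), "outside")
})

test_that("wave movies round-trip through multi-page TIFF", {
  spec <- syntheticWaveSpec(duration = 30, noise_sd = 0.02, seed = 2L)
  mv <- synthWaveMovie(spec)$movie
  d <- tempfile()
  writeWaveMovie(mv, d, "probe")
  back <- readWaveMovie(d, "probe")
  expect_equal(back@pixel_size, mv@pixel_size)
  expect_equal(back@frame_interval, mv@frame_interval)
  expect_equal(back@channels, mv@channels)
  expect_lt(max(abs(back@pixels - mv@pixels)), 1e-6)
  k <- kymograph(mv, c(1, 10, 120, 10))
  f <- tempfile(fileext = ".tsv")
  writeKymograph(k, f)
  expect_equal(unname(as.matrix(utils::read.table(f, sep = "\t"))),
               unname(k), tolerance = 1e-12)
})
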