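test_that("avatar spec validates pitch range and bandwidth ladder", {
  expect_error(avatar_spec(100), "pitch")
  expect_error(avatar_spec(20000), "pitch")
  expect_error(avatar_spec(1000, bandwidth = 0.7), "ladder")
  expect_s3_class(avatar_spec(1000, 1 / 24), "snn_avatar_spec")
})

test_that("bandwidth 0 yields a pure tone at the pitch", {
  w <- synthesize_avatar(avatar_spec(1000, 0, level = 0.1), rate = 8000,
                         duration = 1)
  mono <- rowSums(w)
  sp <- Mod(fft(mono))^2
  f <- (seq_along(sp) - 1) * 8000 / length(sp)
  f <- pmin(f, 8000 - f)
  expect_gt(sum(sp[abs(f - 1000) <= 5]) / sum(sp), 0.99)
})

test_that("positive bandwidth gives a band centred geometrically on the pitch", {
  w <- synthesize_avatar(avatar_spec(1000, 1, level = 0.1), rate = 8000,
                         duration = 4, seed = 2)
  mono <- rowSums(w)
  sp <- Mod(fft(mono))^2
  n <- length(sp)
  f <- (seq_len(n) - 1) * 8000 / n
  half <- f <= 4000
  in_band <- sum(sp[half & f >= 1000 * 2^-0.5 - 5 & f <= 1000 * 2^0.5 + 5])
  expect_gt(in_band / sum(sp[half]), 0.999)
  # spectral centroid of log-frequency close to the pitch
  centroid <- exp(sum(log(f[half & f > 0]) * sp[half & f > 0]) /
                    sum(sp[half & f > 0]))
  expect_equal(centroid, 1000, tolerance = 0.05)
})

test_that("level scales RMS linearly and total RMS matches the level", {
  w1 <- synthesize_avatar(avatar_spec(500, 0, level = 0.1), 8000, 0.5)
  w2 <- synthesize_avatar(avatar_spec(500, 0, level = 0.2), 8000, 0.5)
  rms <- function(w) sqrt(mean(rowSums(as.matrix(w)^2)))
  expect_equal(rms(w2) / rms(w1), 2, tolerance = 0.01)
  expect_equal(rms(w1), 0.1, tolerance = 0.01)
})

test_that("acute schedule holds 90/50/10 percent at the checkpoints", {
  sch <- acute_schedule()
  expect_equal(schedule_ratio(sch, 300), 0.90)
  expect_equal(schedule_ratio(sch, 1800), 0.50)
  expect_equal(schedule_ratio(sch, 3500), 0.10)
  expect_equal(sch$duration, 3600)
})

test_that("chronic ladder spans 100 percent avatar down to pure environment", {
  schs <- chronic_schedules()
  expect_length(schs, 4)
  expect_true(all(schedule_ratio(schs[[1]], c(0, 1000, 3600)) == 1))
  expect_equal(schedule_ratio(schs[[3]], 0), 0.5)
  expect_equal(schedule_ratio(schs[[3]], 3600), 0.1)
  expect_equal(schedule_ratio(schs[[4]], 3600), 0.0)
  # continuity within each file
  for (s in schs) {
    tt <- seq(0, 3600, by = 10)
    r <- schedule_ratio(s, tt)
    expect_true(all(abs(diff(r)) < 0.01))
  }
})

test_that("schedules must tile the duration", {
  expect_error(morph_schedule(10, data.frame(start = c(0, 6), end = c(5, 10),
                                             r0 = 0.5, r1 = 0.5,
                                             interp = "constant")),
               "tile")
  expect_error(morph_schedule(10, data.frame(start = 0, end = 10, r0 = 1.5,
                                             r1 = 0, interp = "linear")),
               "\\[0, 1\\]")
})

test_that("render_morph is exact at r = 1 and splits power at r = 0.5", {
  rate <- 2048
  a <- band_filter(with_seed(1, rnorm(rate * 20)), rate, 200, 400)
  e <- band_filter(with_seed(2, rnorm(rate * 20)), rate, 30, 120)
  st <- equalize_rms(a, e, rms = 0.1)
  one <- morph_schedule(20, data.frame(start = 0, end = 20, r0 = 1, r1 = 1,
                                       interp = "constant"))
  half <- morph_schedule(20, data.frame(start = 0, end = 20, r0 = 0.5,
                                        r1 = 0.5, interp = "constant"))
  expect_equal(max(abs(render_morph(st[[1]], st[[2]], one, rate) - st[[1]])),
               0)
  mix <- render_morph(st[[1]], st[[2]], half, rate)
  share <- avatar_power_share(mix, rate, c(0, 20), c(200, 400), c(30, 120))
  expect_equal(share, 50, tolerance = 2)
})

test_that("morphing conserves total power with equal-RMS disjoint stems", {
  rate <- 1024
  a <- band_filter(with_seed(3, rnorm(rate * 60)), rate, 200, 400)
  e <- band_filter(with_seed(4, rnorm(rate * 60)), rate, 30, 120)
  st <- equalize_rms(a, e, rms = 0.1)
  sch <- morph_schedule(60, data.frame(start = 0, end = 60, r0 = 0.9,
                                       r1 = 0.1, interp = "linear"))
  mix <- render_morph(st[[1]], st[[2]], sch, rate)
  pw <- vapply(seq(0, 50, by = 10), function(t0) {
    seg <- mix[(t0 * rate + 1):((t0 + 10) * rate)]
    mean(seg^2)
  }, numeric(1))
  expect_true(all(abs(pw / mean(pw) - 1) < 0.05))
})

test_that("mismatched stems are rejected", {
  sch <- morph_schedule(1, data.frame(start = 0, end = 1, r0 = 1, r1 = 1,
                                      interp = "constant"))
  expect_error(render_morph(rnorm(100), rnorm(99), sch, 100), "identical")
})

test_that("WAV files round-trip in all three encodings", {
  w <- synthesize_avatar(avatar_spec(440, 0, level = 0.2, balance = -0.5),
                         rate = 8000, duration = 0.25)
  for (bits in c(16, 24, 32)) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(w, path, bits = bits)
    w2 <- read_wav(path)
    expect_equal(attr(w2, "rate"), 8000)
    expect_equal(dim(w2), dim(w))
    tol <- switch(as.character(bits), "16" = 1e-4, "24" = 1e-6, "32" = 1e-6)
    expect_equal(unclass(w2), unclass(w), tolerance = tol,
                 ignore_attr = TRUE)
  }
})
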