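test_that("EDF files round-trip through write_edf / read_edf", {
  set.seed(7)
  data <- matrix(rnorm(4 * 500, sd = 40), 4, 500)
  rec <- eeg_recording(data, fs = 100, labels = c("Fp1", "Fp2", "C3", "C4"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_s3_class(back, "eeg_recording")
  expect_equal(back$labels, rec$labels)
  expect_equal(back$fs, 100)
  expect_equal(dim(back$data), dim(rec$data))
  # 16-bit quantisation bound: half a digital step per channel
  step <- apply(data, 1, function(x) diff(range(x))) / 65535
  for (i in 1:4)
    expect_lt(max(abs(back$data[i, ] - data[i, ])), step[i])
})

test_that("read_edf rejects unreadable or truncated files", {
  expect_error(read_edf(tempfile()), "cannot read")
  empty <- tempfile(fileext = ".edf")
  file.create(empty)
  expect_error(read_edf(empty), "truncated")
})

test_that("recording text container round-trips with montage and areas", {
  g <- make_grid_montage(3, 3)
  rec <- eeg_recording(matrix(rnorm(9 * 50), 9, 50), fs = 120,
                       labels = g$labels, montage = g$montage,
                       areas = list(area1 = g$labels[1:4],
                                    area2 = g$labels[5:9]))
  prefix <- file.path(tempdir(), "rt", "rec")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$montage, rec$montage)
  expect_equal(back$areas, rec$areas)
})

test_that("band-pass plus notch has the designed frequency response", {
  fs <- 1200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(rbind(sin(2 * pi * 50 * t),
                             sin(2 * pi * 10 * t),
                             rep(1, length(t))), fs)
  out <- bandpass_notch(rec)
  expect_lt(rms(mid(out$data[1, ])) / rms(mid(rec$data[1, ])), 0.05)  # notch
  expect_equal(rms(mid(out$data[2, ])) / rms(mid(rec$data[2, ])), 1,
               tolerance = 0.05)                                      # passband
  expect_lt(rms(mid(out$data[3, ])), 0.05)                            # DC
})

test_that("band edge above Nyquist and out-of-band notch are rejected", {
  rec <- eeg_recording(matrix(rnorm(200), 1), fs = 100)
  expect_error(bandpass_notch(rec, band_spec("custom", 0.5, 60)), "Nyquist")
  expect_error(bandpass_notch(rec, band_spec("custom", 0.5, 40), 45, 48),
               "inside the pass band")
})

test_that("filtering twice changes passband content by under 2%", {
  fs <- 600
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  once <- bandpass_notch(rec)
  twice <- bandpass_notch(once)
  expect_equal(rms(mid(twice$data[1, ])), rms(mid(once$data[1, ])),
               tolerance = 0.02)
})

test_that("surface Laplacian annihilates constant fields exactly", {
  rec <- grid_recording(4, 4, 20, fill = function(nch, n) matrix(3, nch, n))
  out <- surface_laplacian(rec)
  complete <- out$meta$laplacian_complete
  expect_equal(sum(complete), 4)          # (4-2)^2 interior channels
  expect_true(all(out$data[complete, ] == 0))
  expect_identical(out$data[!complete, ], rec$data[!complete, ])
})

test_that("surface Laplacian matches the hand arithmetic of one neighbourhood", {
  g <- make_grid_montage(3, 3)
  data <- matrix(1, 9, 1)
  data[5, 1] <- 5                         # centre R2C2; its 4 neighbours are 1
  rec <- eeg_recording(data, fs = 10, labels = g$labels, montage = g$montage)
  out <- surface_laplacian(rec)
  expect_equal(unname(out$data["R2C2", 1]), 4)   # 5 - (1/4)(1+1+1+1)
})

test_that("surface Laplacian equals the brute-force per-sample oracle", {
  rec <- grid_recording(5, 5, 200, seed = 11)
  out <- surface_laplacian(rec)
  expect_lt(max(abs(out$data - laplacian_oracle(rec))), 1e-12)
})

test_that("surface Laplacian is linear on complete-montage channels", {
  rec_x <- grid_recording(5, 5, 50, seed = 1)
  rec_y <- grid_recording(5, 5, 50, seed = 2)
  a <- 2.5; b <- -1.25
  rec_mix <- rec_x
  rec_mix$data <- a * rec_x$data + b * rec_y$data
  lap <- function(r) surface_laplacian(r)$data
  expect_equal(lap(rec_mix), a * lap(rec_x) + b * lap(rec_y),
               tolerance = 1e-12)
})

test_that("surface Laplacian requires a montage", {
  rec <- eeg_recording(matrix(rnorm(40), 2), fs = 10)
  expect_error(surface_laplacian(rec), "montage")
})

test_that("decimation reduces the rate and preserves in-band amplitude", {
  fs <- 1200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  out <- decimate_recording(rec, 120)
  expect_equal(out$fs, 120)
  expect_lte(abs(ncol(out$data) - ncol(rec$data) / 10), 1)
  expect_equal(rms(mid(out$data[1, ])) / rms(mid(rec$data[1, ])), 1,
               tolerance = 0.05)
  expect_error(decimate_recording(rec, 35), "20 Hz")
  expect_error(decimate_recording(rec, 500), "integer")
})
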