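test_that("band-pass keeps the passband and rejects out-of-band tones", {
  rate <- 512
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  rms <- function(x) sqrt(mean(x^2))
  steady <- function(x) x[(length(x) %/% 2):length(x)]
  # passband tone: amplitude preserved within 10%
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_butterworth(x10, rate)
  expect_lt(abs(rms(steady(y10)) / rms(steady(x10)) - 1), 0.10)
  # slow drift strongly attenuated
  x05 <- sin(2 * pi * 0.5 * t)
  y05 <- bandpass_butterworth(x05, rate)
  expect_lt(rms(steady(y05)) / rms(steady(x05)), 0.25)
  # stopband attenuation >= 12 dB at low_cut/2 and 2*high_cut
  for (f in c(3.5 / 2, 60)) {
    y <- bandpass_butterworth(sin(2 * pi * f * t), rate)
    expect_lt(20 * log10(rms(steady(y))), -12)
  }
  expect_equal(bandpass_butterworth(rep(0, 1000), rate), rep(0, 1000))
})

test_that("measured attenuation matches the analytic response within 1 dB", {
  rate <- 512
  spec <- filter_spec()
  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  probes <- c(2, 3.5, 5, 8, 10, 13, 17, 21, 25, 30)
  analytic <- bandpass_response(spec, rate, probes)
  rms <- function(x) sqrt(mean(x^2))
  for (i in seq_along(probes)) {
    x <- sin(2 * pi * probes[i] * t)
    y <- bandpass_butterworth(x, rate, spec)
    sel <- (length(x) %/% 3):length(x)   # discard the transient
    measured_db <- 20 * log10(rms(y[sel]) / rms(x[sel]))
    expect_lt(abs(measured_db - 20 * log10(analytic[i])), 1,
              label = sprintf("probe %g Hz", probes[i]))
  }
})

test_that("cutoffs at or above Nyquist are rejected by name", {
  expect_error(bandpass_butterworth(rnorm(100), 50, filter_spec(3.5, 30)),
               "high_cut")
  expect_error(filter_spec(30, 3.5), "low_cut")
  expect_error(bandpass_butterworth(rnorm(5), 512), "too short")
})

test_that("squaring rectifies and is not idempotent", {
  expect_equal(square_signal(c(-2, 3, 0)), c(4, 9, 0))
  x <- rnorm(100)
  expect_true(all(square_signal(x) >= 0))
  expect_equal(square_signal(square_signal(x)), x^4)
  y <- c(-3, 0.5, 2)
  expect_false(isTRUE(all.equal(square_signal(square_signal(y)),
                                square_signal(y))))
})

test_that("buffered averaging reduces blocks to means and drops the tail", {
  expect_equal(buffered_average(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(buffered_average(rep(7, 96), 32), rep(7, 3))
  expect_length(buffered_average(rnorm(70), 32), 2)
  expect_length(buffered_average(rnorm(31), 32), 0)
  expect_error(buffered_average(1:10, 0), "buffer_size")
  expect_equal(buffered_average(1:9, 3), c(2, 5, 8))
})

test_that("feature tables have the right shape, labels and column order", {
  cfg <- tiny_config(seed = 31)
  r <- generate_recording(cfg)
  ft <- to_feature_table(r, filter_spec(3.5, 30), buffer_size = 32)
  expect_equal(nrow(ft), nrow(r$samples) %/% 32)
  expect_identical(names(ft),
                   c("Time", r$config$channels$name, "Class"))
  expect_identical(ft$Time, seq_len(nrow(ft)))
  # squaring precedes averaging: all feature values non-negative
  for (ch in r$config$channels$name) expect_true(all(ft[[ch]] >= 0))
  # buffer labels follow the epoch schedule majority
  expect_setequal(unique(ft$Class), c("interval", "ball"))
})

test_that("an all-interval recording yields all-interval instances", {
  cfg <- tiny_config(seed = 32, active = list())
  cfg$epoch_schedule <- data.frame(label = "interval", duration = 4,
                                   stringsAsFactors = FALSE)
  r <- generate_recording(cfg)
  ft <- to_feature_table(r, buffer_size = 32)
  expect_true(all(ft$Class == "interval"))
})

test_that("ambiguous buffers are credited to the interval class", {
  # 16 ball + 16 interval samples in one 32-sample buffer: tie -> interval
  labs <- c(rep("ball", 16), rep("interval", 16), rep("ball", 32))
  cfg <- tiny_config(seed = 33)
  r <- generate_recording(cfg)
  r$labels <- c(labs, rep("interval", nrow(r$samples) - length(labs)))
  ft <- to_feature_table(r, buffer_size = 32)
  expect_equal(ft$Class[1], "interval")
  expect_equal(ft$Class[2], "ball")
})

test_that("feature CSV round-trips and malformed files are reported distinctly", {
  ft <- toy_table(c(ball = 5, cube = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- read_feature_csv(path)
  expect_equal(back, ft)

  bad <- ft
  names(bad)[names(bad) == "Class"] <- "Label"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_feature_csv(p2), "'Class'")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("Time,ch1,Class", p3)
  expect_error(read_feature_csv(p3), "no instances")

  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time,ch1,Class", "1,abc,ball", "2,0.5,cube"), p4)
  expect_error(read_feature_csv(p4), "ch1")
})
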