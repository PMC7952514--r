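tone_recording <- function(freq, fs = 5000, dur = 4, n_ch = 4, amp = 10) {
  t <- (seq_len(fs * dur) - 1) / fs
  recording(matrix(rep(amp * sin(2 * pi * freq * t), each = n_ch),
                   nrow = n_ch), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))

test_that("notch filter removes 50 Hz and passes neighbors", {
  rec50 <- tone_recording(50)
  out <- notch_filter(rec50)
  mid <- 5000:15000
  expect_lt(rms(out$data[1, mid]) / rms(rec50$data[1, mid]), 0.01)
  rec10 <- tone_recording(10)
  out10 <- notch_filter(rec10)
  ratio_db <- 20 * log10(rms(out10$data[1, mid]) / rms(rec10$data[1, mid]))
  expect_lt(abs(ratio_db), 1)
  # all-zero input stays zero
  z <- recording(matrix(0, 4, 20000), fs = 5000)
  expect_equal(max(abs(notch_filter(z)$data)), 0)
  expect_error(notch_filter(recording(matrix(rnorm(200), 2), fs = 90)),
               class = "invalid_config")
})

test_that("band-pass filter attenuates stop-band and passes pass-band tones", {
  rec30 <- tone_recording(30, fs = 250, dur = 20)
  out30 <- bandpass_filter(rec30, 2, 20)
  mid <- 1000:4000
  db30 <- 20 * log10(rms(out30$data[1, mid]) / rms(rec30$data[1, mid]))
  expect_lt(db30, -20)
  rec10 <- tone_recording(10, fs = 250, dur = 20)
  out10 <- bandpass_filter(rec10, 2, 20)
  db10 <- 20 * log10(rms(out10$data[1, mid]) / rms(rec10$data[1, mid]))
  expect_lt(abs(db10), 1)
  # DC removal through the broad band
  dc <- recording(matrix(5, 4, 5000), fs = 250)
  outdc <- bandpass_filter(dc, 0.1, 40)
  expect_lt(max(abs(rowMeans(outdc$data[, 1000:4000]))), 0.05)
  expect_error(bandpass_filter(rec10, 30, 20), class = "invalid_config")
})

test_that("resampling preserves length arithmetic and tone amplitude", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 900000), 4), fs = 5000)
  out <- resample_recording(rec, 250)
  expect_equal(ncol(out$data), 45000)
  expect_equal(out$fs, 250)
  # 10 Hz tone survives within 2% amplitude
  rec10 <- tone_recording(10, fs = 5000, dur = 4)
  o <- resample_recording(rec10, 250)
  t2 <- (seq_len(ncol(o$data)) - 1) / 250
  fit <- lm(o$data[1, ] ~ sin(2 * pi * 10 * t2) + cos(2 * pi * 10 * t2))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 10) / 10, 0.02)
  # identity when target equals source
  same <- resample_recording(rec10, 5000)
  expect_identical(same$data, rec10$data)
  expect_error(resample_recording(rec10, 10000), class = "invalid_config")
})

test_that("epoching splits recordings and discards partial epochs", {
  rec <- recording(matrix(rnorm(2 * 45000), 2), fs = 250)
  ep <- epoch_recording(rec, 2)
  expect_equal(dim(ep$data), c(90, 2, 500))
  short <- recording(matrix(rnorm(2 * round(5.5 * 250)), 2), fs = 250)
  ep2 <- epoch_recording(short, 2)
  expect_equal(dim(ep2$data)[1], 2)
  tiny <- recording(matrix(rnorm(2 * 250), 2), fs = 250)
  expect_error(epoch_recording(tiny, 2), class = "invalid_data")
})

test_that("epoch rejection drops exactly the contaminated epochs", {
  sim <- small_subject(seed = 3, duration = 10)
  ep <- epoch_recording(resample_recording(sim$recording, 250), 2)
  clean <- reject_bad_epochs(ep, 150)
  expect_equal(dim(clean$data)[1], dim(ep$data)[1])
  # inject a 500 uV spike into epoch 3
  spiked <- ep
  spiked$data[3, 1, 100] <- spiked$data[3, 1, 100] + 500
  out <- reject_bad_epochs(spiked, 150)
  expect_equal(attr(out, "n_rejected"), 1)
  expect_false(3 %in% out$kept_epoch_ids)
  expect_error(reject_bad_epochs(ep, 0), class = "empty_result")
})

test_that("average referencing zeroes the per-sample channel mean idempotently", {
  sim <- small_subject(seed = 5, duration = 6)
  ep <- epoch_recording(sim$recording, 2)
  ar <- average_reference(ep)
  means <- apply(ar$data, c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-10)
  expect_warning(ar2 <- average_reference(ar), "already")
  expect_equal(ar2$data, ar$data)
})

test_that("the full chain is reproducible and commutes with channel permutation", {
  sim <- small_subject(seed = 6, duration = 10)
  a <- preprocess(sim$recording)
  b <- preprocess(sim$recording)
  expect_identical(a$data, b$data)
  perm <- sample(seq_len(16))
  rec_p <- sim$recording
  rec_p$data <- rec_p$data[perm, ]
  rec_p$channel_labels <- rec_p$channel_labels[perm]
  c_ <- preprocess(rec_p)
  expect_equal(c_$data, a$data[, perm, , drop = FALSE], tolerance = 1e-10)
})
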