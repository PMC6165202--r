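test_that("zero-phase bandpass passes a 10 Hz tone unchanged with zero lag", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)[-1]
  tone <- sin(2 * pi * 10 * t)
  rec <- make_recording(matrix(tone, 1, dimnames = list("ch1", NULL)), fs)
  out <- bandpass(rec, 1, 50, 4)$data[1, ]
  mid <- seq(2000, 8000)                     # away from edges
  expect_lt(abs(sd(out[mid]) / sd(tone[mid]) - 1), 0.01)
  cc <- ccf(out[mid], tone[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("bandpass removes DC and attenuates out-of-band tones by >= 20 dB", {
  fs <- 1000
  rec <- make_recording(matrix(100, 1, 5000, dimnames = list("ch1", NULL)), fs)
  out <- bandpass(rec, 1, 50, 4)$data[1, ]
  expect_lt(abs(mean(out)), 1)

  t <- seq_len(10000) / fs
  hi <- sin(2 * pi * 80 * t)
  rech <- make_recording(matrix(hi, 1, dimnames = list("ch1", NULL)), fs)
  outh <- bandpass(rech, 1, 50, 4)$data[1, ]
  att_db <- 20 * log10(sd(outh[2000:8000]) / sd(hi[2000:8000]))
  expect_lt(att_db, -20)

  expect_error(bandpass(rec, 50, 1), "band")
  expect_error(bandpass(rec, 0, 50), "band")
})

test_that("downsampling keeps every n-th sample and preserves tone frequency", {
  fs <- 1000
  t <- seq_len(10000) / fs
  tone <- sin(2 * pi * 10 * t)
  rec <- make_recording(matrix(tone, 1, dimnames = list("ch1", NULL)), fs)
  rec <- bandpass(rec, 1, 50)
  ds <- downsample(rec, 200)
  expect_equal(ds$fs, 200)
  expect_equal(ncol(ds$data), 2000)
  # FFT peak at 10 Hz before and after
  peak_hz <- function(x, fs) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    f[which.max(sp[f <= fs / 2])]
  }
  expect_equal(peak_hz(ds$data[1, ], 200), 10, tolerance = 0.2)
  expect_equal(peak_hz(rec$data[1, ], 1000), 10, tolerance = 0.2)

  expect_error(downsample(rec, 300), "integer")
  rec2 <- make_recording(matrix(tone, 1, dimnames = list("ch1", NULL)), fs)
  expect_warning(downsample(rec2, 200), "lowpass")
})

test_that("common average reference centres the group and is idempotent", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 8, ncol = 3)
  rownames(x) <- paste0("c", 1:8)
  grp <- paste0("c", 1:6)
  y <- rereference_car(x, grp)
  expect_equal(y[1:6, 1], c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
               ignore_attr = TRUE)
  expect_equal(y[7:8, ], x[7:8, ])                 # non-group untouched
  expect_equal(colSums(y[grp, ]), rep(0, 3), ignore_attr = TRUE)
  expect_equal(rereference_car(y, grp), y)          # idempotent
  y1 <- rereference_car(x, "c3")
  expect_equal(y1["c3", ], rep(0, 3), ignore_attr = TRUE)
  expect_error(rereference_car(x, c("c1", "nope")), "unknown channel")
  expect_error(rereference_car(x, character(0)), "non-empty")
})

test_that("opposite-ear reference uses pre-reference values of the other side", {
  x <- matrix(0, 6, 2)
  rownames(x) <- c("L1", "L2", "L3", "R1", "R2", "R3")
  x["L1", ] <- 5
  x["R1", ] <- 1; x["R2", ] <- 2; x["R3", ] <- 3
  y <- rereference_ear(x, c("L1", "L2", "L3"), c("R1", "R2", "R3"))
  expect_equal(y["L1", ], c(3, 3), ignore_attr = TRUE)   # 5 - mean(1,2,3)
  # right channels use the OLD left values (mean 5/3), not the referenced ones
  expect_equal(y["R1", ], c(1 - 5 / 3, 1 - 5 / 3), ignore_attr = TRUE)
  # all-equal constant zeroes every ear channel
  cst <- matrix(7, 6, 3, dimnames = list(rownames(x), NULL))
  z <- rereference_ear(cst, c("L1", "L2", "L3"), c("R1", "R2", "R3"))
  expect_equal(max(abs(z)), 0)
  expect_error(rereference_ear(x, c("L1", "L2"), c("R1", "R2", "R3")), "3 channels")
  y2 <- rereference_ear(x, c("L1", "L2"), c("R1", "R2", "R3"), strict = FALSE)
  expect_equal(y2["L1", ], c(3, 3), ignore_attr = TRUE)
})

test_that("epoching cuts half-open windows relative to task onsets", {
  m <- build_default_montage()
  sch <- generate_main_schedule(1, 2, c(10, 10), seed = 1)
  fs <- 200
  n <- round(schedule_duration(sch) * fs)
  dat <- matrix(seq_len(n), 31, n, byrow = TRUE)
  rec <- make_recording(dat, fs, m, sch)
  ep <- extract_epochs(rec, c(-2, 10))
  expect_equal(dim(ep$data), c(4, 31, 2400))
  expect_equal(ep$labels, sch$label[sch$label %in% c("MA", "LC")])
  expect_equal(range(ep$times), c(-2, 10 - 1 / fs))
  # sample alignment: value at time 0 equals onset sample index + 1
  on1 <- sch$onset_s[sch$label %in% c("MA", "LC")][1]
  expect_equal(ep$data[1, 1, ep$times == 0], round(on1 * fs) + 1,
               ignore_attr = TRUE)

  cst <- make_recording(matrix(3.5, 31, n), fs, m, sch)
  epc <- extract_epochs(cst, c(-2, 10))
  expect_true(all(epc$data == 3.5))

  expect_error(extract_epochs(rec, c(0, 0)), "positive length")
  short <- make_recording(dat[, 1:2000, drop = FALSE], fs, m,
                          earbci:::new_schedule(c("MA"), 5, 10))
  expect_error(extract_epochs(short, c(-2, 10)), "trial 1")
})

test_that("baseline correction subtracts the pre-task mean and is idempotent", {
  data <- array(7, c(2, 3, 400))
  ep <- make_epochs(data, c("MA", "LC"), fs = 100, t0 = -2)
  bc <- baseline_correct(ep, c(-2, 0))
  expect_equal(max(abs(bc$data)), 0)

  d2 <- array(0, c(1, 1, 400))
  d2[1, 1, 1:200] <- 2
  d2[1, 1, 201:400] <- 5
  ep2 <- make_epochs(d2, "MA", fs = 100, t0 = -2)
  bc2 <- baseline_correct(ep2, c(-2, 0))
  expect_equal(unique(bc2$data[1, 1, 201:400]), 3)
  expect_equal(baseline_correct(bc2, c(-2, 0))$data, bc2$data)
  expect_error(baseline_correct(ep2, c(-10, -5)), "baseline window")
})

test_that("peak-to-peak rejection removes exactly the above-threshold trials", {
  data <- array(0, c(3, 2, 100))
  data[2, 1, 50] <- 300                      # blink-like deflection
  data[3, 2, ] <- seq(0, 126.67, length.out = 100)   # exactly at threshold
  ep <- make_epochs(data, c("MA", "LC", "MA"), fs = 100, t0 = -1)
  res <- reject_peak_to_peak(ep, 126.67)
  expect_equal(attr(res$report, "kept_indices"), c(1L, 3L))
  expect_equal(attr(res$report, "rejected_indices"), 2L)
  expect_equal(n_trials(res$epochs), 2)
  expect_equal(res$epochs$labels, c("MA", "MA"))
  expect_equal(res$report$ptp, c(0, 300, 126.67))
  expect_true(all(sort(c(attr(res$report, "kept_indices"),
                         attr(res$report, "rejected_indices"))) == 1:3))

  all_kept <- reject_peak_to_peak(ep, Inf)
  expect_equal(n_trials(all_kept$epochs), 3)
  expect_equal(all_kept$epochs$data, ep$data)

  expect_error(reject_peak_to_peak(ep, 0), "threshold")
  hot <- ep
  hot$data[, , 1] <- 1e4
  hot$data[, , 2] <- -1e4
  expect_error(reject_peak_to_peak(hot, 126.67), "all 3 trials")
})

test_that("trials containing injected blinks, and only those, are rejected on a quiet background", {
  m <- build_default_montage()
  sch <- generate_main_schedule(1, 5, c(10, 10), seed = 21)
  quiet <- sim_config(seed = 22, noise_scale = 0.5, alpha_amplitude = 0.3,
                      bg_amplitude = 0.3)
  rec <- simulate_recording(m, sch, quiet)
  rec <- inject_blinks(rec, rate = 4, amplitude = 300, seed = 23)
  onsets <- attr(rec, "blink_onsets")
  pp <- preprocess_recording(rec)
  dat <- rereference_car(pp$data, roi_channels(m, "frontal"))
  rec_f <- pp; rec_f$data <- dat
  ep <- baseline_correct(extract_epochs(rec_f, channels = roi_channels(m, "frontal")))
  res <- reject_peak_to_peak(ep, 126.67)
  tasks <- pp$schedule[pp$schedule$label %in% c("MA", "LC"), ]
  truth <- which(vapply(seq_len(nrow(tasks)), function(i) {
    any(onsets + 0.3 > tasks$onset_s[i] - 2 & onsets < tasks$onset_s[i] + 10)
  }, logical(1)))
  expect_equal(attr(res$report, "rejected_indices"), truth)
})
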