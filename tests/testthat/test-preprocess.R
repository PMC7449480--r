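test_that("artifact rules fire on their defining fixtures", {
  fs <- 1000
  # flat line
  rep1 <- detect_artifacts(epoched_signal(rep(0, 10 * fs), fs))
  expect_true(rep1$flagged)
  expect_true("constant_amplitude" %in% rep1$reasons)
  # out-of-range sample
  x <- sin(2 * pi * 10 * seq_len(10 * fs) / fs) * 50
  x[5000] <- 260
  rep2 <- detect_artifacts(epoched_signal(x, fs))
  expect_true("range_exceeded" %in% rep2$reasons)
  # clean moderate sine (60 uV amplitude: 120 uV swing per second, under the
  # 140 uV/s criterion) passes
  clean <- 60 * sin(2 * pi * 10 * seq_len(10 * fs) / fs)
  expect_false(detect_artifacts(epoched_signal(clean, fs))$flagged)
  # a 100 uV-amplitude sine swings 200 uV within a second and is flagged
  big <- 100 * sin(2 * pi * 10 * seq_len(10 * fs) / fs)
  expect_true("slope_exceeded" %in% detect_artifacts(epoched_signal(big, fs))$reasons)
  expect_error(detect_artifacts(1:100), "sampling rate")
  expect_error(detect_artifacts(epoched_signal(1, fs)), "2 samples")
  # flagged <=> reasons non-empty
  expect_identical(rep1$flagged, length(rep1$reasons) > 0)
})

test_that("windowed slope rule agrees with a brute-force scan", {
  fs <- 200
  set.seed(1)
  x <- cumsum(rnorm(1000, sd = 3))
  w <- fs  # 1 s
  brute <- max(vapply(seq_len(length(x) - w + 1), function(i) {
    seg <- x[i:(i + w - 1)]
    max(seg) - min(seg)
  }, numeric(1)))
  rep <- detect_artifacts(epoched_signal(x, fs), slope_limit = brute + 1e-9)
  expect_false("slope_exceeded" %in% rep$reasons)
  rep <- detect_artifacts(epoched_signal(x, fs), slope_limit = brute - 1e-9)
  expect_true("slope_exceeded" %in% rep$reasons)
})

test_that("band-pass filtering attenuates out-of-band power and keeps length", {
  set.seed(2)
  fs <- 1000
  e <- epoched_signal(rnorm(10 * fs), fs)
  f30 <- apply_filter(e, filter_spec(high_cut = 30))
  expect_length(f30$samples, length(e$samples))
  est <- estimate_spectrum(f30, sampling_rate = fs)
  inband <- est$frequencies > 1 & est$frequencies < 30
  above <- est$frequencies > 40
  expect_lt(sum(est$power[above]), 0.02 * sum(est$power[inband]))
  # in-band tone passes essentially unchanged
  t <- seq_len(10 * fs) / fs
  tone <- epoched_signal(sin(2 * pi * 10 * t), fs)
  ft <- apply_filter(tone, filter_spec(high_cut = 49))
  mid <- 2000:8000
  expect_equal(max(abs(ft$samples[mid])), 1, tolerance = 0.01)
  expect_error(apply_filter(e, filter_spec(high_cut = 600)), "Nyquist")
})

test_that("filtering twice is close to filtering once on pass-band content", {
  fs <- 1000
  t <- seq_len(5 * fs) / fs
  x <- epoched_signal(sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 20 * t), fs)
  spec <- filter_spec(high_cut = 49)
  once <- apply_filter(x, spec)
  twice <- apply_filter(once, spec)
  mid <- 1000:4000
  expect_lt(max(abs(once$samples[mid] - twice$samples[mid])), 0.02)
})

test_that("transition epochs are cut on the correct sides and skip the gray zone", {
  fs <- 100
  n <- 600 * fs
  rec <- list(samples = rnorm(n), sampling_rate = fs, patient_id = "P01")
  # mark the gray zones with a sentinel value
  ann <- data.frame(patient_id = "P01",
                    event = c("LOC1", "ROC1", "LOC2", "ROC2"),
                    last_response_time_s = c(60, 180, 300, 540),
                    first_no_response_time_s = c(75, 165, 315, 525))
  for (i in seq_len(nrow(ann))) {
    lo <- min(ann$last_response_time_s[i], ann$first_no_response_time_s[i])
    hi <- max(ann$last_response_time_s[i], ann$first_no_response_time_s[i])
    rec$samples[(lo * fs + 1):(hi * fs)] <- 1e6
  }
  eps <- cut_transition_epochs(rec, ann, epoch_duration = 10)
  expect_length(eps, 8)
  expect_equal(sum(vapply(eps, function(e) e$state == "conscious", logical(1))), 4)
  for (e in eps) expect_false(any(e$samples == 1e6))
  # LOC: conscious before the transition; ROC: conscious after
  loc1_c <- Filter(function(e) e$event_label == "LOC1" & e$state == "conscious", eps)[[1]]
  expect_identical(loc1_c$samples, rec$samples[(50 * fs + 1):(60 * fs)])
  roc1_c <- Filter(function(e) e$event_label == "ROC1" & e$state == "conscious", eps)[[1]]
  expect_identical(roc1_c$samples, rec$samples[(180 * fs + 1):(190 * fs)])
  # one-sided annotation: one epoch plus a warning
  ann1 <- data.frame(patient_id = "P01", event = "LOC1",
                     last_response_time_s = 60, first_no_response_time_s = NA)
  expect_warning(e1 <- cut_transition_epochs(rec, ann1, 10), "one side")
  expect_length(e1, 1)
  # out-of-order annotation errors, naming the event
  bad <- data.frame(patient_id = "P01", event = "LOC1",
                    last_response_time_s = 75, first_no_response_time_s = 60)
  expect_error(cut_transition_epochs(rec, bad, 10), "LOC1")
})

test_that("injected artifacts are all caught; clean epochs mostly pass", {
  cfg <- cohort_config(n_patients = 4, sweeps_per_aep = 8, artifact_rate = 1,
                       seed = 21)
  coh <- generate_cohort(cfg)
  reports <- lapply(coh$epochs, detect_artifacts)
  expect_true(all(vapply(reports, `[[`, logical(1), "flagged")))
  # truth flags present and detector catches each class
  truth <- vapply(coh$epochs, function(e)
    is.null(attr(e, "artifact_truth")), logical(1))
  expect_false(any(truth))
  # rate 0 leaves epochs untouched
  cfg0 <- cohort_config(n_patients = 2, sweeps_per_aep = 8, artifact_rate = 0,
                        seed = 21)
  coh0 <- generate_cohort(cfg0)
  expect_identical(coh0$epochs, inject_artifacts(coh0$epochs, cfg0))
  # false-positive rate on clean epochs below 10%
  flags <- vapply(lapply(coh0$epochs, detect_artifacts), `[[`, logical(1), "flagged")
  expect_lt(mean(flags), 0.1)
  # flat-line corruption is reported as constant amplitude
  e <- coh0$epochs[[1]]
  e$samples[2000:4500] <- e$samples[2000]
  expect_true("constant_amplitude" %in% detect_artifacts(e)$reasons)
})
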