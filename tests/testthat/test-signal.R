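# Signal pipeline: preprocessing, detectors, segmentation, mLAP and PR
# extraction, cohort statistics.

test_that("preprocessing rejects DC, mains and drift, keeps the passband", {
  fs <- 1000
  t <- (0:9999) / fs
  # constant input maps to (numerically) zero
  out <- preprocess_ecg(rep(3.7, 5000), fs)
  expect_lt(max(abs(out)), 3.7 * 1e-3)
  # 50 Hz tone attenuated by >= 40 dB over the whole output
  tone <- sin(2 * pi * 50 * t)
  out50 <- preprocess_ecg(tone, fs)
  expect_lt(sqrt(mean(out50^2)) / sqrt(mean(tone^2)), 0.01)
  # 10 Hz passband tone within 5% of input amplitude
  s10 <- sin(2 * pi * 10 * t)
  o10 <- preprocess_ecg(s10, fs)
  expect_lt(abs(max(abs(o10[2000:8000])) - 1), 0.05)
  # length preserved; too-low sampling rate rejected
  expect_length(out50, length(tone))
  expect_error(preprocess_ecg(tone, 200), "sample_rate")
})

test_that("Pan-Tompkins detects synthetic beats and ignores amplitude", {
  fs <- 1000
  expect_error(detect_r_peaks(numeric(1500), fs), "2 s")
  expect_identical(detect_r_peaks(numeric(5000), fs), integer(0))

  se <- synth_ecg(60, 60, fs, snr_db = 20, seed = 42)
  ecg <- preprocess_ecg(se$ecg, fs)
  pk <- detect_r_peaks(ecg, fs)
  expect_true(abs(length(pk) - length(se$peaks)) <= 1)
  # each detection within 10 ms of a true peak
  err <- vapply(pk, function(p) min(abs(se$peaks - p)), numeric(1))
  expect_lt(max(err), 10)
  expect_true(all(diff(pk) > 0))
  # adaptive thresholds: doubling the amplitude changes nothing
  pk2 <- detect_r_peaks(2 * ecg, fs)
  expect_identical(pk, pk2)
})

test_that("pacing-spike detection is exact and noise-tolerant", {
  fs <- 1000
  expect_identical(detect_pacing_spikes(numeric(5000), fs), integer(0))
  # 100 bpm spike train, 30 s -> 50 spikes within 2 ms
  n <- 30 * fs
  cs <- numeric(n)
  truth <- seq(500, n - 200, by = 600)
  for (s in truth) { cs[s:(s + 1)] <- 4; cs[(s + 2):(s + 3)] <- -4 }
  sp <- detect_pacing_spikes(cs, fs)
  expect_length(sp, length(truth))
  expect_lt(max(abs(sp - truth)), 2.5)
  # additive white noise at 10% of spike amplitude changes no detection
  set.seed(99)
  spn <- detect_pacing_spikes(cs + rnorm(n, 0, 0.4), fs)
  expect_length(spn, length(truth))
  expect_lt(max(abs(spn - truth)), 2.5)
})

test_that("protocol segmentation recovers paced stretches and windows", {
  fs <- 1000
  # 30 s of spikes at 600 ms flanked by 30-s spike-free stretches
  spikes <- seq(30 * fs, 60 * fs, by = 600)
  segs <- segment_protocol(spikes, integer(0), fs, n_samples = 90 * fs)
  expect_equal(segs$kind, c("sinus", "paced", "sinus"))
  expect_equal(segs$rate[2], 100)
  # analysis window is the final 10 s, inside the segment
  expect_equal(segs$win_end, segs$end)
  expect_true(all(segs$win_start >= segs$start))
  expect_equal(segs$win_end[2] - segs$win_start[2], 10 * fs)
  # paced segment length tolerance: ~29.5 s passes a +-10% check
  expect_lt(abs((segs$end[2] - segs$start[2]) / fs - 30) / 30, 0.1)
  # no spikes at all -> single sinus segment with a warning
  expect_warning(s0 <- segment_protocol(integer(0), integer(0), fs,
                                        n_samples = 60 * fs),
                 "no pacing spikes")
  expect_equal(s0$kind, "sinus")
})

test_that("mLAP response differences against flanking sinus windows", {
  fs <- 1000
  spikes <- seq(30 * fs, 60 * fs, by = 600)
  segs <- segment_protocol(spikes, integer(0), fs, n_samples = 90 * fs)
  # constant LA pressure -> zero change everywhere
  ml <- mlap_response(rep(12, 90 * fs), segs)
  expect_equal(ml$per_rate$delta_mlap, 0)
  expect_false(any(ml$per_rate$single_flank))
  # a paced-window offset is recovered exactly with constant flanks
  lap <- rep(10, 90 * fs)
  lap[segs$start[2]:(segs$end[2] - 1)] <- 7.5
  ml2 <- mlap_response(lap, segs)
  expect_equal(ml2$per_rate$delta_mlap, -2.5)
  # missing channel errors
  expect_error(mlap_response(NULL, segs), "missing")
  # window discipline: samples outside analysis windows are ignored
  lap3 <- lap
  outside <- setdiff(seq_along(lap3),
                     unlist(lapply(seq_len(nrow(segs)), function(i)
                       segs$win_start[i]:(segs$win_end[i] - 1))))
  lap3[outside] <- 1e6
  ml3 <- mlap_response(lap3, segs)
  expect_equal(ml3$per_rate$delta_mlap, ml2$per_rate$delta_mlap)
})

test_that("PR intervals follow spikes and P onsets; dropped beats flagged", {
  fs <- 1000
  g <- generate_recording(synthetic_config(seed = 3))
  ecg <- preprocess_ecg(g$recording$channels$ecg, fs)
  rp <- detect_r_peaks(ecg, fs)
  sp <- detect_pacing_spikes(g$recording$channels$cs, fs)
  beats <- pr_intervals(ecg, rp, sp, fs)
  truth <- g$truth$beats
  # every emitted beat with a QRS has a nearby detected counterpart
  expect_equal(nrow(beats), nrow(truth))
  expect_equal(sum(beats$dropped), sum(truth$dropped))
  # match estimated beats to truth by nearest QRS onset (<= 40 ms apart)
  pr_err <- function(est, tru) {
    vapply(seq_len(nrow(est)), function(i) {
      j <- which.min(abs(tru$qrs_onset - est$qrs_onset[i]))
      if (abs(tru$qrs_onset[j] - est$qrs_onset[i]) > 40) return(NA_real_)
      est$pr_ms[i] - tru$pr_ms[j]
    }, numeric(1))
  }
  ep <- pr_err(beats[beats$paced & !beats$dropped, ],
               truth[truth$paced & !truth$dropped, ])
  expect_gt(mean(!is.na(ep)), 0.95)
  expect_lt(abs(mean(ep, na.rm = TRUE)), 10)
  ei <- pr_err(beats[!beats$paced, ], truth[!truth$paced, ])
  expect_gt(sum(!is.na(ei)), 0)
  expect_lt(abs(mean(ei, na.rm = TRUE)), 10)
  # retained PRs are in the physiological range or flagged
  expect_true(all(beats$pr_ms[beats$pr_valid] > 40 &
                    beats$pr_ms[beats$pr_valid] < 400))
})

test_that("spike-to-QRS bookkeeping: an unconducted spike is a dropped beat", {
  fs <- 1000
  n <- 20 * fs
  ecg <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  spikes_s <- seq(1, 18, by = 0.6)
  drop <- seq(4, length(spikes_s), by = 4)
  cs <- numeric(n)
  for (i in seq_along(spikes_s)) {
    s <- round(spikes_s[i] * fs)
    cs[s:(s + 1)] <- 4; cs[(s + 2):(s + 3)] <- -4
    if (!(i %in% drop))
      ecg <- ecg + exp(-((t - (spikes_s[i] + 0.2 + 0.02)) / 0.010)^2 / 2)
  }
  ecg <- preprocess_ecg(ecg, fs)
  beats <- pr_intervals(ecg, detect_r_peaks(ecg, fs),
                        detect_pacing_spikes(cs, fs), fs)
  expect_equal(sum(beats$dropped), length(drop))
  expect_true(all(is.na(beats$pr_ms[beats$dropped])))
})

test_that("cohort statistics choose the paired test by normality", {
  # identical vectors: zero mean difference, degenerate CI around zero
  cs0 <- cohort_stats(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(cs0$mean_diff, 0)
  expect_true(cs0$ci95[1] <= 0 && cs0$ci95[2] >= 0)
  # normal differences -> paired t
  set.seed(11)
  base <- rnorm(40, 10, 2)
  cond <- base + rnorm(40, -1, 0.5)
  csn <- cohort_stats(base, cond)
  expect_identical(csn$test, "paired t")
  expect_lt(csn$p, 0.01)
  # heavy-tailed differences -> Wilcoxon
  set.seed(12)
  d <- rt(60, df = 1)
  csw <- cohort_stats(rep(0, 60), d - 2)
  expect_identical(csw$test, "wilcoxon")
  # guards
  expect_error(cohort_stats(1:5, 1:4), "equal length")
  expect_error(cohort_stats(1:2, 2:3), "at least 3")
  expect_error(cohort_stats(c(1, NA, 3), c(1, 2, 3)), "missing")
})
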