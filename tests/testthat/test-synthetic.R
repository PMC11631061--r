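# Synthetic-data generator: ground-truth bookkeeping, determinism, exact
# window means, cohort construction, and the model-driven cross-check.

test_that("generator is deterministic and windows are exact without noise", {
  cfg0 <- synthetic_config(seed = 5, depth = 0, segment_length = 15,
                           wenckebach_rate = 80,
                           noise = list(ecg_sd = 0, lap_sd = 0, cs_sd = 0,
                                        mains_amp = 0, ecg_drift_amp = 0,
                                        ecg_drift_period = 15,
                                        lap_drift_amp = 0,
                                        lap_drift_period = 120))
  g <- generate_recording(cfg0)
  # depth 0 + zero noise: every analysis-window mean equals m_sinus exactly
  lap <- g$recording$channels$lap
  for (i in seq_len(nrow(g$truth$segments))) {
    s <- g$truth$segments[i, ]
    expect_equal(mean(lap[s$win_start:(s$win_end - 1)]), cfg0$m_sinus,
                 tolerance = 1e-10)
  }
  # same seed -> bit-identical channels
  g2 <- generate_recording(cfg0)
  expect_identical(g$recording$channels, g2$recording$channels)
  # different seed -> different noise (here zero noise, so identical
  # signals; with noise they must differ)
  cfgn <- synthetic_config(seed = 6, segment_length = 15,
                           wenckebach_rate = 80)
  expect_false(identical(generate_recording(cfgn)$recording$channels$ecg,
                         generate_recording(synthetic_config(
                           seed = 7, segment_length = 15,
                           wenckebach_rate = 80))$recording$channels$ecg))
})

test_that("ground-truth bookkeeping is complete and consistent", {
  g <- generate_recording(synthetic_config(seed = 2, segment_length = 15,
                                           wenckebach_rate = 100))
  b <- g$truth$beats
  expect_true(all(!is.na(b$atrial_onset)))
  expect_true(all(!is.na(b$qrs_onset[!b$dropped])))
  expect_true(all(is.na(b$qrs_onset[b$dropped])))
  expect_true(all(b$qrs_onset[!b$dropped] > b$atrial_onset[!b$dropped]))
  # dropped beats only at/above the Wenckebach rate
  segs <- g$truth$segments
  wck_spans <- segs[!is.na(segs$rate) & segs$rate >= 100, ]
  for (i in which(b$dropped)) {
    on <- b$atrial_onset[i]
    expect_true(any(on >= wck_spans$start & on < wck_spans$end))
  }
  # schedule starts at the decade above sinus and ends at Wenckebach
  cfg <- synthetic_config(sinus_hr = 55, wenckebach_rate = 100)
  expect_equal(cfg$rates, c(60, 70, 80, 90, 100))
  expect_equal(g$truth$max_rate, 90)
  # invalid schedule rejected
  expect_error(synthetic_config(sinus_hr = 90, wenckebach_rate = 80),
               "wenckebach")
})

test_that("full-protocol recovery: rates, mLAP, PR, optimal and max rate", {
  g <- generate_recording(synthetic_config(seed = 21))
  res <- analyze_recording(g$recording)
  truth <- g$truth
  expect_equal(res$per_rate$rate, truth$per_rate$rate)
  expect_true(all(abs(res$per_rate$mlap - truth$per_rate$mlap) < 0.5))
  expect_true(all(abs(res$per_rate$mean_pr_ms - truth$per_rate$pr_ms) < 10))
  expect_equal(res$optimal_rate, truth$optimal_rate)
  expect_equal(res$max_rate, truth$max_rate)
  expect_equal(round(res$sinus_hr), truth$sinus_hr)
  expect_lt(abs(res$sinus_mlap - truth$sinus_mlap), 0.5)
})

test_that("cohort draws valid per-patient parameters and truth", {
  ch <- generate_cohort(75, seed = 4)
  expect_length(ch$configs, 75)
  tr <- ch$truth
  # programmed optima always inside each patient's schedule
  for (i in seq_len(75)) {
    expect_true(tr$optimal_rate[i] %in% ch$configs[[i]]$rates)
    expect_true(tr$max_rate[i] %in% ch$configs[[i]]$rates)
  }
  expect_true(all(tr$delta_mlap_opt <= 0))
  # cohort-level unloading is detectable with the packaged statistics
  cs <- cohort_stats(tr$sinus_mlap, tr$sinus_mlap + tr$delta_mlap_opt)
  expect_lt(cs$p, 0.001)
  expect_lt(cs$mean_diff, 0)
  # zero dispersion reproduces the default generator settings
  ch0 <- generate_cohort(1, seed = 9,
                         dispersion = list(sinus_hr = 0, m_sinus = 0,
                                           depth = 0, r_opt = 0, pr0 = 0,
                                           pr_slope = 0))
  base <- synthetic_config()
  for (f in c("sinus_hr", "m_sinus", "depth", "r_opt", "pr0"))
    expect_equal(ch0$configs[[1]][[f]], base[[f]])
})

test_that("a small cohort survives the full pipeline end to end", {
  ch <- generate_cohort(3, seed = 14, segment_length = 20)
  for (i in 1:3) {
    g <- cohort_recording(ch, i)
    res <- analyze_recording(g$recording)
    expect_equal(res$optimal_rate, ch$truth$optimal_rate[i])
    expect_equal(res$max_rate, ch$truth$max_rate[i])
  }
})

test_that("model-driven recordings agree with the model's own metrics", {
  ph <- hfpef_phenotype()
  md <- model_driven_recording(ph, rates = c(60, 90, 120),
                               pr_fun = pr_rate_function())
  res <- analyze_recording(md$recording)
  segs <- md$truth$segments
  paced <- segs[segs$kind == "paced", ]
  # pipeline mLAP per paced segment within 0.2 mmHg of the model's mLAP
  expect_equal(res$per_rate$rate, paced$rate)
  expect_true(all(abs(res$per_rate$mlap - paced$mlap) < 0.2))
  # pipeline PR per paced segment within 10 ms of the scheduled PR
  expect_true(all(abs(res$per_rate$mean_pr_ms - paced$pr_ms) < 10))
})

test_that("model-driven cannon segment has the higher LA pressure peak", {
  ph <- hfpef_phenotype()
  md_long <- model_driven_recording(ph, rates = 140,
                                    pr_fun = function(r) 300,
                                    segment_length = 12)
  md_short <- model_driven_recording(ph, rates = 140,
                                     pr_fun = function(r) 100,
                                     segment_length = 12)
  seg_peak <- function(md) {
    s <- md$truth$segments
    i <- which(s$kind == "paced")[1]
    max(md$recording$channels$lap[s$start[i]:(s$end[i] - 1)])
  }
  expect_gt(seg_peak(md_long), seg_peak(md_short))
})
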