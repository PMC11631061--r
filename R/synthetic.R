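# Synthetic clinical-style recordings with exact ground truth: the
# alternating 30-s sinus/paced protocol with programmed mLAP(rate) and
# PR(rate) laws, Gaussian-bump signal morphology (analytic placement gives
# exact onset truth), Wenckebach above a configurable rate, and additive
# noise/drift/mains interference.

#' Synthetic recording configuration
#'
#' The defaults emulate the clinical protocol and its cohort-level
#' response: sinus rhythm at 55 bpm, pacing from the nearest decade above
#' the intrinsic rate in 10-bpm steps up to Wenckebach block at 140 bpm,
#' 30-s alternating segments, a U-shaped mLAP(rate) =
#' m_sinus - depth exp(-((rate - r_opt)/width)^2) with its optimum at
#' 100 bpm and a depth of 2.3 mmHg, and decremental AV conduction
#' PR(rate) = pr0 + slope (rate - sinus_hr) capped at `pr_cap`.
#'
#' @param seed RNG seed for the noise processes.
#' @param sample_rate Hz.
#' @param sinus_hr intrinsic sinus rate (bpm).
#' @param segment_length segment duration (s).
#' @param m_sinus sinus-rhythm mean LA pressure (mmHg).
#' @param depth,r_opt,width mLAP(rate) trough depth (mmHg), location (bpm)
#'   and Gaussian width (bpm).
#' @param pr0 sinus PR interval (ms).
#' @param pr_slope PR prolongation per bpm of pacing rate (ms/bpm).
#' @param pr_cap PR cap (ms).
#' @param wenckebach_rate rate (bpm) at and above which every
#'   `drop_k`-th atrial beat fails to conduct.
#' @param drop_k Wenckebach conduction pattern (one dropped QRS per
#'   `drop_k` atrial beats).
#' @param noise list: `ecg_sd`, `lap_sd`, `cs_sd` (white noise SDs),
#'   `mains_amp` (50 Hz amplitude, mV), `ecg_drift_amp`/`ecg_drift_period`
#'   and `lap_drift_amp`/`lap_drift_period` (baseline drift sinusoids).
#' @param morphology list of Gaussian bump amplitudes/widths: P, QRS, T on
#'   the ECG (mV, s), pacing spike amplitude (mV), and LA a-/v-wave bumps
#'   (mmHg, s).
#' @return a `synthetic_config` list with the derived `rates` schedule.
#' @export
synthetic_config <- function(seed = 1, sample_rate = 1000, sinus_hr = 55,
                             segment_length = 30, m_sinus = 12.8,
                             depth = 2.3, r_opt = 100, width = 25,
                             pr0 = 153, pr_slope = 1.7, pr_cap = 300,
                             wenckebach_rate = 140, drop_k = 4,
                             noise = list(ecg_sd = 0.02, lap_sd = 0.3,
                                          cs_sd = 0.03, mains_amp = 0.05,
                                          ecg_drift_amp = 0.2,
                                          ecg_drift_period = 15,
                                          lap_drift_amp = 0.3,
                                          lap_drift_period = 120),
                             morphology = list(p_amp = 0.15, p_sigma = 0.020,
                                               qrs_amp = 1.0,
                                               qrs_sigma = 0.010,
                                               t_amp = 0.3, t_sigma = 0.040,
                                               spike_amp = 4,
                                               a_amp = 4, a_sigma = 0.045,
                                               v_amp = 5, v_sigma = 0.070)) {
  first <- ceiling(sinus_hr / 10) * 10
  if (first <= sinus_hr) first <- first + 10
  if (wenckebach_rate < first)
    stop("wenckebach_rate below the first scheduled pacing rate",
         call. = FALSE)
  rates <- seq(first, wenckebach_rate, by = 10)
  stopifnot(depth >= 0, pr0 > 0, width > 0,
            all(unlist(noise) >= 0), segment_length > 10)
  structure(list(seed = seed, sample_rate = sample_rate,
                 sinus_hr = sinus_hr, segment_length = segment_length,
                 m_sinus = m_sinus, depth = depth, r_opt = r_opt,
                 width = width, pr0 = pr0, pr_slope = pr_slope,
                 pr_cap = pr_cap, wenckebach_rate = wenckebach_rate,
                 drop_k = drop_k, noise = noise, morphology = morphology,
                 rates = rates),
            class = "synthetic_config")
}

mlap_profile <- function(config, rate) {
  config$m_sinus -
    config$depth * exp(-((rate - config$r_opt) / config$width)^2)
}

pr_profile <- function(config, rate) {
  pmin(config$pr0 + config$pr_slope * (rate - config$sinus_hr),
       config$pr_cap)
}

# add a Gaussian bump (center/sigma in seconds) to a signal in place
add_bump <- function(sig, fs, center, amp, sigma) {
  lo <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
  hi <- min(length(sig), ceiling((center + 4 * sigma) * fs) + 1L)
  if (hi < lo) return(sig)
  t <- (seq(lo, hi) - 1) / fs
  sig[lo:hi] <- sig[lo:hi] + amp * exp(-((t - center) / sigma)^2 / 2)
  sig
}

#' Generate a synthetic protocol recording with ground truth
#'
#' Builds the alternating sinus/paced protocol: for each beat the atrial
#' onset follows the schedule and the ventricular onset lies PR(rate)
#' later. On the ECG, intrinsic beats carry a P bump whose foot (2 sigma
#' before its centre) is the atrial onset; paced beats instead carry a
#' 2-ms biphasic spike on the CS channel at the atrial onset. The QRS bump
#' foot is the ventricular onset. The LA pressure is a per-beat a-wave +
#' v-wave bump train riding on the programmed mLAP(rate) level — with the
#' a-wave superposed onto the v-wave when the PR interval pushes atrial
#' systole into early diastole (cannon morphology) — normalised so each
#' segment's analysis-window mean equals the programmed level exactly
#' before noise. Above `wenckebach_rate` every `drop_k`-th beat drops its
#' QRS (and its a-wave is boosted: atrial contraction against a closed
#' valve). Noise, mains interference and baseline drift are added last;
#' the whole construction is reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `recording` (a `pacing_recording`: `sample_rate`,
#'   `channels$ecg/lap/cs`, `patient_id`) and `truth` (list: `segments`,
#'   `beats`, `per_rate`, `sinus_hr`, `sinus_mlap`, `optimal_rate`,
#'   `max_rate`).
#' @export
generate_recording <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$sample_rate
  seg_n <- round(config$segment_length * fs)
  win_n <- round(10 * fs)
  mo <- config$morphology

  # protocol: sinus, then (paced, sinus) per rate
  kinds <- c("sinus", rep(c("paced", "sinus"), length(config$rates)))
  seg_rate <- c(NA, as.vector(rbind(config$rates, NA)))
  nseg <- length(kinds)
  n <- nseg * seg_n
  starts <- (seq_len(nseg) - 1L) * seg_n + 1L
  segments <- data.frame(kind = kinds, rate = seg_rate, start = starts,
                         end = starts + seg_n,
                         win_start = starts + seg_n - win_n,
                         win_end = starts + seg_n)

  ecg <- numeric(n); lap <- numeric(n); cs <- numeric(n)
  level <- numeric(n)
  beats <- list()

  for (i in seq_len(nseg)) {
    paced <- kinds[i] == "paced"
    rate <- if (paced) seg_rate[i] else config$sinus_hr
    pr_ms <- if (paced) pr_profile(config, rate) else config$pr0
    cyc <- 60 / rate
    lvl <- if (paced) mlap_profile(config, rate) else config$m_sinus
    level[starts[i]:(starts[i] + seg_n - 1L)] <- lvl

    t0 <- (starts[i] - 1) / fs + 0.2
    onsets <- seq(t0, (starts[i] - 1) / fs + config$segment_length - cyc,
                  by = cyc)
    wck <- paced && rate >= config$wenckebach_rate
    cannon <- pr_ms / 1000 > 0.45 * cyc
    for (j in seq_along(onsets)) {
      ta <- onsets[j]
      dropped <- wck && (j %% config$drop_k == 0L)
      tq <- ta + pr_ms / 1000            # QRS onset (foot of the bump)
      if (paced) {
        # 2-ms biphasic pacing spike at the atrial onset
        i0 <- round(ta * fs) + 1L
        i1 <- min(n, i0 + round(0.001 * fs))
        i2 <- min(n, i1 + round(0.001 * fs))
        cs[i0:i1] <- cs[i0:i1] + mo$spike_amp
        if (i2 > i1) cs[(i1 + 1L):i2] <- cs[(i1 + 1L):i2] - mo$spike_amp
      } else {
        ecg <- add_bump(ecg, fs, ta + 2 * mo$p_sigma, mo$p_amp, mo$p_sigma)
      }
      if (!dropped) {
        qc <- tq + 2 * mo$qrs_sigma      # bump centre 2 sigma past onset
        ecg <- add_bump(ecg, fs, qc, mo$qrs_amp, mo$qrs_sigma)
        ecg <- add_bump(ecg, fs, qc + 0.30 * sqrt(cyc), mo$t_amp,
                        mo$t_sigma)
        lap <- add_bump(lap, fs, tq + 0.30 * sqrt(cyc), mo$v_amp,
                        mo$v_sigma)
      }
      a_amp <- mo$a_amp * (if (cannon || dropped) 2.2 else 1)
      lap <- add_bump(lap, fs, ta + 0.08, a_amp, mo$a_sigma)
      beats[[length(beats) + 1L]] <-
        data.frame(atrial_onset = round(ta * fs) + 1L,
                   qrs_onset = if (dropped) NA_integer_
                               else round(tq * fs) + 1L,
                   pr_ms = if (dropped) NA_real_ else pr_ms,
                   paced = paced, dropped = dropped)
    }
  }

  # exact window means: per-segment offset so that the analysis-window
  # mean of (level + bumps) equals the programmed level
  for (i in seq_len(nseg)) {
    w <- segments$win_start[i]:(segments$win_end[i] - 1L)
    offset <- level[w][1] - mean(level[w] + lap[w])
    span <- segments$start[i]:(segments$end[i] - 1L)
    lap[span] <- lap[span] + level[span] + offset
  }

  set.seed(config$seed)
  tt <- (seq_len(n) - 1) / fs
  nz <- config$noise
  ecg <- ecg + nz$mains_amp * sin(2 * pi * 50 * tt) +
    nz$ecg_drift_amp * sin(2 * pi * tt / nz$ecg_drift_period) +
    stats::rnorm(n, 0, nz$ecg_sd)
  lap <- lap + nz$lap_drift_amp * sin(2 * pi * tt / nz$lap_drift_period) +
    stats::rnorm(n, 0, nz$lap_sd)
  cs <- cs + stats::rnorm(n, 0, nz$cs_sd)

  beats <- do.call(rbind, beats)
  per_rate <- data.frame(rate = config$rates,
                         mlap = mlap_profile(config, config$rates),
                         pr_ms = pr_profile(config, config$rates))
  wck_rates <- per_rate$rate[per_rate$rate >= config$wenckebach_rate]
  pre_wck <- per_rate$rate[per_rate$rate < config$wenckebach_rate]
  max_rate <- if (!length(wck_rates)) max(per_rate$rate)
    else if (length(pre_wck)) max(pre_wck)
    else NA_real_  # Wenckebach already at the first scheduled rate

  recording <- structure(list(sample_rate = fs,
                              channels = list(ecg = ecg, lap = lap,
                                              cs = cs),
                              patient_id = sprintf("synthetic-%04d",
                                                   config$seed)),
                         class = "pacing_recording")
  truth <- list(segments = segments, beats = beats, per_rate = per_rate,
                sinus_hr = config$sinus_hr, sinus_mlap = config$m_sinus,
                optimal_rate = per_rate$rate[which.min(per_rate$mlap)],
                max_rate = max_rate)
  list(recording = recording, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient generator parameters around the defaults with the
#' given dispersions (normal draws, clamped to valid ranges; optimum rate
#' snapped to the schedule decade) and returns one configuration per
#' patient plus the programmed truth table. Recordings are materialised
#' lazily with [cohort_recording()] to keep memory bounded.
#'
#' @param n cohort size.
#' @param seed master seed; patient `i` gets noise seed `seed + i`.
#' @param dispersion list of SDs: `sinus_hr`, `m_sinus`, `depth`, `r_opt`,
#'   `pr0`, `pr_slope`. Zero dispersion reproduces the default recording.
#' @param segment_length segment duration (s) for all patients.
#' @return list with `configs` (list of [synthetic_config()]) and `truth`
#'   (data.frame: patient, sinus_hr, sinus_mlap, depth, optimal_rate,
#'   delta_mlap_opt, max_rate).
#' @export
generate_cohort <- function(n, seed = 1,
                            dispersion = list(sinus_hr = 5, m_sinus = 3,
                                              depth = 1.4, r_opt = 15,
                                              pr0 = 20, pr_slope = 0.3),
                            segment_length = 30) {
  stopifnot(n >= 1)
  set.seed(seed)
  base <- synthetic_config()
  configs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    hr <- min(75, max(42, round(stats::rnorm(1, base$sinus_hr,
                                             dispersion$sinus_hr))))
    wck <- sample(c(120, 130, 140), 1)
    first <- ceiling(hr / 10) * 10
    if (first <= hr) first <- first + 10
    ro <- round(stats::rnorm(1, base$r_opt, dispersion$r_opt) / 10) * 10
    ro <- min(max(ro, first), wck - 10)
    cfg <- synthetic_config(
      seed = seed + i, sinus_hr = hr,
      segment_length = segment_length,
      m_sinus = max(5, stats::rnorm(1, base$m_sinus, dispersion$m_sinus)),
      depth = max(0.3, stats::rnorm(1, base$depth, dispersion$depth)),
      r_opt = ro,
      pr0 = max(80, stats::rnorm(1, base$pr0, dispersion$pr0)),
      pr_slope = max(0.5, stats::rnorm(1, base$pr_slope,
                                       dispersion$pr_slope)),
      wenckebach_rate = wck)
    configs[[i]] <- cfg
    rows[[i]] <- data.frame(
      patient = i, sinus_hr = cfg$sinus_hr, sinus_mlap = cfg$m_sinus,
      depth = cfg$depth,
      optimal_rate = cfg$rates[which.min(mlap_profile(cfg, cfg$rates))],
      delta_mlap_opt = min(mlap_profile(cfg, cfg$rates)) - cfg$m_sinus,
      max_rate = cfg$wenckebach_rate - 10)
  }
  list(configs = configs, truth = do.call(rbind, rows))
}

#' Materialise one cohort recording
#'
#' @param cohort result of [generate_cohort()].
#' @param i patient index.
#' @return as [generate_recording()].
#' @export
cohort_recording <- function(cohort, i) {
  generate_recording(cohort$configs[[i]])
}

#' Model-driven synthetic recording
#'
#' Ties the two halves of the package together: the LA pressure channel of
#' each segment is the tiled steady-beat LA pressure waveform of the
#' regulated circulation model at that segment's (rate, PR), while the ECG
#' and CS channels are synthesised from the same activation timing. The
#' truth carries the model's own beat metrics per segment.
#'
#' @param phenotype a [hfpef_phenotype()].
#' @param rates paced rates (bpm) to include, each as one 30-s segment
#'   flanked by sinus segments at the phenotype's baseline timing.
#' @param pr_fun PR-rate relation, a [pr_rate_function()].
#' @param circulation a [circulation_params()].
#' @param segment_length segment duration (s).
#' @param noise as in [synthetic_config()]; defaults to noise-free.
#' @param seed RNG seed (used only when noise is nonzero).
#' @return list with `recording` and `truth` (`segments` including the
#'   model `mlap` per segment, and `metrics` rows from [beat_metrics()]).
#' @export
model_driven_recording <- function(phenotype, rates = c(60, 90, 120),
                                   pr_fun = pr_rate_function(),
                                   circulation = circulation_params(),
                                   segment_length = 30,
                                   noise = NULL, seed = 1) {
  fs <- 1000
  seg_n <- round(segment_length * fs)
  win_n <- round(10 * fs)
  ref <- steady_regulated(phenotype, circulation)
  mo <- synthetic_config()$morphology

  seg_defs <- list(list(kind = "sinus", rate = NA, timing = phenotype$timing,
                        sim = ref))
  for (r in rates) {
    tm <- activation_timing(r, pr_fun(r), "av_sequential")
    sim <- steady_regulated(phenotype, ref$circulation, tm,
                            state = ref$state)
    if (!sim$regulation_converged) {
      warning(sprintf("segment at %g bpm skipped: regulation not converged", r))
      next
    }
    seg_defs <- c(seg_defs,
                  list(list(kind = "paced", rate = r, timing = tm,
                            sim = sim)),
                  list(list(kind = "sinus", rate = NA,
                            timing = phenotype$timing, sim = ref)))
  }

  nseg <- length(seg_defs)
  n <- nseg * seg_n
  ecg <- numeric(n); lap <- numeric(n); cs <- numeric(n)
  rows <- vector("list", nseg)
  metr <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    sd <- seg_defs[[i]]
    start <- (i - 1L) * seg_n + 1L
    cyc_n <- round(sd$timing$cycle_length)     # samples per beat at 1 kHz
    beat <- sd$sim$trajectory$p_la[seq_len(cyc_n)]
    reps <- ceiling(seg_n / cyc_n)
    lap[start:(start + seg_n - 1L)] <- rep(beat, reps)[seq_len(seg_n)]
    pr_ms <- sd$timing$pr_interval
    onsets <- seq(0, segment_length - cyc_n / fs, by = cyc_n / fs) +
      (start - 1) / fs
    for (ta in onsets) {
      tq <- ta + pr_ms / 1000
      if (sd$kind == "paced") {
        i0 <- round(ta * fs) + 1L
        i1 <- min(n, i0 + 1L)
        cs[i0:i1] <- cs[i0:i1] + mo$spike_amp
        i2 <- min(n, i1 + 1L)
        if (i2 > i1) cs[i2] <- cs[i2] - mo$spike_amp
      } else {
        ecg <- add_bump(ecg, fs, ta + 2 * mo$p_sigma, mo$p_amp, mo$p_sigma)
      }
      qc <- tq + 2 * mo$qrs_sigma
      ecg <- add_bump(ecg, fs, qc, mo$qrs_amp, mo$qrs_sigma)
      ecg <- add_bump(ecg, fs, qc + 0.30 * sqrt(cyc_n / fs), mo$t_amp,
                      mo$t_sigma)
    }
    rows[[i]] <- data.frame(kind = sd$kind, rate = sd$rate,
                            pr_ms = pr_ms, start = start,
                            end = start + seg_n,
                            win_start = start + seg_n - win_n,
                            win_end = start + seg_n,
                            mlap = sd$sim$metrics$mlap)
    metr[[i]] <- sd$sim$metrics
  }
  if (!is.null(noise)) {
    set.seed(seed)
    ecg <- ecg + stats::rnorm(n, 0, noise$ecg_sd)
    lap <- lap + stats::rnorm(n, 0, noise$lap_sd)
    cs <- cs + stats::rnorm(n, 0, noise$cs_sd)
  }
  recording <- structure(list(sample_rate = fs,
                              channels = list(ecg = ecg, lap = lap,
                                              cs = cs),
                              patient_id = "model-driven"),
                         class = "pacing_recording")
  list(recording = recording,
       truth = list(segments = do.call(rbind, rows),
                    metrics = do.call(rbind, metr)))
}
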