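# Clinical signal pipeline: ECG/LA-pressure/CS preprocessing, beat and
# pacing-spike detection, protocol segmentation, per-rate mLAP and PR
# extraction, and paired cohort statistics.

# Zero-phase filtering with linear-prediction padding. Plain filtfilt
# leaves edge transients; odd-reflection padding keeps the signal value
# continuous but reverses its slope, and the resulting kink makes
# high-Q filters (the 50 Hz notch) ring into the signal. An AR extension
# fitted to the edge continues narrowband content coherently, so the
# filters reach steady state inside the pad. Falls back to odd reflection
# when the AR fit is degenerate (e.g. constant signal).
filtfilt_pad <- function(b, a, x, n_pad = NULL) {
  n <- length(x)
  if (is.null(n_pad)) n_pad <- min(n - 1L, 1000L)
  if (n_pad < 1) return(signal::filtfilt(b, a, x))
  fit_len <- min(n, 2000L)
  ar_ext <- function(seg) {
    if (stats::sd(seg) < 1e-10 * (1 + abs(mean(seg))))
      return(rep(seg[length(seg)], n_pad))  # constant continues exactly
    fit <- tryCatch(stats::ar(seg, order.max = 12, method = "burg",
                              aic = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    as.numeric(stats::predict(fit, n.ahead = n_pad, se.fit = FALSE))
  }
  head_pad <- ar_ext(rev(x[seq_len(fit_len)]))
  head_pad <- if (is.null(head_pad)) 2 * x[1] - x[(n_pad + 1):2]
    else rev(head_pad)
  tail_pad <- ar_ext(x[(n - fit_len + 1):n])
  if (is.null(tail_pad)) tail_pad <- 2 * x[n] - x[(n - 1):(n - n_pad)]
  y <- signal::filtfilt(b, a, c(head_pad, x, tail_pad))
  y[(n_pad + 1):(n_pad + n)]
}

# RBJ biquad notch coefficients
notch_coef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Preprocess an ECG channel
#'
#' Band-pass 0.5-100 Hz (4th-order Butterworth, zero-phase), 50 Hz notch
#' (biquad, Q = 30, zero-phase), then subtraction of an 800-sample centred
#' moving median to remove residual baseline drift. Zero-phase application
#' keeps onset timings unshifted; the moving median shrinks to the valid
#' window at the edges.
#'
#' @param ecg numeric vector (mV).
#' @param sample_rate Hz, must be >= 250 so the 100 Hz edge is below
#'   Nyquist.
#' @return filtered vector, same length.
#' @export
preprocess_ecg <- function(ecg, sample_rate) {
  if (sample_rate < 250)
    stop("sample_rate must be >= 250 Hz for the 100 Hz band edge",
         call. = FALSE)
  bp <- signal::butter(2, c(0.5, 100) / (sample_rate / 2), type = "pass")
  # remove the mean first: the band-pass rejects DC at steady state anyway,
  # and a zero-mean input avoids the step transient at the pad boundary
  y <- filtfilt_pad(bp$b, bp$a, ecg - mean(ecg))
  nc <- notch_coef(50, sample_rate, Q = 30)
  y <- filtfilt_pad(nc$b, nc$a, y)
  k <- min(801L, length(y) - (1 - length(y) %% 2))
  if (k >= 3) y <- y - stats::runmed(y, k, endrule = "median")
  y
}

# Pan-Tompkins intermediate signals: 5-15 Hz band-passed ECG, squared
# derivative, and the moving-window integral.
pt_stages <- function(ecg, fs) {
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- filtfilt_pad(bp$b, bp$a, ecg)
  # 5-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4])
  d <- stats::filter(f, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- max(3L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  list(bp = f, sq = sq, mwi = as.numeric(mwi))
}

#' Detect R peaks (Pan-Tompkins)
#'
#' Classic Pan-Tompkins stages: 5-15 Hz band-pass emphasis, five-point
#' derivative, squaring, 150-ms moving-window integration, then adaptive
#' signal/noise thresholds with a 200-ms refractory period and search-back
#' when an expected beat is missed. All thresholds are relative to the
#' running peak estimates, so detections are invariant to amplitude
#' scaling. Each integrated-signal detection is refined to the maximum of
#' the band-passed ECG in a window around it.
#'
#' @param ecg preprocessed ECG (see [preprocess_ecg()]).
#' @param sample_rate Hz.
#' @return strictly increasing integer vector of R-peak sample indices
#'   (1-based).
#' @export
detect_r_peaks <- function(ecg, sample_rate) {
  fs <- sample_rate
  if (length(ecg) < 2 * fs)
    stop("signal shorter than 2 s: insufficient data for QRS detection",
         call. = FALSE)
  st <- pt_stages(ecg, fs)
  mwi <- st$mwi
  if (max(mwi) <= 0) return(integer(0))
  refr <- round(0.2 * fs)
  # candidate local maxima of the integrated signal, >= refractory apart
  d <- diff(mwi)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refr) {
      keep[i] <- TRUE
      last <- cand[i]
    } else if (mwi[cand[i]] > mwi[last]) {
      keep[which(cand == last)] <- FALSE
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  cand <- cand[keep]

  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_avg <- NA_real_
  for (i in seq_along(cand)) {
    pk <- cand[i]
    v <- mwi[pk]
    if (v > thr()) {
      spki <- 0.125 * v + 0.875 * spki
      qrs <- c(qrs, pk)
      if (length(qrs) >= 2) {
        rr <- diff(utils::tail(qrs, 9))
        rr_avg <- mean(rr)
      }
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: accept a sub-threshold candidate at half threshold if
      # the expected beat is overdue
      if (length(qrs) && !is.na(rr_avg) &&
          pk - qrs[length(qrs)] > 1.66 * rr_avg && v > 0.5 * thr()) {
        spki <- 0.25 * v + 0.75 * spki
        qrs <- c(qrs, pk)
      }
    }
  }
  if (!length(qrs)) return(integer(0))
  # refine on the band-passed signal
  half <- round(0.075 * fs)
  out <- vapply(qrs, function(pk) {
    lo <- max(1L, pk - half); hi <- min(length(ecg), pk + half)
    as.integer(lo + which.max(st$bp[lo:hi]) - 1L)
  }, integer(1))
  out <- sort(unique(out))
  out[c(TRUE, diff(out) >= refr)]
}

#' Detect atrial pacing spikes on the coronary sinus channel
#'
#' Flags samples where the first difference of the signal exceeds 8x its
#' rolling median absolute deviation, with a 100-ms refractory period.
#' Returns the onset (first supra-threshold sample) of each spike.
#'
#' @param cs coronary sinus channel (mV).
#' @param sample_rate Hz.
#' @return strictly increasing integer vector of spike onsets (possibly
#'   empty).
#' @export
detect_pacing_spikes <- function(cs, sample_rate) {
  n <- length(cs)
  if (n < 3) return(integer(0))
  d <- diff(cs)
  ad <- abs(d)
  k <- min(1001L, length(ad) - (1 - length(ad) %% 2))
  if (k < 3) return(integer(0))
  rmad <- stats::runmed(ad, k, endrule = "median") * 1.4826
  above <- which(ad > 8 * rmad + 1e-9)
  if (!length(above)) return(integer(0))
  refr <- round(0.1 * sample_rate)
  out <- integer(0)
  last <- -Inf
  for (i in above) {
    if (i - last >= refr) {
      out <- c(out, i + 1L)  # d[i] spans samples i:i+1; onset = i + 1
      last <- i
    }
  }
  out
}

#' Segment the alternating sinus/paced protocol
#'
#' Groups pacing spikes into contiguous paced stretches (inter-spike gap
#' below twice the local pacing interval); gaps between stretches, and the
#' leading/trailing stretches, become sinus segments. Each paced segment's
#' rate is the median inter-spike interval rounded to the nearest 10 bpm;
#' each segment's analysis window is its final 10 s.
#'
#' @param spikes spike onsets from [detect_pacing_spikes()].
#' @param r_peaks R peaks from [detect_r_peaks()] (used for the sinus-rate
#'   annotation).
#' @param sample_rate Hz.
#' @param n_samples recording length in samples.
#' @return data.frame with one row per segment: `kind` ("sinus"/"paced"),
#'   `rate` (bpm; NA for sinus), `start`, `end` (1-based, half-open
#'   \[start, end)), `win_start`, `win_end` (analysis window, same
#'   convention).
#' @export
segment_protocol <- function(spikes, r_peaks, sample_rate,
                             n_samples = NULL) {
  fs <- sample_rate
  if (is.null(n_samples))
    n_samples <- max(c(spikes, r_peaks, 0)) + fs
  win <- round(10 * fs)
  mk <- function(kind, rate, start, end) {
    ws <- max(start, end - win)
    data.frame(kind = kind, rate = rate, start = start, end = end,
               win_start = ws, win_end = end)
  }
  if (!length(spikes)) {
    warning("no pacing spikes found: treating whole recording as sinus")
    return(mk("sinus", NA_real_, 1L, n_samples + 1L))
  }
  # greedy clustering with a local interval estimate: a gap larger than
  # twice the running pacing interval of the current stretch starts a new
  # stretch (2.5 s fallback while a stretch has a single spike)
  gaps <- diff(spikes)
  starts <- 1L
  ends <- integer(0)
  cur <- numeric(0)
  for (g in seq_along(gaps)) {
    lim <- if (length(cur)) 2 * stats::median(utils::tail(cur, 5))
      else 2.5 * fs
    if (gaps[g] > lim) {
      ends <- c(ends, g)
      starts <- c(starts, g + 1L)
      cur <- numeric(0)
    } else {
      cur <- c(cur, gaps[g])
    }
  }
  ends <- c(ends, length(spikes))
  segs <- list()
  prev_end <- 1L
  for (j in seq_along(starts)) {
    sp <- spikes[starts[j]:ends[j]]
    if (length(sp) < 3) next
    ivl <- stats::median(diff(sp))
    rate <- round(60 * fs / ivl / 10) * 10
    seg_start <- sp[1]
    seg_end <- sp[length(sp)] + round(ivl)
    if (seg_start > prev_end)
      segs[[length(segs) + 1L]] <- mk("sinus", NA_real_, prev_end, seg_start)
    segs[[length(segs) + 1L]] <- mk("paced", rate, seg_start, seg_end)
    prev_end <- seg_end
  }
  if (prev_end < n_samples + 1L)
    segs[[length(segs) + 1L]] <- mk("sinus", NA_real_, prev_end,
                                    n_samples + 1L)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Per-rate mLAP response
#'
#' Computes each segment's mean LA pressure over its analysis window, then
#' for every paced rate the change versus the mean of the two flanking
#' sinus windows (a single flank is used, and flagged, at the protocol
#' edges). No sample outside an analysis window contributes.
#'
#' @param lap LA pressure channel (mmHg).
#' @param segments data.frame from [segment_protocol()].
#' @return list with `segments` (input plus `mlap` column), and `per_rate`
#'   (data.frame: rate, mlap, delta_mlap, single_flank).
#' @export
mlap_response <- function(lap, segments) {
  if (is.null(lap) || !length(lap))
    stop("LA pressure channel missing", call. = FALSE)
  segments$mlap <- vapply(seq_len(nrow(segments)), function(i) {
    mean(lap[segments$win_start[i]:(segments$win_end[i] - 1L)])
  }, numeric(1))
  paced <- which(segments$kind == "paced")
  rows <- lapply(paced, function(i) {
    sin_prev <- if (i > 1 && segments$kind[i - 1] == "sinus")
      segments$mlap[i - 1] else NA_real_
    sin_next <- if (i < nrow(segments) && segments$kind[i + 1] == "sinus")
      segments$mlap[i + 1] else NA_real_
    flanks <- c(sin_prev, sin_next)
    data.frame(rate = segments$rate[i], mlap = segments$mlap[i],
               delta_mlap = segments$mlap[i] - mean(flanks, na.rm = TRUE),
               single_flank = sum(!is.na(flanks)) < 2)
  })
  per_rate <- do.call(rbind, rows)
  list(segments = segments, per_rate = per_rate)
}

# QRS onset: scan back (<= 80 ms) from the R peak for the sample where the
# 10-ms slope of the smoothed energy envelope falls below 5% of its local
# peak slope.
qrs_onset_one <- function(env, r_peak, fs) {
  back <- round(0.08 * fs)
  slope_w <- max(1L, round(0.010 * fs))
  lo <- max(slope_w + 1L, r_peak - back)
  if (r_peak <= lo) return(NA_integer_)
  idx <- lo:r_peak
  slope <- env[idx] - env[idx - slope_w]
  ref <- max(slope)
  if (ref <= 0) return(lo)
  onset <- r_peak
  for (j in rev(seq_along(idx))) {
    if (slope[j] < 0.05 * ref) { onset <- idx[j]; break }
    onset <- idx[j]
  }
  onset
}

# P-wave onset in the 300-50 ms pre-QRS window: foot of the maximal
# positive slope of the smoothed ECG.
p_onset_one <- function(ecg_s, qrs_on, fs) {
  lo <- qrs_on - round(0.300 * fs)
  hi <- qrs_on - round(0.050 * fs)
  if (lo < 2 || hi <= lo) return(NA_integer_)
  slope_w <- max(1L, round(0.010 * fs))
  idx <- max(lo, slope_w + 1L):hi
  slope <- ecg_s[idx] - ecg_s[idx - slope_w]
  if (!length(slope)) return(NA_integer_)
  imax <- which.max(slope)
  ref <- slope[imax]
  if (ref <= 0) return(NA_integer_)
  onset <- idx[imax]
  for (j in rev(seq_len(imax))) {
    if (slope[j] < 0.10 * ref) { onset <- idx[j]; break }
    onset <- idx[j]
  }
  onset
}

#' Per-beat electrical annotations and PR intervals
#'
#' For every detected R peak: the QRS onset (energy-envelope slope
#' criterion, scanning back at most 80 ms), the atrial onset (nearest
#' preceding pacing spike for paced beats, P-wave onset by derivative
#' threshold in the 300-50 ms pre-QRS window for intrinsic beats), and the
#' PR interval. Pacing spikes with no following QRS within one pacing cycle
#' are emitted as dropped beats (Wenckebach surrogate) and carry no PR.
#' Retained PR intervals outside (40, 400) ms are flagged (`pr_valid =
#' FALSE`) and must not enter averages.
#'
#' @param ecg preprocessed ECG.
#' @param r_peaks from [detect_r_peaks()].
#' @param spikes from [detect_pacing_spikes()].
#' @param sample_rate Hz.
#' @return data.frame, one row per beat (and one per dropped spike):
#'   `r_peak`, `qrs_onset`, `atrial_onset`, `pr_ms`, `paced`, `dropped`,
#'   `pr_valid`.
#' @export
pr_intervals <- function(ecg, r_peaks, spikes, sample_rate) {
  fs <- sample_rate
  st <- pt_stages(ecg, fs)
  # short smoothing for onset work (20-ms MA of the squared band-pass)
  w <- max(3L, round(0.020 * fs))
  env <- as.numeric(stats::filter(st$bp^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  ecg_s <- as.numeric(stats::filter(ecg, rep(1 / w, w), sides = 2))
  ecg_s[is.na(ecg_s)] <- 0

  pace_ivl <- if (length(spikes) >= 2) stats::median(diff(spikes)) else Inf

  rows <- vector("list", length(r_peaks) + length(spikes))
  nr <- 0L
  used_spikes <- logical(length(spikes))
  for (r in r_peaks) {
    qon <- qrs_onset_one(env, r, fs)
    if (is.na(qon)) next
    prev_sp <- if (length(spikes)) which(spikes < qon) else integer(0)
    paced <- FALSE
    aon <- NA_integer_
    if (length(prev_sp)) {
      sp <- spikes[max(prev_sp)]
      # a spike "belongs" to this beat if within ~one pacing cycle
      if (qon - sp < 1.05 * pace_ivl) {
        paced <- TRUE
        aon <- sp
        used_spikes[max(prev_sp)] <- TRUE
      }
    }
    if (!paced) aon <- p_onset_one(ecg_s, qon, fs)
    if (is.na(aon)) next
    pr <- (qon - aon) / fs * 1000
    nr <- nr + 1L
    rows[[nr]] <- data.frame(r_peak = r, qrs_onset = qon,
                             atrial_onset = as.integer(aon), pr_ms = pr,
                             paced = paced, dropped = FALSE,
                             pr_valid = pr > 40 && pr < 400)
  }
  # dropped beats: spikes with no QRS onset within one pacing cycle
  if (length(spikes) && is.finite(pace_ivl)) {
    qons <- vapply(rows[seq_len(nr)], function(x) x$qrs_onset, numeric(1))
    for (j in seq_along(spikes)) {
      if (used_spikes[j]) next
      sp <- spikes[j]
      if (!any(qons > sp & qons - sp < 1.05 * pace_ivl)) {
        nr <- nr + 1L
        rows[[nr]] <- data.frame(r_peak = NA_integer_,
                                 qrs_onset = NA_integer_,
                                 atrial_onset = sp, pr_ms = NA_real_,
                                 paced = TRUE, dropped = TRUE,
                                 pr_valid = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  out[order(out$atrial_onset), ]
}

#' Full per-patient analysis of one recording
#'
#' Runs the whole pipeline — preprocessing, R-peak and spike detection,
#' protocol segmentation, per-rate mLAP and PR extraction — and summarises
#' the patient: sinus heart rate and mLAP, per-rate table, the optimal rate
#' (lowest mLAP, ties toward the lower rate) and the maximum rate (last
#' rate before the one that induced Wenckebach block; the highest tested
#' rate when no Wenckebach was seen).
#'
#' @param recording a `pacing_recording` (see [read_recording_csv()] or
#'   [generate_recording()]).
#' @return list with `per_rate` (rate, mlap, delta_mlap, mean_pr_ms,
#'   exceeds_sinus, single_flank, wenckebach), `sinus_hr`, `sinus_mlap`,
#'   `optimal_rate`, `max_rate`, `wenckebach_observed`, plus the
#'   intermediate `segments` and `beats` tables.
#' @export
analyze_recording <- function(recording) {
  fs <- recording$sample_rate
  ecg <- preprocess_ecg(recording$channels$ecg, fs)
  r_peaks <- detect_r_peaks(ecg, fs)
  spikes <- detect_pacing_spikes(recording$channels$cs, fs)
  segments <- segment_protocol(spikes, r_peaks, fs,
                               n_samples = length(ecg))
  ml <- mlap_response(recording$channels$lap, segments)
  beats <- pr_intervals(ecg, r_peaks, spikes, fs)

  seg_tbl <- ml$segments
  # mean PR and dropped-beat bookkeeping per segment
  seg_stat <- lapply(seq_len(nrow(seg_tbl)), function(i) {
    b <- beats[beats$atrial_onset >= seg_tbl$start[i] &
                 beats$atrial_onset < seg_tbl$end[i], ]
    c(pr = mean(b$pr_ms[b$pr_valid & !b$dropped]),
      dropped = sum(b$dropped))
  })
  seg_tbl$mean_pr_ms <- vapply(seg_stat, `[[`, numeric(1), "pr")
  seg_tbl$n_dropped <- vapply(seg_stat, `[[`, numeric(1), "dropped")

  sinus_idx <- which(seg_tbl$kind == "sinus")
  sinus_mlap <- mean(seg_tbl$mlap[sinus_idx])
  sinus_rr <- unlist(lapply(sinus_idx, function(i) {
    p <- r_peaks[r_peaks >= seg_tbl$win_start[i] &
                   r_peaks < seg_tbl$win_end[i]]
    diff(p)
  }))
  sinus_hr <- if (length(sinus_rr)) 60 * fs / stats::median(sinus_rr)
    else NA_real_

  paced_idx <- which(seg_tbl$kind == "paced")
  per_rate <- ml$per_rate
  per_rate$mean_pr_ms <- seg_tbl$mean_pr_ms[paced_idx]
  per_rate$wenckebach <- seg_tbl$n_dropped[paced_idx] > 0
  per_rate$exceeds_sinus <- per_rate$mlap > sinus_mlap

  opt_i <- which.min(per_rate$mlap)  # first minimum = lowest rate on ties
  wck <- which(per_rate$wenckebach)
  if (length(wck)) {
    first_w <- min(wck)
    max_rate <- if (first_w > 1) per_rate$rate[first_w - 1] else NA_real_
    wobs <- TRUE
  } else {
    max_rate <- per_rate$rate[nrow(per_rate)]
    wobs <- FALSE
  }
  list(per_rate = per_rate, sinus_hr = sinus_hr, sinus_mlap = sinus_mlap,
       optimal_rate = per_rate$rate[opt_i], max_rate = max_rate,
       wenckebach_observed = wobs, segments = seg_tbl, beats = beats)
}

#' Paired cohort statistics
#'
#' Shapiro-Wilk normality on the paired differences (alpha = 0.05) selects
#' between the paired Student t-test and the Wilcoxon signed-rank test;
#' reports the two-sided p-value, mean +/- SD of the differences with the
#' t-based 95% CI, and medians \[IQR\] of both margins.
#'
#' @param baseline,condition paired numeric vectors, equal length >= 3,
#'   no missing values.
#' @return list: `test` ("paired t" or "wilcoxon"), `p`, `shapiro_p`,
#'   `mean_diff`, `sd_diff`, `ci95` (length 2), `median_diff`, `iqr_diff`,
#'   `n`.
#' @export
cohort_stats <- function(baseline, condition) {
  if (length(baseline) != length(condition))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(baseline) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(baseline) || anyNA(condition))
    stop("missing values not allowed", call. = FALSE)
  d <- condition - baseline
  if (stats::sd(d) < 1e-12) {
    # degenerate: all paired differences identical; no dispersion to test
    return(list(test = "paired t",
                p = if (abs(mean(d)) < 1e-12) 1 else 0,
                shapiro_p = NA_real_, mean_diff = mean(d), sd_diff = 0,
                ci95 = c(mean(d), mean(d)), median_diff = stats::median(d),
                iqr_diff = as.numeric(stats::quantile(d, c(0.25, 0.75))),
                n = length(d)))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= 0.05) {
    ht <- stats::t.test(condition, baseline, paired = TRUE)
    test <- "paired t"
  } else {
    ht <- stats::wilcox.test(condition, baseline, paired = TRUE,
                             exact = FALSE)
    test <- "wilcoxon"
  }
  tt <- stats::t.test(d)  # CI of the mean difference is always t-based
  list(test = test, p = ht$p.value, shapiro_p = sw$p.value,
       mean_diff = mean(d), sd_diff = stats::sd(d),
       ci95 = as.numeric(tt$conf.int),
       median_diff = stats::median(d),
       iqr_diff = as.numeric(stats::quantile(d, c(0.25, 0.75))),
       n = length(d))
}
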