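# Shared, lazily-computed fixtures. The regulated baseline run is used by
# several test files; computing it once keeps the suite fast.

.fixtures <- new.env(parent = emptyenv())

baseline_run <- function() {
  if (is.null(.fixtures$baseline))
    .fixtures$baseline <- steady_regulated(hfpef_phenotype(),
                                           circulation_params())
  .fixtures$baseline
}

# synthetic ECG: Gaussian QRS bumps at a fixed rate plus white noise at a
# given SNR (dB); returns signal and true peak positions (samples)
synth_ecg <- function(rate_bpm, dur_s, fs = 1000, snr_db = 20, seed = 1) {
  set.seed(seed)
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  centers <- seq(0.4, dur_s - 0.4, by = 60 / rate_bpm)
  sig <- numeric(n)
  for (ct in centers)
    sig <- sig + exp(-((t - ct) / 0.010)^2 / 2)
  p_sig <- mean(sig^2)
  noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
  list(ecg = sig + rnorm(n, 0, noise_sd),
       peaks = round(centers * fs) + 1L)
}

# a one-beat trajectory data.frame with prescribed channels, defaults flat
fake_beat <- function(n = 1000, p_la = 10, q_mv = 0, p_lv = 10,
                      p_sa = 90, v_la = 80, v_lv = 120) {
  len <- n + 1L
  expand <- function(x) if (length(x) == 1) rep(x, len) else c(x, x[1])
  data.frame(t_s = (0:n) / 1000, v_la = expand(v_la), v_lv = expand(v_lv),
             v_ra = 80, v_rv = 110, v_sa = 700, v_sv = 2800, v_pa = 180,
             v_pv = 480, p_la = expand(p_la), p_lv = expand(p_lv),
             p_ra = 5, p_rv = 8, p_sa = expand(p_sa), p_sv = 6, p_pa = 15,
             p_pv = 12, q_mv = expand(q_mv), q_av = 0, q_tv = 0, q_pv = 0,
             act_lv = 0)
}
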