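# Core simulation wrapper around the compiled RK4 integrator.

STATE_NAMES <- c("v_la", "v_lv", "v_ra", "v_rv", "v_sa", "v_sv",
                 "v_pa", "v_pv", "q_mv_state")
TRAJ_NAMES <- c("t_s", "v_la", "v_lv", "v_ra", "v_rv", "v_sa", "v_sv",
                "v_pa", "v_pv", "p_la", "p_lv", "p_ra", "p_rv", "p_sa",
                "p_sv", "p_pa", "p_pv", "q_mv", "q_av", "q_tv", "q_pv",
                "act_lv")

# Build the parameter list consumed by the C++ integrator. Times go in as
# seconds; activation durations are rescaled with sqrt(cycle length),
# mimicking rate-dependent shortening of systole.
build_prm <- function(heart, circulation, timing,
                      valves_open = FALSE, activation_const = NULL) {
  cl_s <- timing$cycle_length / 1000
  pr_s <- (timing$pr_interval %% timing$cycle_length) / 1000
  scale_d <- sqrt(cl_s / 1.0)
  ch <- matrix(0, 4, 8)
  order <- c("LA", "LV", "RA", "RV")
  ton <- c(0, pr_s, 0, pr_s)
  for (i in seq_along(order)) {
    p <- heart[[order[i]]]
    d_eff <- min(p$d_act / 1000 * scale_d, 0.85 * cl_s)
    ch[i, ] <- c(p$V0, p$E_act, p$c, p$P_ref, p$k, ton[i], d_eff,
                 p$tau / 1000)
  }
  peri <- circulation$pericardium
  list(chambers = ch, CL = cl_s,
       vessels = c(circulation$C_sa, circulation$V0_sa,
                   circulation$C_sv, circulation$V0_sv,
                   circulation$C_pa, circulation$V0_pa,
                   circulation$C_pv, circulation$V0_pv),
       resistances = c(circulation$R_sys, circulation$R_pul,
                       circulation$R_sv_ra, circulation$R_pv_la),
       valves = c(circulation$R_mv, circulation$L_mv, circulation$R_av,
                  circulation$R_tv, circulation$R_pv),
       pericardium = c(as.integer(isTRUE(peri$enabled)), peri$P_ref,
                       peri$k, peri$V0),
       valves_open = as.integer(valves_open),
       act_const = as.integer(!is.null(activation_const)),
       a_const = if (is.null(activation_const)) 0 else activation_const)
}

#' Initial compartment volumes
#'
#' Distributes the total blood volume over the eight compartments with a
#' physiologically plausible split; the remainder (most of the volume) goes
#' to the systemic veins.
#'
#' @param circulation a [circulation_params()].
#' @return named state vector (mL; last element is the mitral flow state).
#' @export
initial_state <- function(circulation) {
  s <- c(v_la = 90, v_lv = 130, v_ra = 85, v_rv = 120,
         v_sa = circulation$V0_sa + 90 * circulation$C_sa,
         v_sv = 0,
         v_pa = circulation$V0_pa + 15 * circulation$C_pa,
         v_pv = circulation$V0_pv + 12 * circulation$C_pv,
         q_mv_state = 0)
  s["v_sv"] <- circulation$V_tot - sum(s[1:8])
  if (s["v_sv"] <= 0)
    stop("V_tot too small to fill the circulation", call. = FALSE)
  s
}

#' Simulate the closed-loop circulation
#'
#' Integrates the model for a fixed number of beats, or until the periodic
#' steady state is reached (state vectors at consecutive beat onsets differ
#' by less than `steady_tol` in maximum relative norm). Beat boundaries are
#' at atrial activation onset.
#'
#' @param phenotype a [hfpef_phenotype()]; its scalers are applied to the
#'   normal heart.
#' @param circulation a [circulation_params()].
#' @param timing an [activation_timing()]; defaults to the phenotype's.
#' @param n_beats fixed number of beats; `NULL` (default) runs to steady
#'   state with a cap of `max_beats`.
#' @param state initial state (see [initial_state()]); `NULL` builds one.
#' @param dt integration step (s); output is on a 1-ms grid.
#' @param steady_tol relative steady-state criterion (default 0.001).
#' @param max_beats cap when running to steady state.
#' @param valves_open lock all valves open (linear bidirectional flow);
#'   used by the static-equilibrium oracle.
#' @param activation_const freeze all activations at this constant level
#'   (`NULL` = normal time-varying activation).
#' @return list with `trajectory` (data.frame over the final beat, 1-ms
#'   grid), `metrics` ([beat_metrics()] of that beat), `state` (final state
#'   vector), `onsets` (matrix of beat-onset states), `converged`, `n_beats`.
#' @export
simulate_model <- function(phenotype, circulation,
                           timing = phenotype$timing,
                           n_beats = NULL, state = NULL, dt = 1e-4,
                           steady_tol = 1e-3, max_beats = 200,
                           valves_open = FALSE, activation_const = NULL) {
  heart <- apply_phenotype(phenotype)
  prm <- build_prm(heart, circulation, timing, valves_open,
                   activation_const)
  if (is.null(state)) state <- initial_state(circulation)
  state <- as.numeric(state)

  run <- function(y0, nb, save) {
    simulate_beats_cpp(y0, prm, nb, dt, 1e-3, save)
  }

  converged <- FALSE
  onsets <- matrix(state, nrow = 1)
  if (!is.null(n_beats)) {
    res <- run(state, n_beats, 2L)
    onsets <- res$onsets
    nb <- n_beats
  } else {
    chunk <- 4L
    nb <- 0
    prev <- state
    repeat {
      r <- run(prev, chunk, 0L)
      onsets <- rbind(onsets, r$onsets[-1, , drop = FALSE])
      nb <- nb + chunk
      o <- r$onsets
      rel <- abs(o[nrow(o), 1:8] - o[nrow(o) - 1, 1:8]) /
        pmax(abs(o[nrow(o) - 1, 1:8]), 1)
      prev <- r$state
      if (max(rel) < steady_tol) { converged <- TRUE; break }
      if (nb >= max_beats) break
    }
    res <- run(prev, 1L, 2L)
    nb <- nb + 1
    onsets <- rbind(onsets, res$onsets[-1, , drop = FALSE])
  }
  traj <- res$traj
  colnames(traj) <- TRAJ_NAMES
  traj <- as.data.frame(traj)
  nper <- round(timing$cycle_length)
  last <- traj[(nrow(traj) - nper):nrow(traj), ]
  last$t_s <- last$t_s - last$t_s[1]
  metrics <- beat_metrics(last, timing)
  list(trajectory = last, full_trajectory = if (!is.null(n_beats)) traj,
       metrics = metrics, state = res$state, onsets = onsets,
       converged = converged || !is.null(n_beats), n_beats = nb)
}

#' Per-beat haemodynamic summary
#'
#' Computes the beat-level metrics from a trajectory spanning exactly one
#' cardiac cycle on a 1-ms grid starting at atrial activation onset:
#' time-averaged and peak LA pressure, LV end-diastolic pressure and volume
#' (taken at ventricular activation onset), stroke volume, cardiac output,
#' mean arterial pressure, maximal LA volume, and the E/A transmitral flow
#' peaks. E and A are the two mitral-flow maxima separated by the interior
#' minimum between them; when no interior minimum below 20% of the smaller
#' peak exists the waves are flagged as fused and the ratio is `NA`.
#'
#' @param traj data.frame with one full cycle of samples (columns as
#'   produced by [simulate_model()]).
#' @param timing the [activation_timing()] of the simulated beat.
#' @return one-row data.frame (`mlap`, `peak_lap`, `lvedp`, `lvedv`, `sv`,
#'   `co` (from SV), `co_flow` (beat-averaged aortic flow), `map`,
#'   `lav_max`, `e_peak`, `a_peak`, `ea_ratio`, `ea_fused`).
#' @export
beat_metrics <- function(traj, timing) {
  n <- nrow(traj) - 1L
  if (n < 10) stop("trajectory too short for one beat", call. = FALSE)
  ends_rel <- abs(traj$v_lv[1] - traj$v_lv[n + 1]) /
    max(abs(traj$v_lv[1]), 1)
  if (ends_rel > 0.01)
    warning("trajectory endpoints differ by more than 1%: beat may not be periodic")
  cyc <- traj[seq_len(n), ]
  mlap <- mean(cyc$p_la)
  peak_lap <- max(cyc$p_la)
  pr_idx <- round(timing$pr_interval %% timing$cycle_length) + 1L
  pr_idx <- min(max(pr_idx, 1L), n)
  lvedp <- cyc$p_lv[pr_idx]
  lvedv <- cyc$v_lv[pr_idx]
  sv <- lvedv - min(cyc$v_lv)
  co <- sv * timing$heart_rate / 1000
  co_flow <- mean(cyc$q_av) * 60 / 1000   # beat-averaged systemic flow
  map <- mean(cyc$p_sa)
  lav_max <- max(cyc$v_la)

  ea <- ea_peaks(cyc$q_mv, pr_idx)
  data.frame(mlap = mlap, peak_lap = peak_lap, lvedp = lvedp,
             lvedv = lvedv, sv = sv, co = co, co_flow = co_flow,
             map = map, lav_max = lav_max, e_peak = ea$e, a_peak = ea$a,
             ea_ratio = ea$ratio, ea_fused = ea$fused)
}

# E/A decomposition of the mitral flow over one beat. The trace is rotated
# to start at ventricular activation onset so that diastole is contiguous
# and E precedes A chronologically; E is the global diastolic maximum, A the
# largest later local maximum separated from E by an interior minimum below
# 20% of the smaller peak.
ea_peaks <- function(q_mv, pr_idx) {
  n <- length(q_mv)
  rot <- q_mv[c(pr_idx:n, seq_len(pr_idx - 1L))]
  # light smoothing so inertance ripple does not split a wave into
  # spurious local maxima (11-sample ~ 11 ms moving average)
  rot <- as.numeric(stats::filter(rot, rep(1 / 11, 11), sides = 2,
                                  circular = TRUE))
  qmax <- max(rot)
  if (qmax <= 0)
    return(list(e = 0, a = 0, ratio = NA_real_, fused = TRUE))
  d <- diff(rot)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  pk <- pk[rot[pk] > 0.05 * qmax]
  i_e <- which.max(rot)
  cand <- pk[pk > i_e]
  best <- NA_integer_; best_val <- -Inf
  for (i_a in cand) {
    interior_min <- min(rot[i_e:i_a])
    if (interior_min < 0.2 * min(rot[i_e], rot[i_a]) &&
        rot[i_a] > best_val) {
      best <- i_a; best_val <- rot[i_a]
    }
  }
  if (is.na(best))
    return(list(e = qmax, a = qmax, ratio = NA_real_, fused = TRUE))
  list(e = rot[i_e], a = rot[best], ratio = rot[i_e] / rot[best],
       fused = FALSE)
}

#' Closed-form static equilibrium of the open-valve circulation
#'
#' With all activations frozen at a constant level and every valve locked
#' open, the closed loop has a static equilibrium in which all flows vanish
#' and every compartment sits at one common pressure `p*` determined by
#' volume conservation: vascular compartments hold `V0 + C p*`, chambers
#' hold the inverse of their (passive + frozen-active) pressure law. This
#' is the independent oracle for the relaxation behaviour of the dynamic
#' model.
#'
#' @param phenotype a [hfpef_phenotype()].
#' @param circulation a [circulation_params()]; the pericardium is ignored
#'   (disable it in the matching simulation).
#' @param a_const frozen activation level (default 0).
#' @return list with `pressure` (mmHg) and named compartment `volumes` (mL).
#' @export
static_equilibrium <- function(phenotype, circulation, a_const = 0) {
  heart <- apply_phenotype(phenotype)
  ch_vol <- function(p, cp) {
    # invert p = a c E (V - V0) + Pref (exp(k (V/V0 - 1)) - 1) for V
    f <- function(V) a_const * cp$c * cp$E_act * (V - cp$V0) +
      cp$P_ref * (exp(pmin(cp$k * (V / cp$V0 - 1), 50)) - 1) - p
    stats::uniroot(f, c(1e-6, 20 * cp$V0), tol = 1e-10)$root
  }
  total <- function(p) {
    vch <- vapply(heart, function(cp) ch_vol(p, cp), numeric(1))
    sum(vch) + circulation$V0_sa + circulation$C_sa * p +
      circulation$V0_sv + circulation$C_sv * p +
      circulation$V0_pa + circulation$C_pa * p +
      circulation$V0_pv + circulation$C_pv * p
  }
  p_star <- stats::uniroot(function(p) total(p) - circulation$V_tot,
                           c(1e-9, 500), tol = 1e-12)$root
  vols <- c(vapply(heart, function(cp) ch_vol(p_star, cp), numeric(1)),
            sa = circulation$V0_sa + circulation$C_sa * p_star,
            sv = circulation$V0_sv + circulation$C_sv * p_star,
            pa = circulation$V0_pa + circulation$C_pa * p_star,
            pv = circulation$V0_pv + circulation$C_pv * p_star)
  list(pressure = p_star, volumes = vols)
}
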