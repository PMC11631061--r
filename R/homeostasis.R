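# Homeostatic pressure-flow regulation: between-beat adjustment of systemic
# resistance and circulating volume so cardiac output and mean arterial
# pressure sit at their set-points regardless of pacing settings.

#' Regulation set-points
#'
#' @param co_target systemic flow set-point (L/min).
#' @param map_target mean arterial pressure set-point (mmHg).
#' @param rel_tolerance relative convergence tolerance on both targets.
#' @param consecutive_beats_required beats that must sit inside tolerance
#'   in a row before convergence is declared.
#' @param max_beats hard cap on regulated beats.
#' @return a `regulation_targets` list.
#' @export
regulation_targets <- function(co_target = 5.0, map_target = 92,
                               rel_tolerance = 0.005,
                               consecutive_beats_required = 3,
                               max_beats = 500) {
  stopifnot(co_target > 0, map_target > 0,
            rel_tolerance > 0, rel_tolerance < 0.05)
  structure(list(co_target = co_target, map_target = map_target,
                 rel_tolerance = rel_tolerance,
                 consecutive_beats_required = consecutive_beats_required,
                 max_beats = max_beats),
            class = "regulation_targets")
}

#' One regulation update
#'
#' Multiplicative between-beat update of the regulated parameters:
#' \deqn{R_{sys} \leftarrow R_{sys}\left(\frac{MAP^*/CO^*}{MAP/CO}\right)^{g_R}, \quad
#'       V_{tot} \leftarrow V_{tot}\left(\frac{MAP^*}{MAP}\right)^{g_V}}
#' The measured pressure-to-flow ratio MAP/CO is (up to units) the effective
#' systemic resistance, so the resistance update divides by its relative
#' deviation from the target ratio; this is contractive, whereas multiplying
#' by the deviation amplifies it. The volume gain is smaller than the
#' resistance gain because mean arterial pressure is several times more
#' log-sensitive to circulating volume (only the stressed fraction of the
#' volume generates pressure). Both updates are exactly the identity when
#' the measured values equal the set-points.
#'
#' @param R_sys,V_tot current regulated parameters.
#' @param co,map measured beat-averaged systemic flow (L/min) and arterial
#'   pressure (mmHg).
#' @param targets a [regulation_targets()].
#' @param gain_r resistance update gain (default 0.3).
#' @param gain_v volume update gain (default 0.08).
#' @return list with updated `R_sys` and `V_tot`.
#' @export
regulation_update <- function(R_sys, V_tot, co, map, targets,
                              gain_r = 0.3, gain_v = 0.08) {
  stopifnot(co > 0, map > 0)
  list(R_sys = R_sys * ((targets$map_target / targets$co_target) /
                          (map / co))^gain_r,
       V_tot = V_tot * (targets$map_target / map)^gain_v)
}

#' Run pressure-flow regulation to convergence
#'
#' Simulates the model beat by beat; after each beat the systemic flow and
#' mean arterial pressure are measured over that beat and the regulated
#' parameters (systemic resistance, total blood volume) are updated via
#' [regulation_update()]. Volume changes are applied to the systemic venous
#' compartment. Convergence requires both measurements within
#' `rel_tolerance` of the set-points for `consecutive_beats_required`
#' consecutive beats.
#'
#' @param phenotype a [hfpef_phenotype()].
#' @param circulation a [circulation_params()].
#' @param timing an [activation_timing()]; defaults to the phenotype's.
#' @param targets a [regulation_targets()].
#' @param state warm-start state vector (`NULL` builds one).
#' @param gain_r,gain_v update gains (see [regulation_update()]).
#' @param beats_per_update beats simulated between parameter updates; the
#'   measurement uses the last of them.
#' @param dt integration step (s).
#' @return list with adjusted `circulation`, final `state`, `converged`
#'   flag, and `log` (data.frame: beat, co, map, R_sys, V_tot). If the
#'   regulation diverges an error carries the last good parameters.
#' @export
regulate <- function(phenotype, circulation, timing = phenotype$timing,
                     targets = regulation_targets(), state = NULL,
                     gain_r = 0.3, gain_v = 0.08, beats_per_update = 3,
                     dt = 1e-4) {
  heart <- apply_phenotype(phenotype)
  if (is.null(state)) state <- initial_state(circulation)
  state <- as.numeric(state)
  log <- vector("list", targets$max_beats)
  consec <- 0L
  converged <- FALSE
  beat <- 0L
  while (beat < targets$max_beats) {
    prm <- build_prm(heart, circulation, timing)
    res <- tryCatch(
      simulate_beats_cpp(state, prm, as.integer(beats_per_update), dt,
                         1e-3, 1L),
      error = function(e)
        stop("regulation diverged: ", conditionMessage(e),
             " (last good R_sys=", signif(circulation$R_sys, 6),
             ", V_tot=", signif(circulation$V_tot, 6), ")",
             call. = FALSE))
    beat <- beat + beats_per_update
    traj <- res$traj
    np <- nrow(traj) - 1L
    co <- mean(traj[seq_len(np), 19]) * 60 / 1000   # q_av, mL/s -> L/min
    map <- mean(traj[seq_len(np), 14])              # p_sa
    if (!is.finite(map) || map <= 0)
      stop("regulation diverged: non-positive arterial pressure",
           call. = FALSE)
    log[[beat / beats_per_update]] <-
      data.frame(beat = beat, co = co, map = map,
                 R_sys = circulation$R_sys, V_tot = circulation$V_tot)
    ok <- abs(co - targets$co_target) / targets$co_target <
      targets$rel_tolerance &&
      abs(map - targets$map_target) / targets$map_target <
      targets$rel_tolerance
    consec <- if (ok) consec + 1L else 0L
    state <- as.numeric(res$state)
    if (consec >= targets$consecutive_beats_required) {
      converged <- TRUE
      break
    }
    upd <- regulation_update(circulation$R_sys, circulation$V_tot,
                             co, map, targets, gain_r, gain_v)
    dv <- upd$V_tot - circulation$V_tot
    circulation$R_sys <- upd$R_sys
    circulation$V_tot <- upd$V_tot
    state[6] <- state[6] + dv  # systemic venous reservoir
    if (state[6] <= 0)
      stop("regulation diverged: systemic venous volume exhausted",
           call. = FALSE)
  }
  list(circulation = circulation, state = state, converged = converged,
       log = do.call(rbind, log[!vapply(log, is.null, logical(1))]))
}

#' Regulated steady-state simulation
#'
#' Convenience wrapper: run [regulate()] to convergence, then
#' [simulate_model()] to the periodic steady state, returning the final
#' beat's metrics together with the adjusted circulation.
#'
#' @inheritParams regulate
#' @param ... passed to [simulate_model()].
#' @return list: `metrics`, `trajectory`, `circulation`, `state`,
#'   `regulation_converged`, `steady_converged`, `n_beats` (total simulated).
#' @export
steady_regulated <- function(phenotype, circulation,
                             timing = phenotype$timing,
                             targets = regulation_targets(),
                             state = NULL, ...) {
  reg <- regulate(phenotype, circulation, timing, targets, state)
  sim <- simulate_model(phenotype, reg$circulation, timing,
                        state = reg$state, ...)
  list(metrics = sim$metrics, trajectory = sim$trajectory,
       circulation = reg$circulation, state = sim$state,
       regulation_converged = reg$converged,
       steady_converged = sim$converged,
       n_beats = max(reg$log$beat) + sim$n_beats,
       regulation_log = reg$log)
}
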