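#' Chamber parameters
#'
#' Parameters of a single heart chamber under the activation-weighted
#' linear-active / exponential-passive pressure-volume law
#' \deqn{p(V, a) = a\,c\,E_{act}(V - V_0) +
#'   P_{ref}\left(e^{k(V/V_0 - 1)} - 1\right),}
#' where \eqn{a \in [0,1]} is the activation level over the cardiac cycle.
#'
#' @param V0 unstressed volume (mL), > 0.
#' @param E_act active elastance (mmHg/mL), >= 0.
#' @param c contractility scale (dimensionless, 1 = normal), in \[0, 1.5\].
#' @param P_ref passive reference pressure (mmHg), > 0.
#' @param k passive stiffness exponent (dimensionless), > 0.
#' @param t_on activation onset within the cycle (ms).
#' @param d_act activation duration (ms), > 0; rise-to-peak phase length at
#'   the reference cycle length (scaled with sqrt of cycle length at run
#'   time, mimicking rate-dependent shortening of systole).
#' @param tau relaxation time constant (ms), > 0.
#' @return a `chamber_params` list.
#' @export
chamber_params <- function(V0, E_act, c = 1.0, P_ref, k,
                           t_on = 0, d_act, tau) {
  stopifnot(is.numeric(V0), V0 > 0, is.numeric(E_act), E_act >= 0,
            c >= 0, c <= 1.5, P_ref > 0, k > 0, d_act > 0, tau > 0)
  structure(list(V0 = V0, E_act = E_act, c = c, P_ref = P_ref, k = k,
                 t_on = t_on, d_act = d_act, tau = tau),
            class = "chamber_params")
}

#' Pacing/activation timing
#'
#' @param heart_rate beats per minute, in \[30, 250\].
#' @param pr_interval atrial-to-ventricular activation delay (ms), in
#'   \[0, 400\]. Both onsets wrap modulo the cycle length, so a PR interval
#'   longer than diastole is legal (atrial systole then lands in the previous
#'   beat's early diastole).
#' @param mode `"intrinsic"` (nodal conduction, PR as supplied) or
#'   `"av_sequential"` (both chambers paced with the programmed delay). The
#'   haemodynamic model treats both identically: the delay is imposed.
#' @return an `activation_timing` list with `cycle_length` (ms) filled in.
#' @export
activation_timing <- function(heart_rate, pr_interval = 153,
                              mode = c("intrinsic", "av_sequential")) {
  mode <- match.arg(mode)
  stopifnot(heart_rate >= 30, heart_rate <= 250,
            pr_interval >= 0, pr_interval <= 400)
  structure(list(heart_rate = heart_rate,
                 cycle_length = 60000 / heart_rate,
                 pr_interval = pr_interval, mode = mode),
            class = "activation_timing")
}

#' Circulation (vascular + valve) parameters
#'
#' Windkessel compartments for systemic and pulmonary arteries and veins,
#' linear connecting resistances, diode valves (ideal, no regurgitant leak)
#' and an optional mitral inertance that separates the E and A filling waves.
#'
#' @param C_sa,C_sv,C_pa,C_pv compliances (mL/mmHg).
#' @param V0_sa,V0_sv,V0_pa,V0_pv unstressed volumes (mL).
#' @param R_sys systemic peripheral resistance (mmHg.s/mL); adjusted by the
#'   regulation module.
#' @param R_pul pulmonary peripheral resistance (mmHg.s/mL).
#' @param R_sv_ra,R_pv_la venous-return resistances into the atria
#'   (bidirectional, so retrograde pressure waves such as cannon A-waves
#'   transmit into the veins).
#' @param R_mv,R_av,R_tv,R_pv open-valve resistances (mmHg.s/mL).
#' @param L_mv mitral inertance (mmHg.s^2/mL); 0 disables it.
#' @param V_tot total blood volume (mL); adjusted by the regulation module.
#' @param pericardium list with `enabled`, `P_ref` (mmHg), `k`, `V0` (mL):
#'   shared pericardial pressure `P_ref * (V_heart/V0)^k` on total heart
#'   volume, added to all four chambers.
#' @return a `circulation_params` list.
#' @export
circulation_params <- function(C_sa = 1.5, V0_sa = 600,
                               C_sv = 60, V0_sv = 2400,
                               C_pa = 5, V0_pa = 100,
                               C_pv = 12, V0_pv = 300,
                               R_sys = 1.05, R_pul = 0.06,
                               R_sv_ra = 0.03, R_pv_la = 0.015,
                               R_mv = 0.004, L_mv = 3e-4,
                               R_av = 0.005, R_tv = 0.004, R_pv = 0.005,
                               V_tot = 4600,
                               pericardium = list(enabled = TRUE,
                                                  P_ref = 1.0, k = 8,
                                                  V0 = 520)) {
  stopifnot(C_sa > 0, C_sv > 0, C_pa > 0, C_pv > 0,
            R_sys > 0, R_pul > 0, R_sv_ra > 0, R_pv_la > 0,
            R_mv > 0, R_av > 0, R_tv > 0, R_pv > 0, L_mv >= 0,
            V_tot > V0_sa + V0_sv + V0_pa + V0_pv)
  structure(list(C_sa = C_sa, V0_sa = V0_sa, C_sv = C_sv, V0_sv = V0_sv,
                 C_pa = C_pa, V0_pa = V0_pa, C_pv = C_pv, V0_pv = V0_pv,
                 R_sys = R_sys, R_pul = R_pul,
                 R_sv_ra = R_sv_ra, R_pv_la = R_pv_la,
                 R_mv = R_mv, L_mv = L_mv, R_av = R_av, R_tv = R_tv,
                 R_pv = R_pv, V_tot = V_tot, pericardium = pericardium),
            class = "circulation_params")
}

#' Normal four-chamber heart
#'
#' Reference chamber parameters for a resting adult heart at a cycle length
#' of 1000 ms. Activation durations are rescaled with sqrt(cycle length) at
#' simulation time.
#'
#' @return named list of [chamber_params()] for `LA`, `LV`, `RA`, `RV`.
#' @export
normal_heart <- function() {
  list(
    LA = chamber_params(V0 = 45, E_act = 0.80, c = 1, P_ref = 0.80, k = 2.5,
                        t_on = 0, d_act = 100, tau = 60),
    LV = chamber_params(V0 = 25, E_act = 4.0, c = 1, P_ref = 0.06, k = 1.0,
                        t_on = 160, d_act = 300, tau = 45),
    RA = chamber_params(V0 = 45, E_act = 0.50, c = 1, P_ref = 0.50, k = 2.0,
                        t_on = 0, d_act = 100, tau = 60),
    RV = chamber_params(V0 = 25, E_act = 1.3, c = 1, P_ref = 0.045, k = 1.0,
                        t_on = 160, d_act = 300, tau = 45)
  )
}

#' HFpEF phenotype configuration
#'
#' Multiplicative scalers applied to the normal heart to produce a virtual
#' patient with heart failure with preserved ejection fraction: slowed LV
#' active relaxation, increased LV passive stiffness and wall mass, and
#' (optionally) atrial contractile dysfunction.
#'
#' The default scaler values are the result of the package's baseline
#' calibration (see [calibrate_phenotype()]): at 54 bpm under pressure-flow
#' regulation they reproduce mLAP 15.0 mmHg, maximal LA volume 108 mL and
#' E/A 1.1.
#'
#' @param lv_passive_stiffness_scale multiplier on LV `P_ref` (passive
#'   stiffness), > 0.
#' @param lv_relaxation_tau_scale multiplier on LV `tau` (active relaxation
#'   time), > 0.
#' @param lv_mass_scale joint multiplier on LV `E_act` and `P_ref` (wall
#'   mass / hypertrophy), > 0.
#' @param atrial_contractility_fraction active atrial myofiber contractile
#'   function relative to normal, in (0, 1\]; 0.5 models atrial myopathy.
#' @param la_v0 LA unstressed volume (mL); a calibration lever for LA size.
#' @param pericardial_constraint_enabled logical.
#' @param timing baseline [activation_timing()].
#' @return a `phenotype_config` list.
#' @export
hfpef_phenotype <- function(lv_passive_stiffness_scale = 3.2269,
                            lv_relaxation_tau_scale = 1.9468,
                            lv_mass_scale = 1.0762,
                            atrial_contractility_fraction = 1.0,
                            la_v0 = 47.498,
                            pericardial_constraint_enabled = TRUE,
                            timing = activation_timing(54, 153)) {
  stopifnot(lv_passive_stiffness_scale > 0, lv_relaxation_tau_scale > 0,
            lv_mass_scale > 0,
            atrial_contractility_fraction > 0,
            atrial_contractility_fraction <= 1)
  structure(list(lv_passive_stiffness_scale = lv_passive_stiffness_scale,
                 lv_relaxation_tau_scale = lv_relaxation_tau_scale,
                 lv_mass_scale = lv_mass_scale,
                 atrial_contractility_fraction = atrial_contractility_fraction,
                 la_v0 = la_v0,
                 pericardial_constraint_enabled = pericardial_constraint_enabled,
                 timing = timing),
            class = "phenotype_config")
}

#' Apply a phenotype to the normal heart
#'
#' @param phenotype a [hfpef_phenotype()] configuration.
#' @return named list of [chamber_params()] with the scalers applied.
#' @export
apply_phenotype <- function(phenotype) {
  h <- normal_heart()
  h$LV$P_ref <- h$LV$P_ref * phenotype$lv_passive_stiffness_scale *
    phenotype$lv_mass_scale
  h$LV$E_act <- h$LV$E_act * phenotype$lv_mass_scale
  h$LV$tau <- h$LV$tau * phenotype$lv_relaxation_tau_scale
  h$LA$c <- h$LA$c * phenotype$atrial_contractility_fraction
  h$LA$V0 <- phenotype$la_v0
  h
}
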