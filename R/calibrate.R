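# Baseline phenotype calibration against the virtual-patient targets.

#' Calibrate the HFpEF phenotype to its baseline targets
#'
#' Tunes the LV passive-stiffness scale, LV relaxation-time scale, LV
#' wall-mass scale and LA unstressed volume so that the regulated model at
#' the baseline pacing timing reproduces the target mean LA pressure,
#' maximal LA volume and E/A ratio. Cardiac output and arterial pressure
#' are held at their set-points by the regulation module inside every
#' objective evaluation, so they are not free residuals.
#'
#' The objective is the sum of squared relative errors over the three
#' targets, minimised by Nelder-Mead on log-transformed parameters (which
#' enforces positivity without explicit bounds).
#'
#' @param targets list with `mlap` (mmHg), `lav_max` (mL), `ea` (ratio).
#' @param start starting [hfpef_phenotype()].
#' @param circulation a [circulation_params()].
#' @param reg_targets a [regulation_targets()].
#' @param maxit Nelder-Mead iteration cap.
#' @return the calibrated `phenotype_config`, with attributes `fit`
#'   (optim result) and `metrics` (baseline metrics at the optimum).
#' @export
calibrate_phenotype <- function(targets = list(mlap = 15.0, lav_max = 108,
                                               ea = 1.1),
                                start = hfpef_phenotype(),
                                circulation = circulation_params(),
                                reg_targets = regulation_targets(),
                                maxit = 80) {
  make_ph <- function(par) {
    hfpef_phenotype(
      lv_passive_stiffness_scale = exp(par[1]),
      lv_relaxation_tau_scale = exp(par[2]),
      lv_mass_scale = exp(par[3]),
      atrial_contractility_fraction = start$atrial_contractility_fraction,
      la_v0 = exp(par[4]),
      pericardial_constraint_enabled = start$pericardial_constraint_enabled,
      timing = start$timing)
  }
  objective <- function(par) {
    ph <- make_ph(par)
    m <- tryCatch(
      steady_regulated(ph, circulation, targets = reg_targets)$metrics,
      error = function(e) NULL)
    if (is.null(m)) return(1e3)
    ea_err <- if (isTRUE(m$ea_fused) || is.na(m$ea_ratio)) 1
      else (m$ea_ratio - targets$ea) / targets$ea
    ((m$mlap - targets$mlap) / targets$mlap)^2 +
      ((m$lav_max - targets$lav_max) / targets$lav_max)^2 +
      ea_err^2
  }
  par0 <- log(c(start$lv_passive_stiffness_scale,
                start$lv_relaxation_tau_scale,
                start$lv_mass_scale,
                start$la_v0))
  fit <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6))
  ph <- make_ph(fit$par)
  final <- steady_regulated(ph, circulation, targets = reg_targets)
  attr(ph, "fit") <- fit
  attr(ph, "metrics") <- final$metrics
  ph
}
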