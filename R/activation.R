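#' Chamber activation waveform
#'
#' Activation level of a chamber as a function of time since its activation
#' onset: a smooth squared-sinusoid rise to a single maximum of 1 at
#' `d_act`, followed by exponential relaxation with time constant `tau`.
#' Zero at and before onset, continuous everywhere.
#'
#' @param t_since_onset time since activation onset (ms); may be a vector.
#' @param d_act activation duration (ms), > 0.
#' @param tau relaxation time constant (ms), > 0.
#' @return activation level(s) in \[0, 1\].
#' @examples
#' activation(0, 300, 60)            # 0 at onset
#' activation(300, 300, 60)          # peak = 1
#' activation(300 + 3 * 60, 300, 60) # exp(-3), < 5% of peak
#' @export
activation <- function(t_since_onset, d_act, tau) {
  if (!is.numeric(d_act) || !is.numeric(tau) || d_act <= 0 || tau <= 0)
    stop("'d_act' and 'tau' must be positive", call. = FALSE)
  if (any(!is.finite(t_since_onset)))
    stop("'t_since_onset' must be finite", call. = FALSE)
  ifelse(t_since_onset <= 0, 0,
         ifelse(t_since_onset <= d_act,
                sin(pi * t_since_onset / (2 * d_act))^2,
                exp(-(t_since_onset - d_act) / tau)))
}

#' Chamber pressure-volume law
#'
#' Instantaneous chamber pressure: activation-weighted linear active
#' elastance plus exponential passive stiffness,
#' \eqn{p = a c E_{act}(V - V_0) + P_{ref}(e^{k(V/V_0-1)} - 1)}.
#' Pericardial pressure, when modelled, is added by the simulator on top of
#' this chamber-intrinsic term.
#'
#' @param params a [chamber_params()].
#' @param V chamber volume (mL), >= 0; may be a vector.
#' @param a activation level in \[0, 1\].
#' @return pressure (mmHg).
#' @export
chamber_pressure <- function(params, V, a) {
  stopifnot(inherits(params, "chamber_params"))
  if (any(V < 0)) stop("chamber volume must be non-negative", call. = FALSE)
  stopifnot(all(a >= 0), all(a <= 1))
  a * params$c * params$E_act * (V - params$V0) +
    params$P_ref * (exp(pmin(params$k * (V / params$V0 - 1), 50)) - 1)
}

#' Valve flow law
#'
#' Ideal diode valve: forward flow driven by the pressure gradient when
#' open, zero flow and zero leak when closed. With inertance enabled the
#' flow is a state variable obeying
#' \eqn{L \dot q = \Delta p - R q} while open; the function then returns the
#' current flow and its time-derivative.
#'
#' @param p_upstream,p_downstream pressures (mmHg).
#' @param R open-valve resistance (mmHg.s/mL), > 0.
#' @param L inertance (mmHg.s^2/mL); 0 for a purely resistive valve.
#' @param q current flow state (mL/s); used only when `L > 0`.
#' @return for `L == 0`, the flow (mL/s); for `L > 0`, a list with `q`
#'   (mL/s) and `dq_dt` (mL/s^2).
#' @export
valve_flow <- function(p_upstream, p_downstream, R, L = 0, q = 0) {
  stopifnot(is.finite(p_upstream), is.finite(p_downstream), R > 0, L >= 0)
  dp <- p_upstream - p_downstream
  if (L == 0) {
    return(if (dp > 0) dp / R else 0)
  }
  if (q <= 0 && dp <= 0) return(list(q = 0, dq_dt = 0))
  q <- max(q, 0)
  list(q = q, dq_dt = (dp - R * q) / L)
}
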