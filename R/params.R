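#' Parameters of the single-gate Hodgkin-Huxley activation model
#'
#' Describes one homomeric channel population with a linear (ohmic)
#' single-channel characteristic and a single Boltzmann activation gate:
#' \deqn{I(V) = \Gamma (V - E_{rev}) \left[1 + e^{-(V - V_n)/k_n}\right]^{-1}}
#'
#' @param gamma total conductance Gamma (nS, >= 0)
#' @param e_rev reversal potential (mV)
#' @param v_n half-maximal activation voltage (mV)
#' @param k_n slope factor (mV, > 0)
#' @return an object of class `activation_params`
#' @examples
#' activation_params(gamma = 1, e_rev = 2, v_n = -22, k_n = 12)
#' @export
activation_params <- function(gamma, e_rev, v_n, k_n) {
  stopifnot(is.numeric(gamma), is.numeric(e_rev), is.numeric(v_n),
            is.numeric(k_n), length(gamma) == 1L, length(e_rev) == 1L,
            length(v_n) == 1L, length(k_n) == 1L)
  if (!is.finite(k_n) || k_n <= 0)
    stop("slope factor 'k_n' must be positive (mV)", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0)
    stop("total conductance 'gamma' must be non-negative (nS)", call. = FALSE)
  structure(list(gamma = gamma, e_rev = e_rev, v_n = v_n, k_n = k_n),
            class = "activation_params")
}

#' Heteromer-mixture extension parameters for coexpression data
#'
#' Extends [activation_params()] to wild-type/mutant coexpression under a
#' binomial assembly assumption: each of the four subunit positions of the
#' tetramer is mutant with probability `p_s`, the all-mutant channel has
#' the hypothetical half-activation voltage `v_ns` (it conducts no
#' current), and intermediate compositions interpolate linearly.
#'
#' @param v_ns hypothetical all-mutant half-activation voltage (mV)
#' @param p_s per-subunit mutant incorporation probability, in \[0, 1\]
#' @param k_ns mutant slope factor (mV, > 0). `NULL` (the default) ties
#'   it to the wild-type `k_n`, the standard simplification.
#' @return an object of class `mixture_params`
#' @export
mixture_params <- function(v_ns, p_s, k_ns = NULL) {
  stopifnot(is.numeric(v_ns), length(v_ns) == 1L,
            is.numeric(p_s), length(p_s) == 1L)
  if (!is.finite(p_s) || p_s < 0 || p_s > 1)
    stop("'p_s' must lie in [0, 1]", call. = FALSE)
  if (!is.null(k_ns)) {
    stopifnot(is.numeric(k_ns), length(k_ns) == 1L)
    if (!is.finite(k_ns) || k_ns <= 0)
      stop("'k_ns' must be positive (mV)", call. = FALSE)
  }
  structure(list(v_ns = v_ns, p_s = p_s, k_ns = k_ns),
            class = "mixture_params")
}

#' Parameters of the tail-current activation curve
#'
#' Boltzmann description of normalized tail currents measured at a fixed
#' repolarization voltage after variable depolarizations (used for
#' strongly inactivating channels such as Kv11.1):
#' \deqn{I_{tail}(V)/I_{tail}(30\,mV) = r_{-\infty} +
#'   (r_\infty - r_{-\infty}) / (1 + e^{-(V - V_n)/k_n})}
#'
#' @param r_neg_inf residual ratio at hyperpolarized voltages
#' @param r_inf maximal ratio
#' @param v_n half-activation voltage (mV)
#' @param k_n slope factor (mV, > 0)
#' @return an object of class `tail_activation_params`
#' @export
tail_activation_params <- function(r_neg_inf, r_inf, v_n, k_n) {
  stopifnot(is.numeric(r_neg_inf), is.numeric(r_inf), is.numeric(v_n),
            is.numeric(k_n))
  if (!is.finite(k_n) || k_n <= 0)
    stop("'k_n' must be positive (mV)", call. = FALSE)
  if (r_inf <= r_neg_inf)
    stop("'r_inf' must exceed 'r_neg_inf'", call. = FALSE)
  structure(list(r_neg_inf = r_neg_inf, r_inf = r_inf, v_n = v_n,
                 k_n = k_n),
            class = "tail_activation_params")
}

#' Parameters of the binomial multi-exponential deactivation model
#'
#' Tail currents of wild-type/mutant heteromer populations deactivate as
#' a weighted sum of exponentials: homomeric wild-type channels (4:0)
#' decay with `tau_fast`; 1:3 wild-type:mutant channels with `tau_slow`;
#' 2:2 with `tau_slow / f`; 3:1 with `tau_slow / f^2`. The all-mutant
#' composition carries no current. Component amplitudes follow the
#' binomial weights of the composition probabilities at `p_s`.
#'
#' @param tau_fast fast (homomeric wild-type) time constant (s, > 0)
#' @param tau_slow slow (1:3 composition) time constant (s, > 0)
#' @param f geometric scaling factor between compositions (> 0)
#' @param p_s probability of a mutant subunit among open channels at the
#'   end of the test pulse; scalar or one value per tail trace, each in
#'   \[0, 1\]
#' @param amplitude initial tail amplitude(s), pA; one per trace
#' @return an object of class `deactivation_params`
#' @export
deactivation_params <- function(tau_fast, tau_slow, f, p_s = 0.5,
                                amplitude = 1) {
  stopifnot(is.numeric(tau_fast), is.numeric(tau_slow), is.numeric(f))
  if (!is.finite(tau_fast) || tau_fast <= 0)
    stop("'tau_fast' must be positive (s)", call. = FALSE)
  if (!is.finite(tau_slow) || tau_slow <= 0)
    stop("'tau_slow' must be positive (s)", call. = FALSE)
  if (!is.finite(f) || f <= 0)
    stop("scaling factor 'f' must be positive", call. = FALSE)
  if (any(!is.finite(p_s)) || any(p_s < 0) || any(p_s > 1))
    stop("all 'p_s' values must lie in [0, 1]", call. = FALSE)
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow, f = f,
                 p_s = p_s, amplitude = amplitude),
            class = "deactivation_params")
}

#' Ratiometric voltage-sensor calibration standard
#'
#' Constants of the sigmoid calibration curve relating membrane voltage
#' to the green/red fluorescence ratio R = F_green/F_red:
#' \deqn{R(V) = R_{max} + \Delta R / (1 + e^{-(V - V_{half})/k_s})}
#' For a sensor whose ratio rises upon hyperpolarization, `delta_r` is
#' negative and R spans `(r_max + delta_r, r_max)`.
#'
#' @param r_max maximal ratio (hyperpolarized limit)
#' @param delta_r ratio span (negative for this sensor class)
#' @param v_half half-response voltage (mV)
#' @param k_s slope factor (mV, > 0)
#' @return an object of class `calibration_standard`
#' @seealso [restus_calibration()] for the published mK2-rEstus constants
#' @export
calibration_standard <- function(r_max, delta_r, v_half, k_s) {
  stopifnot(is.numeric(r_max), is.numeric(delta_r), is.numeric(v_half),
            is.numeric(k_s))
  if (!is.finite(k_s) || k_s <= 0)
    stop("'k_s' must be positive (mV)", call. = FALSE)
  if (!is.finite(delta_r) || delta_r >= 0)
    stop("'delta_r' must be negative: hyperpolarization increases R",
         call. = FALSE)
  structure(list(r_max = r_max, delta_r = delta_r, v_half = v_half,
                 k_s = k_s),
            class = "calibration_standard")
}

#' Published calibration constants of the mKate2-rEstus voltage sensor
#'
#' Convenience constructor for the calibration standard determined under
#' whole-cell voltage clamp for the mKate2-rEstus indicator:
#' R_max = 2.86, Delta R = -2.39, V_half = -31.8 mV, k_s = 25.3 mV.
#'
#' @return a [calibration_standard()]
#' @export
restus_calibration <- function() {
  calibration_standard(r_max = 2.86, delta_r = -2.39, v_half = -31.8,
                       k_s = 25.3)
}

#' Nernst equilibrium potential
#'
#' @param c_out extracellular concentration (mM)
#' @param c_in intracellular concentration (mM)
#' @param temperature_c temperature in degrees Celsius (default 22)
#' @param z ion valence (default +1 for K+)
#' @return equilibrium potential in mV
#' @examples
#' # K+ reversal with 140 mM external / 130 mM internal K+
#' nernst_potential(140, 130)
#' @export
nernst_potential <- function(c_out, c_in, temperature_c = 22, z = 1) {
  stopifnot(c_out > 0, c_in > 0, z != 0)
  R <- 8.314462618   # J mol-1 K-1
  F <- 96485.33212   # C mol-1
  t_k <- temperature_c + 273.15
  1000 * R * t_k / (z * F) * log(c_out / c_in)
}

#' @export
print.activation_params <- function(x, ...) {
  cat(sprintf(
    "Activation parameters: Gamma = %g nS, E_rev = %g mV, V_n = %g mV, k_n = %g mV\n",
    x$gamma, x$e_rev, x$v_n, x$k_n))
  invisible(x)
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Mixture parameters: V_ns = %g mV, p_s = %g, k_ns = %s\n",
              x$v_ns, x$p_s,
              if (is.null(x$k_ns)) "tied to k_n" else sprintf("%g mV", x$k_ns)))
  invisible(x)
}

#' @export
print.deactivation_params <- function(x, ...) {
  cat(sprintf(
    "Deactivation parameters: tau_fast = %g s, tau_slow = %g s, f = %g\n",
    x$tau_fast, x$tau_slow, x$f))
  cat("  p_s:", paste(signif(x$p_s, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.calibration_standard <- function(x, ...) {
  cat(sprintf(
    "Calibration standard: R_max = %g, Delta R = %g, V_half = %g mV, k_s = %g mV\n",
    x$r_max, x$delta_r, x$v_half, x$k_s))
  invisible(x)
}
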