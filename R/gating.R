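# Steady-state activation models: single Boltzmann gate and the binomial
# heteromer mixture. Units are fixed package-wide: mV, pA, nS, s. The
# identity 1 nS * 1 mV = 1 pA is what makes Gamma*(V - E_rev) a current;
# this is asserted once in the test suite, nowhere re-derived.

#' Boltzmann open fraction of a single activation gate
#'
#' @param v membrane voltage (mV); vectorized
#' @param v_half half-maximal activation voltage (mV)
#' @param k slope factor (mV, > 0)
#' @return open probability in (0, 1), strictly increasing in `v`
#' @examples
#' boltzmann_open_fraction(0, v_half = -20, k = 10)  # 1/(1 + exp(-2))
#' @export
boltzmann_open_fraction <- function(v, v_half, k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0))
    stop("slope factor 'k' must be positive (mV)", call. = FALSE)
  1 / (1 + exp(-(v - v_half) / k))
}

#' Steady-state current of a homomeric channel population
#'
#' Evaluates the single-gate activation model
#' \eqn{I(V) = \Gamma (V - E_{rev}) / (1 + e^{-(V - V_n)/k_n})}.
#' The current is exactly zero at the reversal potential and changes sign
#' there (the driving-force factor is the only sign-carrying term).
#'
#' @param params an [activation_params()] object
#' @param v voltage (mV); vectorized
#' @return current in pA
#' @export
hh_current <- function(params, v) {
  stopifnot(inherits(params, "activation_params"))
  params$gamma * (v - params$e_rev) *
    boltzmann_open_fraction(v, params$v_n, params$k_n)
}

#' Binomial stoichiometry weights of tetramer compositions
#'
#' Probabilities of the five wild-type:mutant compositions 4:0, 3:1,
#' 2:2, 1:3 and 0:4 when each of the four subunit positions is occupied
#' by a mutant independently with probability `p_s` (binomial, n = 4).
#' At `p_s = 0.5` the weights are 1/16, 4/16, 6/16, 4/16, 1/16.
#'
#' @param p_s per-subunit mutant probability in \[0, 1\]
#' @return named numeric vector of five probabilities summing to 1;
#'   names give the wild-type:mutant ratio
#' @export
stoichiometry_weights <- function(p_s) {
  stopifnot(is.numeric(p_s), length(p_s) == 1L)
  if (!is.finite(p_s) || p_s < 0 || p_s > 1)
    stop("'p_s' must lie in [0, 1]", call. = FALSE)
  q <- 1 - p_s
  w <- c(q^4, 4 * p_s * q^3, 6 * p_s^2 * q^2, 4 * p_s^3 * q, p_s^4)
  names(w) <- c("4:0", "3:1", "2:2", "1:3", "0:4")
  w
}

#' Half-activation voltage of a given subunit composition
#'
#' Linear interpolation between the wild-type `v_n` (no mutant subunits)
#' and the hypothetical all-mutant `v_ns`:
#' \eqn{V_n(m) = V_n + (m/4)(V_{ns} - V_n)} for m mutant subunits.
#'
#' @param m number of mutant subunits, integer in 0..4; vectorized
#' @param v_n wild-type half-activation voltage (mV)
#' @param v_ns all-mutant half-activation voltage (mV)
#' @return half-activation voltage (mV)
#' @export
vn_of_composition <- function(m, v_n, v_ns) {
  if (any(!is.finite(m)) || any(m != round(m)) || any(m < 0) || any(m > 4))
    stop("'m' must be an integer number of mutant subunits in 0..4",
         call. = FALSE)
  v_n + (m / 4) * (v_ns - v_n)
}

# slope factor of a composition; tied mode (k_ns NULL) returns k_n
k_of_composition <- function(m, k_n, k_ns = NULL) {
  if (is.null(k_ns)) rep_len(k_n, length(m))
  else k_n + (m / 4) * (k_ns - k_n)
}

#' Steady-state current of a binomial wild-type/mutant channel mixture
#'
#' Current-voltage relationship of the heteromer population arising from
#' coexpression: compositions with m = 0..3 mutant subunits contribute a
#' Boltzmann gate centered at [vn_of_composition()], weighted by the
#' binomial composition probability at `p_s`; the homomeric mutant
#' channel (m = 4) is non-functional and contributes no current. With
#' `p_s = 0` this reduces exactly to [hh_current()]; with `p_s = 1` the
#' current is zero at all voltages.
#'
#' @param act wild-type [activation_params()]
#' @param mix [mixture_params()]
#' @param v voltage (mV); vectorized
#' @return current in pA
#' @export
mixture_iv <- function(act, mix, v) {
  stopifnot(inherits(act, "activation_params"),
            inherits(mix, "mixture_params"))
  w <- unname(stoichiometry_weights(mix$p_s))
  m <- 0:3
  vn_m <- vn_of_composition(m, act$v_n, mix$v_ns)
  k_m <- k_of_composition(m, act$k_n, mix$k_ns)
  p_open <- Reduce(`+`, lapply(seq_along(m), function(i)
    w[i] * boltzmann_open_fraction(v, vn_m[i], k_m[i])))
  act$gamma * (v - act$e_rev) * p_open
}

#' Tail-current activation curve
#'
#' Evaluates the normalized tail-current voltage dependence
#' \eqn{r(V) = r_{-\infty} + (r_\infty - r_{-\infty})/(1 + e^{-(V-V_n)/k_n})}.
#'
#' @param params a [tail_activation_params()] object
#' @param v depolarization voltage (mV); vectorized
#' @return dimensionless tail ratio
#' @export
tail_activation_ratio <- function(params, v) {
  stopifnot(inherits(params, "tail_activation_params"))
  params$r_neg_inf + (params$r_inf - params$r_neg_inf) *
    boltzmann_open_fraction(v, params$v_n, params$k_n)
}
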