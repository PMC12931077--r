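# Binomially weighted multi-exponential deactivation of heteromer tail
# currents, and its global fit across a voltage family. Composition
# weights follow the binomial assembly probabilities; the all-mutant
# (0:4) composition carries no current and its weight is deliberately
# NOT renormalized away - the per-trace amplitude absorbs the constant.

#' Deactivation time constant of a tetramer composition
#'
#' Wild-type homomers (m = 0 mutant subunits) close with `tau_fast`;
#' mutant-containing channels close with `tau_slow / f^2` (m = 1),
#' `tau_slow / f` (m = 2) and `tau_slow` (m = 3). The all-mutant
#' composition (m = 4) is non-functional and has no time constant.
#'
#' @param m number of mutant subunits, integer in 0..3; vectorized
#' @param params a [deactivation_params()]
#' @return time constant(s) in s
#' @export
composition_time_constant <- function(m, params) {
  stopifnot(inherits(params, "deactivation_params"))
  if (any(!is.finite(m)) || any(m != round(m)) || any(m < 0) || any(m > 3))
    stop("'m' must be in 0..3; the homomeric mutant (m = 4) conducts no ",
         "current and has no deactivation time constant", call. = FALSE)
  tau <- c(params$tau_fast, params$tau_slow / params$f^2,
           params$tau_slow / params$f, params$tau_slow)
  tau[m + 1L]
}

#' Binomial multi-exponential tail-current model
#'
#' Tail current at time `t` after repolarization:
#' \deqn{I(t) = A \sum_{m=0}^{3} w_m(p_s)\, e^{-t/\tau_m}}
#' with binomial composition weights \eqn{w_m} from
#' [stoichiometry_weights()] and time constants from
#' [composition_time_constant()]. The 0:4 term is absent, so
#' \eqn{I(0) = A (1 - p_s^4)}.
#'
#' @param t time since repolarization (s, >= 0); vectorized
#' @param params a [deactivation_params()]
#' @param p_s mutant-subunit probability for this trace (default: first
#'   element of `params$p_s`)
#' @param amplitude scale in pA (default: first element of
#'   `params$amplitude`)
#' @return current in pA
#' @export
tail_mixture_model <- function(t, params, p_s = params$p_s[1],
                               amplitude = params$amplitude[1]) {
  stopifnot(inherits(params, "deactivation_params"))
  if (any(t < 0))
    stop("tail time must be non-negative (t = 0 at the tail onset)",
         call. = FALSE)
  w <- unname(stoichiometry_weights(p_s)[1:4])
  tau <- composition_time_constant(0:3, params)
  amplitude * Reduce(`+`, lapply(1:4, function(i)
    w[i] * exp(-t / tau[i])))
}

# analytic area under the tail: A * sum_m w_m * tau_m
tail_mixture_area <- function(params, p_s = params$p_s[1],
                              amplitude = params$amplitude[1]) {
  w <- stoichiometry_weights(p_s)[1:4]
  amplitude * sum(w * composition_time_constant(0:3, params))
}

# initialization heuristics for the global fit (see methods vignette):
# tau_fast from the initial 10%-amplitude drop of the most depolarized
# trace, tau_slow from a log-linear fit of the final third, f = 3.
.init_deactivation <- function(tails) {
  t <- tails$time_s
  i_fast <- tails$currents[, which.max(tails$test_voltage_mV)]
  n10 <- which(i_fast <= 0.9 * i_fast[1])[1]
  if (is.na(n10)) n10 <- length(t)
  n10 <- max(3L, n10)
  pos <- i_fast[seq_len(n10)] > 0
  tau_fast <- 0.01
  if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(i_fast[seq_len(n10)][pos]) ~
                                  t[seq_len(n10)][pos]))[2]
    if (is.finite(sl) && sl < 0) tau_fast <- -0.1 / sl
  }
  i_slow <- tails$currents[, which.min(tails$test_voltage_mV)]
  last3 <- t >= t[length(t)] * 2 / 3
  pos <- last3 & i_slow > 0
  tau_slow <- max(t) / 2
  if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(i_slow[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) tau_slow <- -1 / sl
  }
  list(tau_fast = min(max(tau_fast, 1e-4), 1),
       tau_slow = min(max(tau_slow, 1e-2), 100), f = 3)
}

#' Globally fit the binomial deactivation model to a tail family
#'
#' Fits all tail traces of a voltage family jointly: one shared
#' `tau_fast`, `tau_slow` and `f`; one free positive amplitude per
#' trace; and `p_s` either shared or per test voltage (default), since
#' the fraction of mutant subunits among *open* channels at the pulse
#' end varies with depolarization. Fitting is in linear current space
#' with uniform weights. Bounds: tau_fast in \[1e-4, 1\] s, tau_slow in
#' \[0.01, 100\] s, f in \[1, 100\].
#'
#' @param tails a [tail_trace_set()] with >= 2 traces
#' @param mode `"per-voltage"` (default) or `"shared"` p_s
#' @param initial optional [deactivation_params()] start guess;
#'   heuristics are used when omitted
#' @param n_starts deterministic multi-start points (default 3; the
#'   heuristic initialization is usually close)
#' @return a `kvmix_fit`; parameters `tau_fast`, `tau_slow`, `f`,
#'   `p_s_<voltage>` (or `p_s`), `amp_<voltage>`; the corresponding
#'   [deactivation_params()] in `$deactivation_params`
#' @export
global_fit_tails <- function(tails, mode = c("per-voltage", "shared"),
                             initial = NULL, n_starts = 3) {
  stopifnot(inherits(tails, "tail_trace_set"))
  mode <- match.arg(mode)
  n_tr <- ncol(tails$currents)
  if (n_tr < 2L)
    stop("global fit requires at least two tail traces", call. = FALSE)
  t <- tails$time_s
  if (is.null(initial)) {
    ini <- .init_deactivation(tails)
  } else {
    ini <- list(tau_fast = initial$tau_fast, tau_slow = initial$tau_slow,
                f = initial$f)
  }
  if (max(t) < 3 * ini$tau_slow)
    warning("tail traces cover less than 3 x the slow time-constant ",
            "guess; confidence intervals will widen", call. = FALSE)
  vlab <- sprintf("%g", tails$test_voltage_mV)
  p_names <- if (mode == "shared") "p_s" else paste0("p_s_", vlab)
  a_names <- paste0("amp_", vlab)
  p0 <- if (!is.null(initial)) rep_len(initial$p_s, length(p_names))
        else rep(0.5, length(p_names))
  a0 <- pmax(tails$currents[1, ], 1e-6)
  start <- as.list(c(stats::setNames(c(ini$tau_fast, ini$tau_slow, ini$f),
                                     c("tau_fast", "tau_slow", "f")),
                     stats::setNames(p0, p_names),
                     stats::setNames(a0, a_names)))
  lower <- c(tau_fast = 1e-4, tau_slow = 1e-2, f = 1,
             stats::setNames(rep(0, length(p_names)), p_names),
             stats::setNames(rep(1e-9, n_tr), a_names))
  upper <- c(tau_fast = 1, tau_slow = 100, f = 100,
             stats::setNames(rep(1, length(p_names)), p_names),
             stats::setNames(rep(1e9, n_tr), a_names))
  if (length(t) * n_tr <= length(start))
    stop("fewer samples than free parameters", call. = FALSE)
  resid_fn <- function(p) {
    dp <- deactivation_params(p$tau_fast, p$tau_slow, p$f)
    res <- vapply(seq_len(n_tr), function(j) {
      ps_j <- if (mode == "shared") p$p_s else p[[p_names[j]]]
      tails$currents[, j] -
        tail_mixture_model(t, dp, p_s = ps_j, amplitude = p[[a_names[j]]])
    }, numeric(length(t)))
    as.numeric(res)
  }
  fit <- .ls_multistart(resid_fn, start, lower, upper, n_starts)
  res <- .make_fit_result(fit, names(start), c(), lower, upper,
                          length(t) * n_tr,
                          "Binomial deactivation (global)",
                          NULL)
  pars <- res$parameters
  res$deactivation_params <- deactivation_params(
    tau_fast = pars[["tau_fast"]], tau_slow = pars[["tau_slow"]],
    f = pars[["f"]],
    p_s = unname(pars[p_names]), amplitude = unname(pars[a_names]))
  res$mode <- mode
  res$test_voltage_mV <- tails$test_voltage_mV
  res
}
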