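# Bounded least-squares fitting with deterministic multi-start and
# linearized 95% confidence intervals. The mixture model's (v_ns, p_s)
# surface has shallow valleys, so every fit runs from five start points:
# the supplied guess plus four fixed +/-20% perturbations. Perturbations
# are deterministic (no RNG) so that fitting never consumes the caller's
# random stream.

.start_grid <- function(start, lower, upper, n_starts = 5, jitter = 0.2) {
  p <- length(start)
  pat <- list(rep(0, p), rep(jitter, p), rep(-jitter, p),
              jitter * (-1)^(seq_len(p)), jitter * (-1)^(1 + seq_len(p)))
  pat <- pat[seq_len(min(n_starts, length(pat)))]
  lapply(pat, function(off) {
    s <- ifelse(abs(start) > 1e-8, start * (1 + off), start + off)
    pmin(pmax(s, lower), upper)
  })
}

.at_bounds <- function(par, lower, upper, tol = 1e-6) {
  (par - lower) < tol * (1 + abs(lower)) |
    (upper - par) < tol * (1 + abs(upper))
}

# run nls.lm from multiple starts, keep the best-deviance solution
.ls_multistart <- function(resid_fn, start, lower, upper, n_starts = 5) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-10,
                                     gtol = 1e-10, maxiter = 500)
  best <- NULL
  for (s in .start_grid(unlist(start), lower, upper, n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.list(s), lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("least-squares optimization failed from every start point",
         call. = FALSE)
  best
}

# assemble a fit_result from an nls.lm solution
.make_fit_result <- function(fit, free, fixed, lower, upper, n_obs,
                             model, model_fn) {
  p <- length(fit$par)
  rdf <- n_obs - p
  se <- rep(NA_real_, p)
  cov_ok <- FALSE
  if (rdf > 0) {
    ch <- tryCatch(chol(fit$hessian), error = function(e) NULL)
    if (!is.null(ch)) {
      se <- sqrt(diag(chol2inv(ch)) * fit$deviance / rdf)
      cov_ok <- TRUE
    } else {
      # singular J'J (unidentifiable directions): eigen pseudo-inverse;
      # the affected parameters surface through huge intervals below
      ev <- eigen(fit$hessian, symmetric = TRUE)
      pos <- ev$values > max(ev$values) * 1e-12
      if (any(pos)) {
        pinv_diag <- as.numeric((ev$vectors[, pos, drop = FALSE]^2) %*%
                                  (1 / ev$values[pos]))
        se <- sqrt(pmax(pinv_diag, 0) * fit$deviance / rdf)
        # parameters with weight in the null space carry no information
        null_comp <- rowSums(ev$vectors[, !pos, drop = FALSE]^2)
        se[null_comp > 1e-8 | !is.finite(se)] <- Inf
        cov_ok <- TRUE
      }
    }
  }
  ci95 <- if (rdf > 0) stats::qt(0.975, rdf) * se else rep(Inf, p)
  names(ci95) <- names(fit$par)
  span <- upper - lower
  unident <- names(fit$par)[!is.finite(ci95) | ci95 >= span / 2]
  if (!cov_ok) unident <- names(fit$par)
  converged <- fit$info %in% 1:3 &&
    !any(.at_bounds(unlist(fit$par), lower, upper))
  structure(list(
    parameters = c(unlist(fit$par), fixed),
    free = names(fit$par), fixed = names(fixed),
    ci95 = ci95, rss = fit$deviance, n_obs = n_obs,
    converged = converged, info = fit$info,
    message = fit$message, unidentifiable = unident,
    model = model, model_fn = model_fn),
    class = "kvmix_fit")
}

#' @export
print.kvmix_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): RSS = %.4g on %d points\n", x$model,
              if (x$converged) "converged" else
                "NOT converged - parameters unusable",
              x$rss, x$n_obs))
  for (nm in x$free)
    cat(sprintf("  %-10s %10.4g  +/- %.4g (95%% CI)%s\n", nm,
                x$parameters[[nm]], x$ci95[[nm]],
                if (nm %in% x$unidentifiable) "  [unidentifiable]" else ""))
  if (length(x$fixed))
    cat("  fixed:", paste(sprintf("%s = %.4g", x$fixed,
                                  x$parameters[x$fixed]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Fit the single-gate activation model to a wild-type IV curve
#'
#' Least-squares fit of the Hodgkin-Huxley/Boltzmann steady-state model
#' to a (normalized or absolute) IV relationship. For normalized data
#' the conductance Gamma is not identifiable and is replaced by a free
#' dimensionless scale, reported as parameter `amp`; for absolute data
#' `amp` is Gamma in nS. The reversal potential is fixed by default (it
#' is known from the ionic conditions); pass `fix_e_rev = FALSE` to free
#' it.
#'
#' @param iv an [iv_curve()] with at least 5 voltages spanning the
#'   activation range
#' @param initial an [activation_params()] start guess
#' @param fix_e_rev keep `e_rev` at its initial value (default `TRUE`)
#' @param n_starts number of deterministic multi-start points (default 5)
#' @return a `kvmix_fit` with free parameters `amp`, `v_n`, `k_n`
#'   (and `e_rev` unless fixed), 95% confidence half-widths, RSS and a
#'   convergence flag; non-convergence is flagged, never an error
#' @export
fit_wildtype_iv <- function(iv, initial, fix_e_rev = TRUE, n_starts = 5) {
  stopifnot(inherits(iv, "iv_curve"), inherits(initial, "activation_params"))
  v <- iv$voltage_mV; y <- iv$current
  if (length(v) < 5L)
    stop("need at least 5 voltage points", call. = FALSE)
  if (all(abs(y) < 1e-12))
    stop("degenerate IV: all currents are zero", call. = FALSE)
  shape0 <- (v - initial$e_rev) *
    boltzmann_open_fraction(v, initial$v_n, initial$k_n)
  amp0 <- sum(y * shape0) / max(sum(shape0^2), 1e-12)
  if (!is.finite(amp0) || amp0 <= 0) amp0 <- 1
  start <- list(amp = amp0, v_n = initial$v_n, k_n = initial$k_n)
  lower <- c(amp = 1e-9, v_n = -250, k_n = 0.5)
  upper <- c(amp = 1e9, v_n = 150, k_n = 200)
  fixed <- c(e_rev = initial$e_rev)
  if (!fix_e_rev) {
    start$e_rev <- initial$e_rev
    lower <- c(lower, e_rev = -150); upper <- c(upper, e_rev = 150)
    fixed <- c()
  }
  model_of <- function(p, v) {
    e_rev <- if (fix_e_rev) initial$e_rev else p$e_rev
    p$amp * (v - e_rev) * boltzmann_open_fraction(v, p$v_n, p$k_n)
  }
  fit <- .ls_multistart(function(p) y - model_of(p, v),
                        start, lower, upper, n_starts)
  res <- .make_fit_result(fit, names(start), fixed, lower, upper,
                          length(y), "Activation (single gate)",
                          function(vv) model_of(as.list(fit$par), vv))
  res$activation_params <- activation_params(
    gamma = res$parameters[["amp"]], e_rev = res$parameters[["e_rev"]],
    v_n = res$parameters[["v_n"]], k_n = res$parameters[["k_n"]])
  res
}

#' Fit the binomial heteromer mixture model to a coexpression IV curve
#'
#' Fits `v_ns` (hypothetical all-mutant half-activation voltage) and
#' `p_s` (per-subunit mutant incorporation probability), with the
#' wild-type `v_n` and `k_n` held at the values obtained from the
#' control (wild-type only) fit and an overall free scale `amp`. By
#' default the mutant slope factor is tied to `k_n` (`fix_k_ns = TRUE`),
#' the standard simplification; untying it adds `k_ns` as a free
#' parameter.
#'
#' @param iv coexpression [iv_curve()], normalized or absolute
#'   consistently with the wild-type fit
#' @param fixed converged [activation_params()] from the wild-type fit
#' @param initial a [mixture_params()] start guess
#' @param fix_k_ns tie the mutant slope factor to `k_n` (default `TRUE`)
#' @param n_starts deterministic multi-start points (default 5)
#' @return a `kvmix_fit`; free parameters `amp`, `v_ns`, `p_s`
#'   (+ `k_ns` when untied)
#' @export
fit_coexpression_iv <- function(iv, fixed, initial, fix_k_ns = TRUE,
                                n_starts = 5) {
  stopifnot(inherits(iv, "iv_curve"), inherits(fixed, "activation_params"),
            inherits(initial, "mixture_params"))
  v <- iv$voltage_mV; y <- iv$current
  if (length(v) < 5L)
    stop("need at least 5 voltage points", call. = FALSE)
  if (all(abs(y) < 1e-12))
    stop("degenerate IV: all currents are zero", call. = FALSE)
  base <- activation_params(1, fixed$e_rev, fixed$v_n, fixed$k_n)
  model_of <- function(p, v) {
    k_ns <- if (fix_k_ns) NULL else p$k_ns
    p$amp * mixture_iv(base, mixture_params(p$v_ns, p$p_s, k_ns), v)
  }
  shape0 <- mixture_iv(base, initial, v)
  amp0 <- sum(y * shape0) / max(sum(shape0^2), 1e-12)
  if (!is.finite(amp0) || amp0 <= 0) amp0 <- 1
  start <- list(amp = amp0, v_ns = initial$v_ns, p_s = initial$p_s)
  lower <- c(amp = 1e-9, v_ns = -300, p_s = 0)
  upper <- c(amp = 1e9, v_ns = 100, p_s = 1)
  fixedp <- c(v_n = fixed$v_n, k_n = fixed$k_n, e_rev = fixed$e_rev)
  if (!fix_k_ns) {
    start$k_ns <- if (is.null(initial$k_ns)) fixed$k_n else initial$k_ns
    lower <- c(lower, k_ns = 0.5); upper <- c(upper, k_ns = 200)
  } else {
    fixedp <- c(fixedp, k_ns = fixed$k_n)
  }
  fit <- .ls_multistart(function(p) y - model_of(p, v),
                        start, lower, upper, n_starts)
  res <- .make_fit_result(fit, names(start), fixedp, lower, upper,
                          length(y), "Binomial heteromer mixture",
                          function(vv) model_of(as.list(fit$par), vv))
  res$mixture_params <- mixture_params(
    v_ns = res$parameters[["v_ns"]], p_s = res$parameters[["p_s"]],
    k_ns = if (fix_k_ns) NULL else res$parameters[["k_ns"]])
  res
}

#' Fit the tail-current activation curve
#'
#' Least-squares fit of the Boltzmann tail-activation model to tail
#' currents measured at a fixed repolarization voltage and normalized to
#' the value after the +30 mV depolarization. Flat input (no voltage
#' dependence) yields a flagged, non-converged result.
#'
#' @param iv [iv_curve()] of normalized tail currents vs test voltage
#' @param initial optional [tail_activation_params()] start guess;
#'   heuristics are used when omitted
#' @param n_starts deterministic multi-start points (default 5)
#' @return a `kvmix_fit` with free parameters `r_neg_inf`, `r_inf`,
#'   `v_n`, `k_n`
#' @export
fit_tail_activation <- function(iv, initial = NULL, n_starts = 5) {
  stopifnot(inherits(iv, "iv_curve"))
  v <- iv$voltage_mV; y <- iv$current
  if (length(v) < 5L)
    stop("need at least 5 voltage points", call. = FALSE)
  if (diff(range(y)) < 1e-8) {
    # degenerate: no voltage dependence to fit
    return(structure(list(
      parameters = c(r_neg_inf = mean(y), r_inf = mean(y),
                     v_n = NA_real_, k_n = NA_real_),
      free = c("r_neg_inf", "r_inf", "v_n", "k_n"), fixed = character(),
      ci95 = c(r_neg_inf = Inf, r_inf = Inf, v_n = Inf, k_n = Inf),
      rss = sum((y - mean(y))^2), n_obs = length(y), converged = FALSE,
      info = 0L, message = "flat input: degenerate tail-activation data",
      unidentifiable = c("r_neg_inf", "r_inf", "v_n", "k_n"),
      model = "Tail activation", model_fn = function(vv) rep(mean(y),
                                                             length(vv))),
      class = "kvmix_fit"))
  }
  if (is.null(initial)) {
    lo <- min(y); hi <- max(y)
    vh <- v[which.min(abs(y - (lo + hi) / 2))]
    initial <- tail_activation_params(lo, hi, vh, 10)
  }
  start <- list(r_neg_inf = initial$r_neg_inf, r_inf = initial$r_inf,
                v_n = initial$v_n, k_n = initial$k_n)
  lower <- c(r_neg_inf = -10, r_inf = -10, v_n = -250, k_n = 0.5)
  upper <- c(r_neg_inf = 20, r_inf = 20, v_n = 150, k_n = 200)
  model_of <- function(p, v)
    p$r_neg_inf + (p$r_inf - p$r_neg_inf) *
      boltzmann_open_fraction(v, p$v_n, p$k_n)
  fit <- .ls_multistart(function(p) y - model_of(p, v),
                        start, lower, upper, n_starts)
  res <- .make_fit_result(fit, names(start), c(), lower, upper,
                          length(y), "Tail activation",
                          function(vv) model_of(as.list(fit$par), vv))
  if (res$converged)
    res$tail_activation_params <- tail_activation_params(
      res$parameters[["r_neg_inf"]], res$parameters[["r_inf"]],
      res$parameters[["v_n"]], res$parameters[["k_n"]])
  res
}
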