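# Whole-cell trace containers and preprocessing: leak subtraction and
# steady-state IV extraction. A trace set holds one voltage-step family
# on a shared uniform time base; by convention t = 0 is the onset of the
# depolarizing step, which lasts protocol$step_duration_s and is
# followed (optionally) by a tail segment at protocol$tail_voltage_mV.

#' Construct a voltage-step trace family
#'
#' @param time_s shared, uniformly sampled time base (s), starting at the
#'   step onset
#' @param currents numeric matrix, one column per sweep (pA)
#' @param protocol list with elements `holding_mV`, `step_mV` (one
#'   voltage per sweep, strictly increasing), `step_duration_s`, and
#'   optionally `tail_voltage_mV` (default: holding)
#' @param construct free-text construct label
#' @param leak_corrected logical flag
#' @return an object of class `trace_set`
#' @export
trace_set <- function(time_s, currents, protocol, construct = "",
                      leak_corrected = FALSE) {
  currents <- as.matrix(currents)
  stopifnot(is.numeric(time_s), is.numeric(currents),
            nrow(currents) == length(time_s))
  dt <- diff(time_s)
  if (length(dt) && (any(dt <= 0) ||
                     max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1e-12)))
    stop("time base must be uniform and increasing", call. = FALSE)
  req <- c("holding_mV", "step_mV", "step_duration_s")
  if (!all(req %in% names(protocol)))
    stop("protocol must contain: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (length(protocol$step_mV) != ncol(currents))
    stop("protocol lists ", length(protocol$step_mV),
         " step voltages but the trace set has ", ncol(currents),
         " sweeps", call. = FALSE)
  if (is.unsorted(protocol$step_mV, strictly = TRUE))
    stop("step voltages must be strictly increasing", call. = FALSE)
  if (is.null(protocol$tail_voltage_mV))
    protocol$tail_voltage_mV <- protocol$holding_mV
  colnames(currents) <- sprintf("sweep_%02d", seq_len(ncol(currents)))
  structure(list(time_s = time_s, currents = currents,
                 protocol = protocol, construct = construct,
                 leak_corrected = leak_corrected),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "Trace set '%s': %d sweeps (%g to %g mV), %d samples @ %g kHz%s\n",
    x$construct, ncol(x$currents), min(x$protocol$step_mV),
    max(x$protocol$step_mV), length(x$time_s),
    1e-3 / diff(x$time_s[1:2]),
    if (x$leak_corrected) ", leak-corrected" else ""))
  invisible(x)
}

#' Construct a tail-current trace family
#'
#' Tail currents recorded at one fixed repolarization voltage after a
#' family of depolarizing test pulses; t = 0 is the start of the tail
#' segment.
#'
#' @param time_s shared time base (s) starting at 0
#' @param currents matrix, one column per tail trace (pA)
#' @param test_voltage_mV preceding test voltage of each trace (mV)
#' @param tail_voltage_mV repolarization voltage (mV), e.g. -120
#' @return an object of class `tail_trace_set`
#' @export
tail_trace_set <- function(time_s, currents, test_voltage_mV,
                           tail_voltage_mV = -120) {
  currents <- as.matrix(currents)
  stopifnot(nrow(currents) == length(time_s),
            ncol(currents) == length(test_voltage_mV))
  if (abs(time_s[1]) > 1e-12)
    stop("tail time base must start at t = 0 (tail-segment onset)",
         call. = FALSE)
  structure(list(time_s = time_s, currents = currents,
                 test_voltage_mV = test_voltage_mV,
                 tail_voltage_mV = tail_voltage_mV),
            class = "tail_trace_set")
}

#' Construct a current-voltage curve
#'
#' @param voltage_mV strictly increasing voltages (mV)
#' @param current currents (pA), or dimensionless when normalized
#' @param normalized logical; `TRUE` when divided by a reference value
#' @param reference_mV reference voltage of the normalization (mV)
#' @return an object of class `iv_curve` (also a data.frame)
#' @export
iv_curve <- function(voltage_mV, current, normalized = FALSE,
                     reference_mV = NA_real_) {
  stopifnot(length(voltage_mV) == length(current))
  if (is.unsorted(voltage_mV, strictly = TRUE))
    stop("voltages must be strictly increasing", call. = FALSE)
  if (normalized && is.finite(reference_mV)) {
    at_ref <- current[match(reference_mV, voltage_mV)]
    if (!is.na(at_ref) && abs(at_ref - 1) > 1e-6)
      stop("normalized IV must equal 1 at its reference voltage",
           call. = FALSE)
  }
  structure(data.frame(voltage_mV = voltage_mV, current = current),
            normalized = normalized, reference_mV = reference_mV,
            class = c("iv_curve", "data.frame"))
}

# command voltage at each sample of a trace-set sweep
.sweep_voltage <- function(traces, sweep) {
  p <- traces$protocol
  ifelse(traces$time_s <= p$step_duration_s + 1e-12,
         p$step_mV[sweep], p$tail_voltage_mV)
}

#' Subtract linear (ohmic) leak currents offline
#'
#' Estimates the leak conductance and reversal by linear regression of
#' the steady current against the step voltage over a window of voltages
#' at which the channels are closed (default: steps at or below -100 mV,
#' below the activation range of wild-type Kv10 channels), then removes
#' g_leak * (V - V_leak_rev) from every sample of every sweep. Note the
#' caveat for coexpression data: heteromeric gain-of-function channels
#' are already partially activated at -120 mV, so a voltage window free
#' of channel activity may not exist; use generator-known leak or skip.
#'
#' @param traces a [trace_set()]
#' @param leak_below_mV sweeps with step voltage <= this value define the
#'   leak regression window (default -100)
#' @param window_s length of the steady-state averaging window at the end
#'   of the step (s, default 0.1)
#' @return the leak-corrected [trace_set()]; the estimate is attached as
#'   attribute `leak` (list with `g_leak_nS`, `v_rev_mV`)
#' @export
subtract_linear_leak <- function(traces, leak_below_mV = -100,
                                 window_s = 0.1) {
  stopifnot(inherits(traces, "trace_set"))
  v <- traces$protocol$step_mV
  sel <- which(v <= leak_below_mV)
  if (length(sel) < 2L)
    stop("leak estimation requires at least two sweeps at or below ",
         leak_below_mV, " mV", call. = FALSE)
  iv <- extract_steady_state_iv(traces, window_s = window_s,
                                normalize_at = NULL)
  fit <- stats::lm(current ~ voltage_mV, data = iv[sel, ])
  g <- unname(stats::coef(fit)[2])            # pA/mV = nS
  a <- unname(stats::coef(fit)[1])            # pA at 0 mV
  corrected <- traces$currents
  for (j in seq_len(ncol(corrected))) {
    v_t <- .sweep_voltage(traces, j)
    corrected[, j] <- corrected[, j] - (a + g * v_t)
  }
  out <- trace_set(traces$time_s, corrected, traces$protocol,
                   construct = traces$construct, leak_corrected = TRUE)
  attr(out, "leak") <- list(g_leak_nS = g, v_rev_mV = -a / g)
  out
}

#' Extract a steady-state current-voltage relationship
#'
#' Averages each sweep over a window at the end of the depolarizing
#' segment (default: the final 100 ms) and optionally normalizes to the
#' value at a reference voltage (conventionally +30 mV). The reference
#' must match a protocol voltage exactly; no interpolation is performed.
#'
#' @param traces a [trace_set()]
#' @param window_s averaging window length (s), within the step
#' @param normalize_at reference voltage (mV) or `NULL` for absolute
#'   currents
#' @return an [iv_curve()]
#' @export
extract_steady_state_iv <- function(traces, window_s = 0.1,
                                    normalize_at = 30) {
  stopifnot(inherits(traces, "trace_set"))
  dur <- traces$protocol$step_duration_s
  if (window_s <= 0 || window_s > dur)
    stop("averaging window must lie within the depolarizing segment",
         call. = FALSE)
  in_win <- traces$time_s >= dur - window_s - 1e-12 &
    traces$time_s <= dur + 1e-12
  if (!any(in_win))
    stop("no samples inside the averaging window", call. = FALSE)
  i_ss <- colMeans(traces$currents[in_win, , drop = FALSE])
  v <- traces$protocol$step_mV
  if (is.null(normalize_at))
    return(iv_curve(v, unname(i_ss)))
  ref <- match(normalize_at, v)
  if (is.na(ref))
    stop("normalization voltage ", normalize_at,
         " mV is not part of the protocol", call. = FALSE)
  if (abs(i_ss[ref]) < .Machine$double.eps * 100)
    stop("reference current at ", normalize_at,
         " mV is zero; cannot normalize", call. = FALSE)
  iv_curve(v, unname(i_ss / i_ss[ref]), normalized = TRUE,
           reference_mV = normalize_at)
}

#' Per-voltage current ratio between two IV curves
#'
#' Fractional current change of a coexpression IV relative to the
#' corresponding wild-type IV (the voltage-dependent gain-of-function
#' readout). Entries where the wild-type current is below `floor` are
#' masked as `NA`.
#'
#' @param iv_coexp,iv_wt [iv_curve()]s on identical voltage grids, both
#'   normalized at the same reference
#' @param floor minimum |wild-type current| for a defined ratio
#' @return data.frame with columns `voltage_mV`, `ratio`
#' @export
gof_ratio <- function(iv_coexp, iv_wt, floor = 1e-3) {
  if (!isTRUE(all.equal(iv_coexp$voltage_mV, iv_wt$voltage_mV)))
    stop("IV curves are on different voltage grids", call. = FALSE)
  ratio <- iv_coexp$current / iv_wt$current
  ratio[abs(iv_wt$current) < floor] <- NA_real_
  data.frame(voltage_mV = iv_wt$voltage_mV, ratio = ratio)
}

#' Normalize an activation time course from peak tail currents
#'
#' Takes a table of peak tail currents measured after depolarizations of
#' variable length and normalizes all peaks to the maximal activation
#' reference entry (by default 20 mV for 6.5 s).
#'
#' @param peaks data.frame with columns `voltage_mV`, `duration_s`,
#'   `peak_pA`
#' @param ref_voltage_mV,ref_duration_s the reference entry (defaults
#'   20 mV, 6.5 s); must be present in the table
#' @return `peaks` with an added `activation` column in \[0, ~1\]
#' @export
activation_timecourse <- function(peaks, ref_voltage_mV = 20,
                                  ref_duration_s = 6.5) {
  stopifnot(all(c("voltage_mV", "duration_s", "peak_pA") %in%
                  names(peaks)))
  ref <- which(peaks$voltage_mV == ref_voltage_mV &
                 abs(peaks$duration_s - ref_duration_s) < 1e-9)
  if (length(ref) != 1L)
    stop("reference entry (", ref_voltage_mV, " mV, ", ref_duration_s,
         " s) not found in the peak table", call. = FALSE)
  peaks$activation <- peaks$peak_pA / peaks$peak_pA[ref]
  peaks
}
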