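# Readers and writers for the package's plain-text interchange formats:
# long-format trace CSVs with a JSON protocol sidecar, IV-curve CSVs,
# and fit-result JSON. The sidecar lives at "<csv path>.json".

sidecar_path <- function(path) paste0(path, ".json")

#' Write a trace family to CSV with a JSON protocol sidecar
#'
#' Voltage-step families are written long-format with columns
#' `sweep_id`, `step_voltage_mV`, `time_s`, `current_pA`; tail families
#' with `trace_id`, `test_voltage_mV`, `time_s`, `current_pA`. The
#' protocol (and any generator ground truth) goes to `<path>.json`.
#'
#' @param x a [trace_set()] or [tail_trace_set()]
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_trace_set <- function(x, path) {
  if (inherits(x, "trace_set")) {
    n_t <- length(x$time_s)
    df <- data.frame(
      sweep_id = rep(seq_len(ncol(x$currents)), each = n_t),
      step_voltage_mV = rep(x$protocol$step_mV, each = n_t),
      time_s = rep(x$time_s, ncol(x$currents)),
      current_pA = as.numeric(x$currents))
    meta <- list(kind = "trace_set", protocol = x$protocol,
                 construct = x$construct,
                 leak_corrected = x$leak_corrected)
  } else if (inherits(x, "tail_trace_set")) {
    n_t <- length(x$time_s)
    df <- data.frame(
      trace_id = rep(seq_len(ncol(x$currents)), each = n_t),
      test_voltage_mV = rep(x$test_voltage_mV, each = n_t),
      time_s = rep(x$time_s, ncol(x$currents)),
      current_pA = as.numeric(x$currents))
    meta <- list(kind = "tail_trace_set",
                 tail_voltage_mV = x$tail_voltage_mV,
                 test_voltage_mV = x$test_voltage_mV)
  } else stop("not a trace_set or tail_trace_set", call. = FALSE)
  if (!is.null(attr(x, "ground_truth")))
    meta$ground_truth <- .truth_to_json(attr(x, "ground_truth"))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.truth_to_json <- function(gt) {
  if (is.function(gt)) return(NULL)
  if (is.list(gt)) return(lapply(unclass(gt), .truth_to_json))
  gt
}

#' Read a trace family written by [write_trace_set()]
#'
#' The sidecar's `kind` field decides whether a [trace_set()] or a
#' [tail_trace_set()] is reconstructed; all container invariants are
#' re-validated on read.
#'
#' @param path CSV path (sidecar expected at `<path>.json`)
#' @return a [trace_set()] or [tail_trace_set()]
#' @export
read_trace_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar_path(path)))
    stop("protocol sidecar missing: ", sidecar_path(path), call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (identical(meta$kind, "trace_set")) {
    req <- c("sweep_id", "step_voltage_mV", "time_s", "current_pA")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("trace CSV is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ids <- sort(unique(df$sweep_id))
    if (length(ids) != length(meta$protocol$step_mV))
      stop("sidecar lists ", length(meta$protocol$step_mV),
           " step voltages but the CSV holds ", length(ids), " sweeps",
           call. = FALSE)
    time_s <- df$time_s[df$sweep_id == ids[1]]
    cur <- vapply(ids, function(i) df$current_pA[df$sweep_id == i],
                  numeric(length(time_s)))
    trace_set(time_s, cur, protocol = meta$protocol,
              construct = meta$construct %||% "",
              leak_corrected = isTRUE(meta$leak_corrected))
  } else if (identical(meta$kind, "tail_trace_set")) {
    req <- c("trace_id", "test_voltage_mV", "time_s", "current_pA")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("tail CSV is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ids <- sort(unique(df$trace_id))
    time_s <- df$time_s[df$trace_id == ids[1]]
    cur <- vapply(ids, function(i) df$current_pA[df$trace_id == i],
                  numeric(length(time_s)))
    test_v <- vapply(ids, function(i)
      df$test_voltage_mV[df$trace_id == i][1], numeric(1))
    tail_trace_set(time_s, cur, test_v,
                   tail_voltage_mV = meta$tail_voltage_mV %||% -120)
  } else stop("sidecar 'kind' must be trace_set or tail_trace_set",
              call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an IV curve to CSV (with normalization metadata sidecar)
#' @param iv an [iv_curve()]
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_iv_curve <- function(iv, path) {
  utils::write.csv(as.data.frame(iv), path, row.names = FALSE)
  jsonlite::write_json(list(kind = "iv_curve",
                            normalized = attr(iv, "normalized"),
                            reference_mV = attr(iv, "reference_mV")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an IV curve written by [write_iv_curve()]
#' @param path CSV path
#' @return an [iv_curve()]
#' @export
read_iv_curve <- function(path) {
  df <- utils::read.csv(path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list(normalized = FALSE, reference_mV = NA_real_)
  iv_curve(df$voltage_mV, df$current,
           normalized = isTRUE(meta$normalized),
           reference_mV = meta$reference_mV %||% NA_real_)
}

#' Write a fit result to JSON
#'
#' Serializes parameters, 95% confidence half-widths, RSS, free/fixed
#' parameter names, convergence and identifiability flags, plus any
#' provenance block supplied by the caller.
#'
#' @param fit a `kvmix_fit`
#' @param path JSON output path
#' @param provenance optional named list (config, seed, versions)
#' @return `path`, invisibly
#' @export
write_fit_result <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "kvmix_fit"))
  out <- list(model = fit$model,
              parameters = as.list(fit$parameters),
              ci95 = as.list(fit$ci95), rss = fit$rss,
              n_obs = fit$n_obs, converged = fit$converged,
              free = fit$free, fixed = fit$fixed,
              unidentifiable = fit$unidentifiable,
              message = fit$message)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
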