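# Pipeline dispatcher behind the command-line wrapper (inst/cli/kvmix.R).
# A run is described by a config (R list, JSON or YAML file): subcommand,
# input/output paths, per-subcommand options, seed. Every result
# artifact embeds the resolved config, seed and package version.

#' Published fit parameters for the studied constructs
#'
#' Convenience presets carrying the reported activation parameters:
#' Kv10.1 (V_n = -22.0 mV), Kv10.2 (V_n = -54.4 mV), and the
#' Kv10.1 + Kv10.1-G496E coexpression (V_ns = -111 mV, p_s = 0.7).
#' The slope factor is not reported for these constructs; the package
#' default of k_n = 12 mV is used (see the methods vignette). E_rev =
#' 2 mV corresponds to the 140/130 mM K+ recording solutions.
#'
#' @param name one of `"kv10.1"`, `"kv10.2"`, `"coexpression"`
#' @param gamma total conductance for trace simulation (nS, default 1)
#' @return list with elements `act` ([activation_params()]) and `mix`
#'   ([mixture_params()] or `NULL`)
#' @export
preset_params <- function(name = c("kv10.1", "kv10.2", "coexpression"),
                          gamma = 1) {
  name <- match.arg(name)
  e_rev <- 2
  k_n <- 12
  switch(name,
    "kv10.1" = list(act = activation_params(gamma, e_rev, -22, k_n),
                    mix = NULL),
    "kv10.2" = list(act = activation_params(gamma, e_rev, -54.4, k_n),
                    mix = NULL),
    "coexpression" = list(
      act = activation_params(gamma, e_rev, -22, k_n),
      mix = mixture_params(v_ns = -111, p_s = 0.7)))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package", call. = FALSE)
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

.provenance <- function(config) {
  list(config = config, seed = config$seed %||% NA,
       package = "kvmix",
       version = as.character(utils::packageVersion("kvmix")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run one analysis or simulation pipeline step
#'
#' Dispatches on `config$subcommand`: `simulate-iv`, `simulate-tails`,
#' `simulate-imaging`, `fit-iv`, `fit-coexpression-iv`, `fit-tails`,
#' `fit-tail-activation`, `analyze-imaging`, or `calibrate`. All
#' randomness flows from `config$seed`. Result artifacts (CSV/JSON)
#' embed the resolved config for provenance. A flagged non-converged
#' fit raises an error after writing its artifact, unless
#' `config$allow_nonconverged` is true.
#'
#' @param config named list, or path to a JSON/YAML config file.
#'   Common fields: `subcommand`, `input`, `out`, `seed`; subcommand
#'   options are documented with the corresponding functions.
#' @return (invisibly) a list of written artifact paths
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  sub <- cfg$subcommand
  if (is.null(sub))
    stop("config must name a 'subcommand'", call. = FALSE)
  out <- cfg$out %||% stop("config must name an output path 'out'",
                           call. = FALSE)
  seed <- cfg$seed %||% 1L
  prov <- .provenance(cfg)
  check_conv <- function(fit) {
    if (!fit$converged && !isTRUE(cfg$allow_nonconverged))
      stop("fit did not converge (artifact written); rerun with ",
           "allow_nonconverged to accept flagged parameters",
           call. = FALSE)
  }
  paths <- switch(sub,
    "simulate-iv" = {
      pr <- preset_params(cfg$preset %||% "kv10.1",
                          gamma = cfg$gamma %||% 1)
      spec <- iv_generator_spec(
        pr$act, pr$mix,
        noise = cfg$noise %||% 0.01,
        leak_g_nS = cfg$leak_g_nS %||% 0,
        sample_rate_hz = cfg$sample_rate_hz %||% 500,
        step_duration_s = cfg$step_duration_s %||% 5,
        seed = seed)
      write_trace_set(gen_iv_dataset(spec), out)
      out
    },
    "simulate-tails" = {
      dp <- deactivation_params(cfg$tau_fast %||% 0.008,
                                cfg$tau_slow %||% 5, cfg$f %||% 5)
      v <- cfg$test_voltages_mV %||% seq(-60, 20, 20)
      spec <- tail_generator_spec(
        dp, p_s = rep_len(cfg$p_s %||% 0.6, length(v)),
        amplitude = rep_len(cfg$amplitude %||% 100, length(v)),
        test_voltages_mV = v,
        tail_voltage_mV = cfg$tail_voltage %||% -120,
        duration_s = cfg$duration_s %||% 15,
        noise = cfg$noise %||% 0.01, seed = seed)
      write_trace_set(gen_tail_dataset(spec), out)
      out
    },
    "simulate-imaging" = {
      cond <- if (!is.null(cfg$conditions)) as.data.frame(cfg$conditions)
              else data.frame(condition = c("control", "channel"),
                              mean_mV = c(-37, -60), sd_mV = c(8, 8))
      spec <- imaging_generator_spec(
        cond,
        dishes_per_condition = cfg$dishes_per_condition %||% 6,
        cells_per_dish = cfg$cells_per_dish %||% 1000,
        background = cfg$background %||% 50,
        gain = cfg$gain %||% 1, seed = seed)
      rec <- gen_imaging_dataset(spec, level = "table")
      utils::write.csv(rec, out, row.names = FALSE)
      jsonlite::write_json(
        c(.truth_to_json(attr(rec, "ground_truth")),
          list(provenance = prov)),
        sidecar_path(out), auto_unbox = TRUE, digits = NA)
      out
    },
    "fit-iv" = {
      traces <- read_trace_set(cfg$input)
      win <- (cfg$window_ms %||% 100) / 1000
      iv <- extract_steady_state_iv(traces, window_s = win,
                                    normalize_at = cfg$normalize_at
                                      %||% 30)
      init <- activation_params(1, cfg$e_rev %||% 2,
                                cfg$v_n_init %||% -30,
                                cfg$k_n_init %||% 12)
      fit <- fit_wildtype_iv(iv, init)
      write_fit_result(fit, out, provenance = prov)
      check_conv(fit)
      out
    },
    "fit-coexpression-iv" = {
      traces <- read_trace_set(cfg$input)
      win <- (cfg$window_ms %||% 100) / 1000
      iv <- extract_steady_state_iv(traces, window_s = win,
                                    normalize_at = cfg$normalize_at
                                      %||% 30)
      fixed <- activation_params(1, cfg$e_rev %||% 2, cfg$v_n,
                                 cfg$k_n)
      init <- mixture_params(cfg$v_ns_init %||% (cfg$v_n - 60),
                             cfg$p_s_init %||% 0.5)
      fit <- fit_coexpression_iv(iv, fixed, init,
                                 fix_k_ns = !isTRUE(cfg$free_kns))
      write_fit_result(fit, out, provenance = prov)
      check_conv(fit)
      out
    },
    "fit-tails" = {
      tails <- read_trace_set(cfg$input)
      fit <- global_fit_tails(tails, mode = cfg$mode %||% "per-voltage")
      write_fit_result(fit, out, provenance = prov)
      check_conv(fit)
      out
    },
    "fit-tail-activation" = {
      iv <- read_iv_curve(cfg$input)
      fit <- fit_tail_activation(iv)
      write_fit_result(fit, out, provenance = prov)
      check_conv(fit)
      out
    },
    "analyze-imaging" = {
      rec <- utils::read.csv(cfg$input)
      res <- analyze_imaging(
        rec, gramicidin_dishes = cfg$gramicidin_dishes,
        offset_green = cfg$offset %||% 0,
        offset_red = cfg$offset %||% 0,
        anchor_mode = cfg$anchor_mode %||% "scale")
      utils::write.csv(res$summary, out, row.names = FALSE)
      jsonlite::write_json(
        list(background = res$background, anchor = res$anchor,
             gating = res$gating_report,
             mean_of_medians_mV = attr(res$summary,
                                       "mean_of_medians_mV"),
             provenance = prov),
        sidecar_path(out), auto_unbox = TRUE, digits = NA)
      out
    },
    "calibrate" = {
      anchor <- gramicidin_anchor(cfg$dish_medians,
                                  mode = cfg$anchor_mode %||% "scale")
      jsonlite::write_json(c(anchor, list(provenance = prov)), out,
                           auto_unbox = TRUE, digits = NA)
      out
    },
    stop("unknown subcommand: ", sub, call. = FALSE))
  invisible(paths)
}
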