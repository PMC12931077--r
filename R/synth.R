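# Seeded generators for every input the analysis consumes: steady-state
# IV families (with optional activation-kinetics and leak realism), tail
# deactivation families, and single-cell imaging populations. Each
# generator attaches a "ground_truth" attribute sufficient to score any
# downstream estimate. Generators never call fitting code.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one noisy steady-state IV curve
#'
#' Evaluates the activation model (wild type or binomial mixture) on a
#' voltage grid, adds Gaussian noise scaled to the largest absolute
#' current, and optionally normalizes at a reference voltage. Uses the
#' current RNG state; wrap in a seeded loop for replicate studies.
#'
#' @param act an [activation_params()]
#' @param mix optional [mixture_params()] for coexpression curves
#' @param voltages voltage grid (mV), default -120..30 in 10-mV steps
#' @param noise Gaussian noise SD as a fraction of max |current|
#'   (default 0.01)
#' @param normalize_at reference voltage (mV) or `NULL`
#' @return an [iv_curve()] with attribute `ground_truth`
#' @export
gen_iv_curve <- function(act, mix = NULL, voltages = seq(-120, 30, 10),
                         noise = 0.01, normalize_at = 30) {
  clean <- if (is.null(mix)) hh_current(act, voltages)
           else mixture_iv(act, mix, voltages)
  y <- clean + stats::rnorm(length(clean), sd = noise * max(abs(clean)))
  if (!is.null(normalize_at)) {
    ref <- match(normalize_at, voltages)
    if (is.na(ref)) stop("normalize_at must be on the voltage grid",
                         call. = FALSE)
    y <- y / y[ref]
    out <- iv_curve(voltages, y, normalized = TRUE,
                    reference_mV = normalize_at)
  } else out <- iv_curve(voltages, y)
  attr(out, "ground_truth") <- list(act = act, mix = mix, noise = noise)
  out
}

#' Specification for a synthetic voltage-step trace family
#'
#' @param act [activation_params()] of the (wild-type) population
#' @param mix optional [mixture_params()] for coexpression
#' @param tau_act_s activation time constant (s); scalar, one value per
#'   step voltage, or a function of voltage. Single-exponential
#'   activation is a realism device for testing window placement, not a
#'   kinetic model.
#' @param leak_g_nS,leak_e_rev_mV linear leak conductance and reversal
#' @param noise Gaussian noise SD as a fraction of the per-sweep maximum
#' @param holding_mV,steps_mV,step_duration_s,tail_duration_s,tail_voltage_mV
#'   voltage protocol (defaults: 5-s steps, -120..30 mV in 10-mV
#'   increments, return to -120 mV)
#' @param sample_rate_hz sampling rate (default 500 Hz)
#' @param tau_deact_s deactivation time constant of the appended tail
#' @param seed RNG seed; identical seeds give identical output
#' @return an object of class `iv_generator_spec`
#' @export
iv_generator_spec <- function(act, mix = NULL, tau_act_s = 0.2,
                              leak_g_nS = 0, leak_e_rev_mV = 0,
                              noise = 0.01, holding_mV = -120,
                              steps_mV = seq(-120, 30, 10),
                              step_duration_s = 5,
                              tail_duration_s = 0.5,
                              tail_voltage_mV = holding_mV,
                              sample_rate_hz = 500, tau_deact_s = 0.02,
                              seed = 1L) {
  stopifnot(inherits(act, "activation_params"), noise >= 0,
            sample_rate_hz > 0, step_duration_s > 0)
  structure(as.list(environment()), class = "iv_generator_spec")
}

#' Generate a synthetic voltage-step trace family
#'
#' Per sweep: linear leak plus the model steady-state current scaled by
#' a single-exponential activation time course, followed by a tail
#' segment at the tail voltage with exponential deactivation. Gaussian
#' noise is added at the configured fraction of each sweep's maximum.
#'
#' @param spec an [iv_generator_spec()]
#' @return a [trace_set()] with attribute `ground_truth`
#' @export
gen_iv_dataset <- function(spec) {
  stopifnot(inherits(spec, "iv_generator_spec"))
  with_seed(spec$seed, {
    v <- spec$steps_mV
    tau <- if (is.function(spec$tau_act_s)) spec$tau_act_s(v)
           else rep_len(spec$tau_act_s, length(v))
    dt <- 1 / spec$sample_rate_hz
    time_s <- seq(0, spec$step_duration_s + spec$tail_duration_s, by = dt)
    in_step <- time_s <= spec$step_duration_s + 1e-12
    open_frac <- function(vv) {
      if (is.null(spec$mix))
        boltzmann_open_fraction(vv, spec$act$v_n, spec$act$k_n)
      else {
        w <- stoichiometry_weights(spec$mix$p_s)
        vn_m <- vn_of_composition(0:3, spec$act$v_n, spec$mix$v_ns)
        k_m <- k_of_composition(0:3, spec$act$k_n, spec$mix$k_ns)
        sum(w[1:4] * boltzmann_open_fraction(vv, vn_m, k_m))
      }
    }
    leak <- function(vv) spec$leak_g_nS * (vv - spec$leak_e_rev_mV)
    cur <- vapply(seq_along(v), function(j) {
      i_ss <- spec$act$gamma * (v[j] - spec$act$e_rev) * open_frac(v[j])
      act_tc <- if (tau[j] <= 0) rep(1, sum(in_step))
                else 1 - exp(-time_s[in_step] / tau[j])
      step_i <- leak(v[j]) + i_ss * act_tc
      g_end <- spec$act$gamma * open_frac(v[j]) *
        (if (tau[j] <= 0) 1 else 1 - exp(-spec$step_duration_s / tau[j]))
      t_tail <- time_s[!in_step] - spec$step_duration_s
      tail_i <- leak(spec$tail_voltage_mV) +
        g_end * (spec$tail_voltage_mV - spec$act$e_rev) *
        exp(-t_tail / spec$tau_deact_s)
      clean <- c(step_i, tail_i)
      clean + stats::rnorm(length(clean),
                           sd = spec$noise * max(abs(clean)))
    }, numeric(length(time_s)))
    out <- trace_set(time_s, cur,
                     protocol = list(holding_mV = spec$holding_mV,
                                     step_mV = v,
                                     step_duration_s = spec$step_duration_s,
                                     tail_voltage_mV = spec$tail_voltage_mV),
                     construct = if (is.null(spec$mix)) "wild-type"
                                 else "coexpression")
    attr(out, "ground_truth") <- list(
      act = spec$act, mix = spec$mix, tau_act_s = tau,
      leak_g_nS = spec$leak_g_nS, leak_e_rev_mV = spec$leak_e_rev_mV,
      noise = spec$noise, seed = spec$seed)
    out
  })
}

#' Specification for a synthetic tail-current family
#'
#' @param params [deactivation_params()] (shared kinetic constants)
#' @param p_s mutant-subunit probability per test voltage
#' @param amplitude initial tail amplitude per test voltage (pA)
#' @param test_voltages_mV preceding test voltages (mV)
#' @param tail_voltage_mV repolarization voltage (default -120)
#' @param sample_rate_hz sampling rate (default 1 kHz; must resolve the
#'   fast millisecond-scale wild-type deactivation)
#' @param duration_s tail duration (s, default 15)
#' @param noise Gaussian noise SD as a fraction of the family's largest
#'   initial amplitude (default 0.01); shared across traces, matching
#'   the uniform-weight global fit
#' @param seed RNG seed
#' @return an object of class `tail_generator_spec`
#' @export
tail_generator_spec <- function(params, p_s, amplitude,
                                test_voltages_mV, tail_voltage_mV = -120,
                                sample_rate_hz = 1000, duration_s = 15,
                                noise = 0.01, seed = 1L) {
  stopifnot(inherits(params, "deactivation_params"),
            length(p_s) == length(test_voltages_mV),
            length(amplitude) == length(test_voltages_mV),
            duration_s > 0, noise >= 0)
  if (duration_s < 1 / sample_rate_hz)
    stop("duration shorter than one sample", call. = FALSE)
  structure(as.list(environment()), class = "tail_generator_spec")
}

#' Generate a synthetic tail-current family
#'
#' Samples [tail_mixture_model()] on the configured time base for each
#' test voltage and adds Gaussian noise.
#'
#' @param spec a [tail_generator_spec()]
#' @return a [tail_trace_set()] with attribute `ground_truth`
#' @export
gen_tail_dataset <- function(spec) {
  stopifnot(inherits(spec, "tail_generator_spec"))
  with_seed(spec$seed, {
    t <- seq(0, spec$duration_s, by = 1 / spec$sample_rate_hz)
    cur <- vapply(seq_along(spec$test_voltages_mV), function(j) {
      clean <- tail_mixture_model(t, spec$params, p_s = spec$p_s[j],
                                  amplitude = spec$amplitude[j])
      clean + stats::rnorm(length(clean),
                           sd = spec$noise * max(spec$amplitude))
    }, numeric(length(t)))
    out <- tail_trace_set(t, cur, spec$test_voltages_mV,
                          spec$tail_voltage_mV)
    attr(out, "ground_truth") <- list(
      params = spec$params, p_s = spec$p_s, amplitude = spec$amplitude,
      noise = spec$noise, seed = spec$seed)
    out
  })
}

#' Specification for a synthetic imaging experiment
#'
#' @param conditions data.frame with columns `condition`, `mean_mV`,
#'   `sd_mV`: the true resting-voltage distribution per construct
#' @param dishes_per_condition dishes per condition (default 6)
#' @param cells_per_dish cells per dish (default 1000)
#' @param gramicidin_dishes number of gramicidin calibration dishes
#'   (true voltage forced to 0 mV; default 2)
#' @param expression_meanlog,expression_sdlog log-normal F_red
#'   expression distribution (defaults log(500), 0.6)
#' @param gain instrument gain multiplying the green channel (default 1)
#' @param background additive green-channel background (a.u., default 50)
#' @param offset camera offset added to green and red (default 100)
#' @param full_scale camera full scale (default 16383, 14-bit)
#' @param shot_scale green-channel shot-noise scale: SD =
#'   `shot_scale * sqrt(signal)` (default 1; gain-scaled Poisson
#'   approximation at the green acquisition camera gain of 64)
#' @param shot_scale_red red-channel shot-noise scale. The red channel
#'   is acquired at camera gain 5.1 versus 64 for green, so its
#'   variance per count is lower by that ratio; default
#'   `shot_scale * sqrt(5.1 / 64)`.
#' @param photoswitch_tau_frames photoswitching time constant of the
#'   green frame series, in frames (default 0.8: plateau by frame 3-4)
#' @param std a [calibration_standard()]
#' @param pixel_size_um image scale for image-level output
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd nucleus size
#'   distribution
#' @param seed RNG seed
#' @return an object of class `imaging_generator_spec`
#' @export
imaging_generator_spec <- function(conditions,
                                   dishes_per_condition = 6,
                                   cells_per_dish = 1000,
                                   gramicidin_dishes = 2,
                                   expression_meanlog = log(500),
                                   expression_sdlog = 0.6,
                                   gain = 1, background = 50,
                                   offset = 100, full_scale = 16383,
                                   shot_scale = 1,
                                   shot_scale_red =
                                     shot_scale * sqrt(5.1 / 64),
                                   photoswitch_tau_frames = 0.8,
                                   std = restus_calibration(),
                                   pixel_size_um = 0.73,
                                   nucleus_radius_um_mean = 2,
                                   nucleus_radius_um_sd = 0.15,
                                   seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "mean_mV", "sd_mV") %in% names(conditions)),
            cells_per_dish > 0, dishes_per_condition > 0, gain > 0,
            background >= 0, shot_scale >= 0,
            inherits(std, "calibration_standard"))
  structure(as.list(environment()), class = "imaging_generator_spec")
}

# one cell-record table row block for a dish
.gen_dish_records <- function(spec, dish_id, condition, true_v) {
  n <- length(true_v)
  f_red_sig <- stats::rlnorm(n, spec$expression_meanlog,
                             spec$expression_sdlog)
  r_true <- voltage_to_ratio(true_v, spec$std)
  f_green_sig <- spec$gain * f_red_sig * r_true + spec$background
  shot <- function(x, scale) x + scale * sqrt(pmax(x, 0)) *
    stats::rnorm(length(x))
  radius <- stats::rnorm(n, spec$nucleus_radius_um_mean,
                         spec$nucleus_radius_um_sd)
  data.frame(dish_id = dish_id, condition = condition,
             position_id = rep_len(1:16, n),
             f_green = pmin(shot(f_green_sig, spec$shot_scale) +
                              spec$offset, spec$full_scale),
             f_red = pmin(shot(f_red_sig, spec$shot_scale_red) +
                            spec$offset, spec$full_scale),
             f_blue = shot(rep(200, n), spec$shot_scale) + spec$offset,
             area_um2 = pi * radius^2, border_flag = FALSE,
             true_voltage_mV = true_v)
}

#' Generate a synthetic single-cell imaging experiment
#'
#' Table level: draws each cell's true resting voltage from its
#' condition's distribution, an F_red expression level, and builds
#' F_green as `gain * F_red * R(V) + background` plus camera offset and
#' shot-like noise. Gramicidin dishes have true voltage 0 mV. Image
#' level additionally renders, for a reduced number of cells per
#' position, the blue nuclear disks and the green (4-frame
#' photoswitching series) and red channels over the surrounding soma
#' disks.
#'
#' @param spec an [imaging_generator_spec()]
#' @param level `"table"` (default) or `"image"`
#' @param image_px side length of rendered positions (image level)
#' @param cells_per_position cells per rendered position (image level)
#' @return table level: cell-record data.frame (with a
#'   `true_voltage_mV` column) plus attribute `ground_truth`; image
#'   level: list of positions, each with `blue`, `green` (list of 4),
#'   `red` matrices and the true per-cell table
#' @export
gen_imaging_dataset <- function(spec, level = c("table", "image"),
                                image_px = 192, cells_per_position = 8) {
  stopifnot(inherits(spec, "imaging_generator_spec"))
  level <- match.arg(level)
  with_seed(spec$seed, {
    if (level == "table") {
      blocks <- list(); truth_med <- list()
      for (ci in seq_len(nrow(spec$conditions))) {
        cond <- spec$conditions$condition[ci]
        for (d in seq_len(spec$dishes_per_condition)) {
          v <- stats::rnorm(spec$cells_per_dish,
                            spec$conditions$mean_mV[ci],
                            spec$conditions$sd_mV[ci])
          id <- sprintf("%s_dish%02d", cond, d)
          blocks[[id]] <- .gen_dish_records(spec, id, cond, v)
        }
        truth_med[[cond]] <- stats::median(unlist(
          lapply(blocks[grepl(paste0("^", cond, "_"), names(blocks))],
                 function(b) b$true_voltage_mV)))
      }
      for (g in seq_len(spec$gramicidin_dishes)) {
        id <- sprintf("gramicidin_dish%02d", g)
        blocks[[id]] <- .gen_dish_records(
          spec, id, "gramicidin", rep(0, spec$cells_per_dish))
      }
      out <- do.call(rbind, blocks)
      rownames(out) <- NULL
      attr(out, "ground_truth") <- list(
        condition_median_mV = unlist(truth_med),
        background = spec$background, gain = spec$gain,
        offset = spec$offset, seed = spec$seed)
      out
    } else {
      .gen_imaging_images(spec, image_px, cells_per_position)
    }
  })
}

# image-level rendering: nuclei as blue disks, green/red over soma disks
.gen_imaging_images <- function(spec, image_px, cells_per_position) {
  px <- spec$pixel_size_um
  r_nuc_px <- spec$nucleus_radius_um_mean / px
  r_soma_px <- 2.5 * r_nuc_px
  cond <- spec$conditions[1, ]
  v <- stats::rnorm(cells_per_position, cond$mean_mV, cond$sd_mV)
  f_red <- stats::rlnorm(cells_per_position, spec$expression_meanlog,
                         spec$expression_sdlog)
  f_green_plateau <- spec$gain * f_red * voltage_to_ratio(v, spec$std) +
    spec$background
  # non-overlapping centers, away from borders
  margin <- ceiling(r_soma_px) + 2
  centers <- matrix(numeric(0), 0, 2)
  while (nrow(centers) < cells_per_position) {
    cand <- stats::runif(2, margin, image_px - margin)
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2))) >
          2.2 * r_soma_px)
      centers <- rbind(centers, cand)
  }
  xx <- matrix(seq_len(image_px), image_px, image_px)
  yy <- t(xx)
  blank <- matrix(0, image_px, image_px)
  blue <- red <- blank
  green <- lapply(1:4, function(k) blank)
  ps <- 1 - exp(-(1:4) / spec$photoswitch_tau_frames)
  for (i in seq_len(cells_per_position)) {
    d2 <- (xx - centers[i, 1])^2 + (yy - centers[i, 2])^2
    nuc <- d2 <= r_nuc_px^2
    soma <- d2 <= r_soma_px^2
    blue[nuc] <- blue[nuc] + 200
    red[soma] <- red[soma] + f_red[i]
    for (k in 1:4)
      green[[k]][soma] <- green[[k]][soma] + f_green_plateau[i] * ps[k]
  }
  truth <- data.frame(cell = seq_len(cells_per_position),
                      x = centers[, 1] - 1, y = centers[, 2] - 1,
                      true_voltage_mV = v, f_red = f_red,
                      f_green_plateau = f_green_plateau)
  list(positions = list(list(blue = blue, green = green, red = red)),
       truth = truth, pixel_size_um = px,
       nucleus_radius_um = spec$nucleus_radius_um_mean)
}
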