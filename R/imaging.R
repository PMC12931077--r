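# Ratiometric voltage-indicator pipeline. A green voltage-sensitive
# fluorophore is normalized by a voltage-insensitive red partner; the
# per-cell ratio R = F_green/F_red is anchored at 0 mV with gramicidin
# dish medians and converted to membrane voltage through a sigmoid
# calibration standard. Segmentation operates on the blue nuclear stain.

#' Segmentation configuration
#'
#' @param rolling_ball_radius_um background-subtraction radius (µm,
#'   default 74); implemented as a grayscale morphological opening with
#'   a disc structuring element of this radius
#' @param min_area_um2,max_area_um2 nucleus size gate (µm², defaults
#'   7.5 and 19); particles strictly outside the range are excluded
#' @param pixel_size_um image scale (µm/pixel, default 0.73)
#' @param threshold `"otsu"` for automatic thresholding or a numeric
#'   manual threshold on the background-subtracted image
#' @param exclude_border drop particles intersecting the image border
#'   (default `TRUE`)
#' @return an object of class `segmentation_config`
#' @export
segmentation_config <- function(rolling_ball_radius_um = 74,
                                min_area_um2 = 7.5, max_area_um2 = 19,
                                pixel_size_um = 0.73,
                                threshold = "otsu",
                                exclude_border = TRUE) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel size must be positive (µm/pixel)", call. = FALSE)
  if (min_area_um2 >= max_area_um2)
    stop("min nucleus area must be below max nucleus area", call. = FALSE)
  structure(list(rolling_ball_radius_um = rolling_ball_radius_um,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 pixel_size_um = pixel_size_um, threshold = threshold,
                 exclude_border = exclude_border),
            class = "segmentation_config")
}

# labels touching the image border
.border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

#' Segment cell nuclei in the blue (nuclear stain) channel
#'
#' Pipeline: rolling-ball style background subtraction (morphological
#' opening with a disc of the configured radius) -> threshold (Otsu or
#' manual) -> binary mask -> watershed on the distance transform to
#' split touching nuclei -> connected components -> exclusion of
#' particles intersecting the image border and of particles outside the
#' nucleus size range.
#'
#' @param blue 2-D numeric matrix, camera offset already subtracted
#' @param config a [segmentation_config()]
#' @return list with `labels` (integer label matrix, relabeled 1..n) and
#'   `table` (data.frame: `label`, `area_um2`, `centroid_x`,
#'   `centroid_y`, `border_flag`); zero detections give an empty table
#' @export
segment_nuclei <- function(blue, config = segmentation_config()) {
  stopifnot(is.matrix(blue), inherits(config, "segmentation_config"))
  empty <- list(labels = matrix(0L, nrow(blue), ncol(blue)),
                table = data.frame(label = integer(), area_um2 = numeric(),
                                   centroid_x = numeric(),
                                   centroid_y = numeric(),
                                   border_flag = logical()))
  if (max(blue) <= 0) return(empty)
  r_px <- max(1L, round(config$rolling_ball_radius_um /
                          config$pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  bg <- EBImage::opening(blue, brush)
  sub <- pmax(blue - bg, 0)
  thr <- config$threshold
  if (identical(thr, "otsu")) {
    rng <- c(0, max(sub))
    if (rng[2] <= 0) return(empty)
    thr <- EBImage::otsu(EBImage::Image(sub / rng[2])) * rng[2]
  }
  mask <- sub > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(mask)))
  lab <- as.matrix(EBImage::imageData(lab))
  keep_tab <- tabulate(lab[lab > 0])
  ids <- which(keep_tab > 0)
  area <- keep_tab[ids] * config$pixel_size_um^2
  on_border <- ids %in% .border_labels(lab)
  keep <- area >= config$min_area_um2 & area <= config$max_area_um2
  if (config$exclude_border) keep <- keep & !on_border
  ids <- ids[keep]; area <- area[keep]; on_border <- on_border[keep]
  out <- matrix(0L, nrow(lab), ncol(lab))
  cx <- cy <- numeric(length(ids))
  for (i in seq_along(ids)) {
    px <- which(lab == ids[i], arr.ind = TRUE)
    out[px] <- i
    cx[i] <- mean(px[, 1]) - 1     # 0-based pixel coordinates
    cy[i] <- mean(px[, 2]) - 1
  }
  list(labels = out,
       table = data.frame(label = seq_along(ids), area_um2 = area,
                          centroid_x = cx, centroid_y = cy,
                          border_flag = on_border))
}

#' Extract per-cell fluorescence records from segmented ROIs
#'
#' For every ROI, the mean pixel intensity is taken in the green channel
#' (the *fourth* of the four green frames, so that the voltage-sensitive
#' fluorophore is read only after complete photoswitching), the red
#' channel and the blue channel. All images must be co-registered and
#' camera-offset subtracted beforehand.
#'
#' @param rois output of [segment_nuclei()]
#' @param green_frames list of exactly 4 matrices (the photoswitching
#'   frame series)
#' @param red,blue single matrices
#' @param dish_id,position_id identifiers propagated into the records
#' @return data.frame of cell records with columns `dish_id`,
#'   `position_id`, `f_green`, `f_red`, `f_blue`, `area_um2`,
#'   `centroid_x`, `centroid_y`, `border_flag`
#' @export
extract_cell_records <- function(rois, green_frames, red, blue,
                                 dish_id = "dish1", position_id = 1L) {
  if (!is.list(green_frames) || length(green_frames) != 4L)
    stop("protocol requires exactly 4 green frames; got ",
         length(green_frames), call. = FALSE)
  lab <- rois$labels
  dims_ok <- vapply(c(green_frames, list(red, blue)), function(img)
    identical(dim(img), dim(lab)), logical(1))
  if (!all(dims_ok))
    stop("all channel images must match the ROI label image in size",
         call. = FALSE)
  tab <- rois$table
  if (nrow(tab) == 0L)
    return(cbind(data.frame(dish_id = character(), position_id = integer(),
                            f_green = numeric(), f_red = numeric(),
                            f_blue = numeric()), tab[, -1, drop = FALSE]))
  sel <- lab > 0
  mean_by_label <- function(img)
    as.numeric(tapply(img[sel], lab[sel], mean))
  data.frame(dish_id = dish_id, position_id = position_id,
             f_green = mean_by_label(green_frames[[4]]),
             f_red = mean_by_label(red),
             f_blue = mean_by_label(blue),
             area_um2 = tab$area_um2,
             centroid_x = tab$centroid_x, centroid_y = tab$centroid_y,
             border_flag = tab$border_flag)
}

# slope of median (f_green - b)/f_red vs f_red over equal-count bins
.ratio_slope <- function(records, b, n_bins = 8) {
  r <- (records$f_green - b) / records$f_red
  qs <- stats::quantile(records$f_red, probs = seq(0, 1, length.out =
                                                     n_bins + 1))
  bin <- findInterval(records$f_red, qs, rightmost.closed = TRUE,
                      all.inside = TRUE)
  med <- tapply(r, bin, stats::median)
  ctr <- tapply(records$f_red, bin, stats::median)
  unname(stats::coef(stats::lm(as.numeric(med) ~ as.numeric(ctr)))[2])
}

#' Adaptive green-channel background estimation
#'
#' Residual autofluorescence of the medium adds a constant to F_green
#' that biases the ratio of weakly expressing cells. The background is
#' estimated as the value `b` whose subtraction removes the dependence
#' of the per-cell ratio on expression level: records are binned by
#' F_red into equal-count bins, the median of (F_green - b)/F_red per
#' bin is regressed linearly on F_red, and `b*` minimizes the squared
#' slope (golden-section search on \[0, 0.9 min(F_green)\]).
#'
#' @param records cell-record data.frame (>= 50 rows recommended)
#' @param n_bins equal-count F_red bins (default 8)
#' @return list with `background` (a.u.), `records` (with corrected
#'   `f_green`), and `slope` (residual slope at the optimum)
#' @export
adaptive_background <- function(records, n_bins = 8) {
  stopifnot(all(c("f_green", "f_red") %in% names(records)))
  if (nrow(records) < 50L)
    stop("adaptive background estimation needs at least 50 records",
         call. = FALSE)
  if (max(records$f_red) / min(records$f_red) < 2)
    warning("F_red spread below 2x: background estimate is unreliable",
            call. = FALSE)
  hi <- 0.9 * min(records$f_green)
  if (hi <= 0)
    stop("non-positive F_green values: cannot bracket the background",
         call. = FALSE)
  opt <- stats::optimize(function(b) .ratio_slope(records, b, n_bins)^2,
                         interval = c(0, hi), tol = 1e-6 * hi)
  if (opt$minimum > hi * (1 - 1e-3) &&
      .ratio_slope(records, hi, n_bins)^2 <
        .ratio_slope(records, 0.99 * hi, n_bins)^2)
    stop("background minimum not bracketed by the search range ",
         "[0, 0.9 min(F_green)]", call. = FALSE)
  records$f_green <- records$f_green - opt$minimum
  list(background = opt$minimum, records = records,
       slope = .ratio_slope(records, 0, n_bins))
}

#' Gate cell records on the red (expression) channel
#'
#' Removes cells with very high F_red (limited camera dynamic range)
#' and cells with low F_red (background-subtraction error is largest in
#' weakly expressing cells). Default thresholds: low = 5th percentile of
#' F_red per dish; high = the 98th percentile overall, or 90% of the
#' camera full scale, whichever is lower.
#'
#' @param records cell-record data.frame
#' @param low,high absolute F_red bounds; when `NULL` the percentile
#'   defaults above apply
#' @param low_percentile,high_percentile percentile defaults
#' @param full_scale camera full scale (a.u.), used to cap `high`
#' @return filtered records; attribute `gating_report` holds the counts
#'   removed per reason
#' @export
gate_records <- function(records, low = NULL, high = NULL,
                         low_percentile = 5, high_percentile = 98,
                         full_scale = NULL) {
  stopifnot("f_red" %in% names(records))
  if (!is.null(low) && !is.null(high) && low >= high)
    stop("lower F_red gate must be below the upper gate", call. = FALSE)
  lo <- if (!is.null(low)) rep(low, nrow(records))
        else stats::ave(records$f_red, records$dish_id, FUN = function(x)
          stats::quantile(x, low_percentile / 100))
  hi_val <- if (!is.null(high)) high
            else stats::quantile(records$f_red, high_percentile / 100)
  if (is.null(high) && !is.null(full_scale))
    hi_val <- min(hi_val, 0.9 * full_scale)
  too_low <- records$f_red < lo
  too_high <- records$f_red > hi_val
  out <- records[!too_low & !too_high, , drop = FALSE]
  attr(out, "gating_report") <- list(removed_low = sum(too_low),
                                     removed_high = sum(too_high),
                                     low = if (!is.null(low)) low else
                                       paste0("p", low_percentile,
                                              " per dish"),
                                     high = unname(hi_val))
  out
}

#' Calibration curve: membrane voltage to fluorescence ratio
#'
#' \deqn{R(V) = R_{max} + \Delta R / (1 + e^{-(V - V_{half})/k_s})}
#' Strictly monotone (decreasing for the negative \eqn{\Delta R} of this
#' sensor class: an increase in R reports hyperpolarization).
#'
#' @param v membrane voltage (mV); vectorized
#' @param std a [calibration_standard()]
#' @return dimensionless ratio R
#' @export
voltage_to_ratio <- function(v, std = restus_calibration()) {
  stopifnot(inherits(std, "calibration_standard"))
  std$r_max + std$delta_r * stats::plogis((v - std$v_half) / std$k_s)
}

#' Inverse calibration: fluorescence ratio to membrane voltage
#'
#' Exact analytic inverse of [voltage_to_ratio()]. Valid ratios lie
#' strictly inside (r_max + delta_r, r_max); out-of-gamut values raise
#' an error unless `clamp = TRUE`, which maps them just inside the
#' gamut edge.
#'
#' @param R dimensionless ratio(s)
#' @param std a [calibration_standard()]
#' @param clamp clamp out-of-gamut ratios instead of erroring
#' @return membrane voltage (mV)
#' @export
ratio_to_voltage <- function(R, std = restus_calibration(),
                             clamp = FALSE) {
  stopifnot(inherits(std, "calibration_standard"))
  lo <- std$r_max + std$delta_r
  hi <- std$r_max
  out_of_gamut <- R <= lo | R >= hi
  if (any(out_of_gamut)) {
    if (!clamp)
      stop(sum(out_of_gamut), " ratio value(s) outside the calibration ",
           "gamut (", signif(lo, 4), ", ", signif(hi, 4), "); use ",
           "clamp = TRUE to map them to the gamut edge", call. = FALSE)
    eps <- 1e-9 * abs(std$delta_r)
    R <- pmin(pmax(R, lo + eps), hi - eps)
  }
  s <- (R - std$r_max) / std$delta_r
  std$v_half + std$k_s * stats::qlogis(s)
}

#' One-point ratio anchor from gramicidin-depolarized dishes
#'
#' Gramicidin clamps cells near 0 mV; the mean of the per-dish median
#' ratios of gramicidin-treated dishes defines the measured 0-mV ratio.
#' The anchor rescales all experimental ratios so that this measured
#' value maps onto `voltage_to_ratio(0, std)`. The default correction is
#' multiplicative (gain-like drift); an additive mode is available.
#'
#' @param dish_medians per-dish median ratios of the gramicidin dishes
#' @param std a [calibration_standard()]
#' @param mode `"scale"` (default) or `"shift"`
#' @return list with `anchor` (mean of dish medians), `mode`, and
#'   `factor` (scale mode) or `offset` (shift mode)
#' @export
gramicidin_anchor <- function(dish_medians, std = restus_calibration(),
                              mode = c("scale", "shift")) {
  mode <- match.arg(mode)
  if (length(dish_medians) < 1L)
    stop("at least one gramicidin dish median is required", call. = FALSE)
  anchor <- mean(dish_medians)
  if (anchor <= 0)
    stop("non-positive gramicidin anchor ratio", call. = FALSE)
  r0 <- voltage_to_ratio(0, std)
  out <- list(anchor = anchor, mode = mode)
  if (mode == "scale") out$factor <- r0 / anchor
  else out$offset <- r0 - anchor
  out
}

# apply an anchor correction to raw ratios
apply_anchor <- function(R, anchor) {
  if (anchor$mode == "scale") R * anchor$factor else R + anchor$offset
}

#' Convert anchored cell records to membrane voltages
#'
#' @param records cell records (background-corrected, gated)
#' @param anchor a [gramicidin_anchor()] result
#' @param std a [calibration_standard()]
#' @param clamp clamp out-of-gamut ratios (default `TRUE`; biological
#'   noise places a few cells outside the sigmoid's range)
#' @return records with added `ratio` and `voltage_mV` columns
#' @export
calibrate_records <- function(records, anchor,
                              std = restus_calibration(), clamp = TRUE) {
  records$ratio <- apply_anchor(records$f_green / records$f_red, anchor)
  records$voltage_mV <- ratio_to_voltage(records$ratio, std,
                                         clamp = clamp)
  records
}

#' Per-dish resting-voltage summaries
#'
#' @param records calibrated cell records with `dish_id` and
#'   `voltage_mV` columns
#' @return data.frame with one row per dish (`dish_id`, `n_cells`,
#'   `median_ratio`, `median_mV`, `mean_mV`, plus `condition` when the
#'   records carry one); attribute `mean_of_medians_mV` holds the
#'   dataset-level mean of the dish medians
#' @export
summarize_dishes <- function(records) {
  stopifnot(all(c("dish_id", "voltage_mV") %in% names(records)))
  sp <- split(records, records$dish_id)
  sp <- sp[vapply(sp, nrow, 1L) > 0]
  out <- do.call(rbind, lapply(sp, function(d) {
    row <- data.frame(dish_id = d$dish_id[1], n_cells = nrow(d),
                      median_ratio = if ("ratio" %in% names(d))
                        stats::median(d$ratio) else NA_real_,
                      median_mV = stats::median(d$voltage_mV),
                      mean_mV = mean(d$voltage_mV))
    if ("condition" %in% names(d)) row$condition <- d$condition[1]
    row
  }))
  rownames(out) <- NULL
  attr(out, "mean_of_medians_mV") <- mean(out$median_mV)
  out
}

#' Full imaging analysis: background, gating, anchoring, voltages
#'
#' Runs the complete per-cell pipeline on a cell-record table: camera
#' offset subtraction, adaptive background correction, F_red gating,
#' gramicidin anchoring, ratio-to-voltage conversion, and per-dish
#' summaries. Gramicidin dishes contribute the 0-mV anchor and are
#' excluded from the reported condition summaries.
#'
#' @param records cell-record data.frame (columns `dish_id`, `f_green`,
#'   `f_red`, optionally `condition`)
#' @param gramicidin_dishes dish_id values of the gramicidin-treated
#'   dishes
#' @param std a [calibration_standard()]
#' @param offset_green,offset_red camera offsets to subtract (default 0)
#' @param anchor_mode `"scale"` or `"shift"`
#' @param gating list of arguments forwarded to [gate_records()]
#' @return list with `records` (calibrated), `summary` (per-dish),
#'   `background` (mean of the per-dish estimates),
#'   `background_per_dish`, `anchor`, `gating_report`
#' @export
analyze_imaging <- function(records, gramicidin_dishes,
                            std = restus_calibration(),
                            offset_green = 0, offset_red = 0,
                            anchor_mode = "scale", gating = list()) {
  stopifnot(all(c("dish_id", "f_green", "f_red") %in% names(records)))
  if (!any(records$dish_id %in% gramicidin_dishes))
    stop("no records found for the gramicidin dishes", call. = FALSE)
  records$f_green <- records$f_green - offset_green
  records$f_red <- records$f_red - offset_red
  # background (medium autofluorescence) is a per-dish property; the
  # dish-wise estimate also keeps each fit's ratio distribution unimodal
  sp <- split(records, records$dish_id)
  bg_per_dish <- vapply(sp, function(d)
    adaptive_background(d)$background, numeric(1))
  records$f_green <- records$f_green -
    bg_per_dish[as.character(records$dish_id)]
  bg <- list(background = mean(bg_per_dish),
             per_dish = bg_per_dish)
  records <- do.call(gate_records, c(list(records), gating))
  report <- attr(records, "gating_report")
  is_gram <- records$dish_id %in% gramicidin_dishes
  gram_medians <- tapply(records$f_green[is_gram] / records$f_red[is_gram],
                         records$dish_id[is_gram], stats::median)
  anchor <- gramicidin_anchor(as.numeric(gram_medians), std,
                              mode = anchor_mode)
  records <- calibrate_records(records, anchor, std)
  list(records = records,
       summary = summarize_dishes(records[!is_gram, , drop = FALSE]),
       background = bg$background, background_per_dish = bg$per_dish,
       anchor = anchor, gating_report = report)
}
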