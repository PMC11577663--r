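#' Detect systolic and diastolic arrows with the flip trick
#'
#' Downward (systolic) and upward (diastolic) arrows are mirror images, so a
#' single one-class arrow detector suffices: it is run on the section as-is
#' for systolic marks and on the vertically flipped section for diastolic
#' marks, whose y-centers are then restored via `y = height - y_flipped`.
#' Both passes go through the tiled detection path and duplicate merging.
#'
#' @param section blood-pressure section image (grayscale matrix).
#' @param detector a one-class arrow detector contract.
#' @param grid a [tile_grid()].
#' @param iou_threshold passed to [merge_duplicates()].
#' @return `list(systolic =, diastolic =)` of box tibbles in section
#'   coordinates.
#' @export
detect_arrows <- function(section, detector, grid = tile_grid(),
                          iou_threshold = 0.4) {
  systolic <- tiled_detect(section, detector, grid, iou_threshold,
                           orientation = "normal")
  flipped <- tiled_detect(flip_vertical(section), detector, grid,
                          iou_threshold, orientation = "flipped")
  flipped$y_center <- nrow(section) - flipped$y_center
  list(systolic = systolic, diastolic = flipped)
}

#' Calibrate the y-to-mmHg map from the legend markers
#'
#' The printed "200" and "30" legend markers anchor a linear interpolation:
#' the vertical span between their box centers covers 170 mmHg, so
#' `mmhg_per_pixel = 170 / (y_30 - y_200)` and
#' `mmHg(y) = 200 - (y - y_200) * mmhg_per_pixel`.
#'
#' @param legend_boxes box tibble containing exactly one box labeled `"200"`
#'   and one labeled `"30"`. A missing or duplicated marker makes the chart
#'   unusable for blood pressure and is an error.
#' @return A list with class `bp_calibration`: `y_200`, `y_30`,
#'   `mmhg_per_pixel`.
#' @export
calibrate <- function(legend_boxes) {
  for (lab in c("200", "30")) {
    n <- sum(legend_boxes$label == lab)
    if (n != 1) {
      stop("legend marker '", lab, "' detected ", n,
           " times (need exactly 1); section unusable for blood pressure",
           call. = FALSE)
    }
  }
  y_200 <- legend_boxes$y_center[legend_boxes$label == "200"]
  y_30 <- legend_boxes$y_center[legend_boxes$label == "30"]
  if (y_30 <= y_200) {
    stop("legend geometry invalid: '30' marker must lie below '200'",
         call. = FALSE)
  }
  structure(
    list(y_200 = y_200, y_30 = y_30,
         mmhg_per_pixel = (200 - 30) / (y_30 - y_200)),
    class = "bp_calibration"
  )
}

#' Convert arrow boxes to mmHg values
#'
#' Values anchor on the box center; the arrow tip offset cancels when the
#' glyph is vertically symmetric about its box, and `tip_offset` (px, positive
#' toward the tip) is available when it is not. Values beyond the printed
#' \[30, 200\] legend span are extrapolated linearly and flagged.
#'
#' @param boxes arrow box tibble.
#' @param cal a [calibrate()] result.
#' @param tip_offset optional px correction added to each y-center.
#' @return The input tibble with columns `mmHg` and `out_of_legend` added.
#' @export
value_of <- function(boxes, cal, tip_offset = 0) {
  y <- boxes$y_center + tip_offset
  boxes$mmHg <- 200 - (y - cal$y_200) * cal$mmhg_per_pixel
  boxes$out_of_legend <- boxes$mmHg > 200 | boxes$mmHg < 30
  boxes
}

#' Timestamp-imputation configuration
#'
#' Pairing and gap bounds as fractions of the section width: systolic and
#' diastolic marks within 1% of the width of one another are taken at the
#' same epoch; consecutive readings more than 1.8% of the width apart are
#' assumed to straddle a missed 5-minute epoch (observed real spacings were
#' all within 1.6% of the width; 1.8% adds error margin), so 10 minutes are
#' applied instead of 5.
#'
#' @param pair_frac systolic/diastolic pairing bound, fraction of width.
#' @param gap_frac missed-epoch bound, fraction of width.
#' @param epoch_minutes nominal epoch length (minutes).
#' @param gap_minutes time applied across a detected gap (minutes).
#' @return A list with class `timestamp_config`.
#' @export
timestamp_config <- function(pair_frac = 0.01, gap_frac = 0.018,
                             epoch_minutes = 5, gap_minutes = 10) {
  if (!(pair_frac > 0 && pair_frac < gap_frac && gap_frac < 1)) {
    stop("need 0 < pair_frac < gap_frac < 1", call. = FALSE)
  }
  structure(list(pair_frac = pair_frac, gap_frac = gap_frac,
                 epoch_minutes = epoch_minutes, gap_minutes = gap_minutes),
            class = "timestamp_config")
}

#' Impute timestamps to blood-pressure detections
#'
#' Sorts both arrow lists by x-center, greedily pairs the globally closest
#' systolic/diastolic pair whose x-distance is within `pair_frac * width`
#' (each box used at most once, ties broken toward the leftmost), leaves
#' unpaired boxes as single-component readings, orders readings by x (a
#' pair's x is the mean of its members), and walks left to right assigning
#' times: the first reading gets t = 0, each later reading advances by
#' `epoch_minutes` if its x-distance to the previous reading is within
#' `gap_frac * width`, else by `gap_minutes`.
#'
#' The series origin is relative — only spacing between readings is
#' inferred, and gaps longer than one missed epoch still advance by
#' `gap_minutes`.
#'
#' @param systolic,diastolic box tibbles with an `mmHg` column (see
#'   [value_of()]); may be empty.
#' @param width section width in pixels.
#' @param cfg a [timestamp_config()].
#' @return A tibble with columns `t_minutes`, `systolic`, `diastolic`
#'   (`NA` for the missing half of an unpaired reading) and `x` (px).
#' @export
assign_timestamps <- function(systolic, diastolic, width,
                              cfg = timestamp_config()) {
  sys <- dplyr::arrange(systolic, .data$x_center)
  dia <- dplyr::arrange(diastolic, .data$x_center)
  n_s <- nrow(sys); n_d <- nrow(dia)
  if (n_s + n_d == 0) {
    return(tibble::tibble(t_minutes = numeric(), systolic = numeric(),
                          diastolic = numeric(), x = numeric()))
  }
  pair_bound <- cfg$pair_frac * width
  pairs <- list()
  used_s <- rep(FALSE, n_s); used_d <- rep(FALSE, n_d)
  if (n_s > 0 && n_d > 0) {
    d <- abs(outer(sys$x_center, dia$x_center, "-"))
    repeat {
      d_open <- d
      d_open[used_s, ] <- Inf
      d_open[, used_d] <- Inf
      m <- min(d_open)
      if (!is.finite(m) || m > pair_bound) break
      # which.min scans column-major: ties resolve to the leftmost systolic
      hit <- which(d_open == m, arr.ind = TRUE)[1, ]
      used_s[hit[1]] <- TRUE
      used_d[hit[2]] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        x = mean(c(sys$x_center[hit[1]], dia$x_center[hit[2]])),
        systolic = sys$mmHg[hit[1]], diastolic = dia$mmHg[hit[2]]
      )
    }
  }
  singles_s <- tibble::tibble(x = sys$x_center[!used_s],
                              systolic = sys$mmHg[!used_s],
                              diastolic = NA_real_)
  singles_d <- tibble::tibble(x = dia$x_center[!used_d],
                              systolic = NA_real_,
                              diastolic = dia$mmHg[!used_d])
  readings <- dplyr::arrange(
    dplyr::bind_rows(dplyr::bind_rows(pairs), singles_s, singles_d),
    .data$x
  )
  gaps <- diff(readings$x)
  dt <- ifelse(gaps <= cfg$gap_frac * width, cfg$epoch_minutes,
               cfg$gap_minutes)
  readings$t_minutes <- cumsum(c(0, dt))
  readings[, c("t_minutes", "systolic", "diastolic", "x")]
}

#' Mean absolute error of matched blood-pressure values
#'
#' The evaluation protocol matches predicted and ground-truth values by hand
#' (timestamps excluded) into equal-length lists before computing the mean
#' absolute difference.
#'
#' @param predicted,truth equal-length numeric vectors of mmHg values.
#' @return The mean absolute error.
#' @export
bp_mae <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length (values are matched ",
         "before scoring)", call. = FALSE)
  }
  mean(abs(predicted - truth))
}
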