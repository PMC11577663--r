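#' Digitize a chart photograph end to end
#'
#' Runs the full pipeline: grayscale conversion, optional shadow removal,
#' landmark detection, optional homography dewarp into the layout's control
#' frame, section cropping, per-section tiled detection, and rule-based
#' inference of the blood-pressure series, physiological rows and checkbox
#' states. One section's failure (missing landmark, unusable legend,
#' checkbox count mismatch) never aborts the others; failures are recorded
#' as warnings in the record's provenance.
#'
#' The two preprocessing toggles (`deshadow`, `homography`) are first-class
#' so their effect on accuracy can be re-measured on synthetic data.
#'
#' @param image grayscale matrix (0-255) or path to a PNG file.
#' @param layout a `chart_layout`.
#' @param detectors named list of detector contracts plus a classifier, as
#'   built by [fixture_detectors()] (or adapters with the same surface):
#'   `landmarks`, `bp_arrows`, `bp_legend`, `physio_digits`, `checkboxes`,
#'   `classifier`.
#' @param deshadow run morphological shadow removal first.
#' @param homography detect landmarks and dewarp into the control frame; if
#'   `FALSE` (or landmark detection fails) sections are cropped at the
#'   layout's nominal positions on the unwarped image.
#' @param grid a [tile_grid()] for small-object detection.
#' @param iou_threshold duplicate-merge threshold.
#' @param ts_cfg a [timestamp_config()].
#' @param seed recorded in provenance and available to stochastic detector
#'   adapters.
#' @param detector_id identifier string recorded in provenance.
#' @return A [digitized_record()].
#' @export
digitize <- function(image, layout, detectors, deshadow = TRUE,
                     homography = TRUE, grid = tile_grid(),
                     iou_threshold = 0.4, ts_cfg = timestamp_config(),
                     seed = 0L, detector_id = "fixture") {
  if (is.character(image)) image <- read_chart_image(image)
  image <- to_grayscale(image)
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)

  if (deshadow) {
    image <- remove_shadows(image)
  }

  used_homography <- FALSE
  if (homography) {
    lm_boxes <- detectors$landmarks$detect(image)
    lms <- landmark_set(lm_boxes$label, lm_boxes$x_center, lm_boxes$y_center)
    if (landmarks_complete(lms)) {
      h <- tryCatch(compute_homography(lms, layout$landmarks),
                    error = function(e) {
                      note(paste("homography failed:", conditionMessage(e)))
                      NULL
                    })
      if (!is.null(h)) {
        image <- warp_to_reference(image, h, layout)
        used_homography <- TRUE
      }
    } else {
      missing <- setdiff(chart_landmark_names(), lms$name)
      note(paste("landmark failure: missing",
                 paste(missing, collapse = ", ")))
    }
  }

  crops <- withCallingHandlers(
    crop_sections(image, layout$sections),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  # --- blood pressure ------------------------------------------------------
  bp <- tryCatch({
    sec <- crops$blood_pressure$image
    arrows <- detect_arrows(sec, detectors$bp_arrows, grid, iou_threshold)
    legend <- detectors$bp_legend$detect(sec)
    cal <- calibrate(legend)
    sys <- value_of(arrows$systolic, cal)
    dia <- value_of(arrows$diastolic, cal)
    if (any(sys$out_of_legend) || any(dia$out_of_legend)) {
      note("blood pressure: value(s) beyond the printed legend span")
    }
    assign_timestamps(sys, dia, ncol(sec), ts_cfg)[,
      c("t_minutes", "systolic", "diastolic")]
  }, error = function(e) {
    note(paste("blood pressure section failed:", conditionMessage(e)))
    NULL
  })

  # --- physiology ----------------------------------------------------------
  physio <- tryCatch({
    sec <- crops$physiology$image
    digits <- tiled_detect(sec, detectors$physio_digits, grid, iou_threshold)
    by_row <- withCallingHandlers(
      assign_rows(digits, layout$physio_rows),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    series <- list()
    for (name in names(by_row)) {
      spec_row <- row_spec(layout, name)
      obs <- cluster_observations(by_row[[name]], spec_row)
      if (name == "tidal_volume") {
        tv_vals <- numeric(); rr_vals <- numeric()
        for (cl in obs) {
          sp <- split_tidal_volume(cl, detectors$classifier)
          if (length(sp$flags) > 0) {
            note(paste0("tidal_volume observation: ",
                        paste(sp$flags, collapse = ", ")))
          }
          tv_vals <- c(tv_vals, sp$tidal_volume)
          rr_vals <- c(rr_vals, sp$respiratory_rate)
        }
        series$tidal_volume <- tv_vals
        series$respiratory_rate <- rr_vals
      } else {
        series[[name]] <- vapply(obs, function(cl) {
          as.numeric(assemble_value(cl, detectors$classifier)$value)
        }, numeric(1))
      }
    }
    out <- list()
    for (name in names(series)) {
      spec_row <- row_spec(layout, name)
      vals <- series[[name]]
      if (length(vals) == 0) next
      flags <- flag_implausible(vals, spec_row)
      imp <- impute(vals, flags, spec_row)
      out[[name]] <- tibble::tibble(row = name,
                                    index = seq_along(imp$values),
                                    value = imp$values, flag = imp$flags)
    }
    dplyr::bind_rows(out)
  }, error = function(e) {
    note(paste("physiology section failed:", conditionMessage(e)))
    NULL
  })

  # --- checkboxes ----------------------------------------------------------
  checkboxes <- tryCatch({
    sec <- crops$checkboxes$image
    dets <- tiled_detect(sec, detectors$checkboxes, grid, iou_threshold)
    assign_checkbox_labels(dets, layout)[, c("label", "checked")]
  }, error = function(e) {
    note(paste("checkbox section failed:", conditionMessage(e)))
    NULL
  })

  digitized_record(
    bp = bp, physio = physio, checkboxes = checkboxes,
    provenance = list(
      deshadow = deshadow,
      homography_requested = homography,
      homography_applied = used_homography,
      seed = as.integer(seed),
      detector = detector_id,
      iou_threshold = iou_threshold,
      tile = c(grid$tile_width, grid$tile_height),
      warnings = warnings
    )
  )
}

#' Score a digitized record against ground truth
#'
#' Computes the evaluation metrics: blood-pressure MAE over value-matched
#' lists (systolic and diastolic matched in temporal order, truncated to
#' the shorter list — timestamps are not scored), per-row physiological MAE
#' with the same truncation rule, and checkbox accuracy/precision/recall/F1.
#' A record whose checkbox section failed the strict count guard is
#' reported `checkbox_skipped = TRUE` and excluded from checkbox metrics.
#'
#' @param record a `digitized_record`.
#' @param truth a `ground_truth` list (from [render_chart()]) or any list
#'   with `bp_truth`, `physio_truth`, `checkbox_truth` of the same shape.
#' @return A list: `bp` (one-row tibble of MAEs and counts), `physio`
#'   (tibble row/mae/n), `checkboxes` (metrics tibble or `NULL`),
#'   `checkbox_skipped`, `n_warnings`.
#' @export
evaluate <- function(record, truth) {
  sys_pred <- record$bp$systolic[!is.na(record$bp$systolic)]
  dia_pred <- record$bp$diastolic[!is.na(record$bp$diastolic)]
  sys_true <- truth$bp_truth$systolic
  dia_true <- truth$bp_truth$diastolic
  n_sys <- min(length(sys_pred), length(sys_true))
  n_dia <- min(length(dia_pred), length(dia_true))
  bp <- tibble::tibble(
    systolic_mae = if (n_sys > 0) {
      bp_mae(sys_pred[seq_len(n_sys)], sys_true[seq_len(n_sys)])
    } else NA_real_,
    diastolic_mae = if (n_dia > 0) {
      bp_mae(dia_pred[seq_len(n_dia)], dia_true[seq_len(n_dia)])
    } else NA_real_,
    n_systolic = n_sys, n_diastolic = n_dia
  )
  physio <- purrr::map_dfr(names(truth$physio_truth), function(name) {
    pred <- record$physio$value[record$physio$row == name]
    tru <- truth$physio_truth[[name]]
    tibble::tibble(
      row = name,
      mae = if (length(pred) > 0 && length(tru) > 0) {
        physio_mae(pred, tru)
      } else NA_real_,
      n = min(length(pred), length(tru))
    )
  })
  checkbox_skipped <- is.null(record$checkboxes)
  checkboxes <- NULL
  if (!checkbox_skipped) {
    truth_tbl <- tibble::tibble(label = names(truth$checkbox_truth),
                                checked = unlist(truth$checkbox_truth))
    checkboxes <- checkbox_metrics(record$checkboxes, truth_tbl)
  }
  list(bp = bp, physio = physio, checkboxes = checkboxes,
       checkbox_skipped = checkbox_skipped,
       n_warnings = length(record$provenance$warnings))
}
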