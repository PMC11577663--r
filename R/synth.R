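# --- deterministic vector glyphs ------------------------------------------
# 5x7 bitmap strokes for digits, the tidal-volume "X", a check mark, the
# arrow glyphs and the landmark mark; scaled by integer factors at render
# time. A built-in glyph set (not handwriting samples) keeps the generator
# fully deterministic and free of downloads.

glyph_bitmaps <- local({
  parse <- function(...) {
    rows <- c(...)
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  }
  g <- list(
    "0" = parse("01110","10001","10011","10101","11001","10001","01110"),
    "1" = parse("00100","01100","00100","00100","00100","00100","01110"),
    "2" = parse("01110","10001","00001","00010","00100","01000","11111"),
    "3" = parse("11111","00010","00100","00010","00001","10001","01110"),
    "4" = parse("00010","00110","01010","10010","11111","00010","00010"),
    "5" = parse("11111","10000","11110","00001","00001","10001","01110"),
    "6" = parse("00110","01000","10000","11110","10001","10001","01110"),
    "7" = parse("11111","00001","00010","00100","01000","01000","01000"),
    "8" = parse("01110","10001","10001","01110","10001","10001","01110"),
    "9" = parse("01110","10001","10001","01111","00001","00010","01100"),
    "x" = parse("10001","10001","01010","00100","01010","10001","10001"),
    check = parse("00001","00001","00010","10010","10100","01100","01000"),
    arrow_down = parse("00100","00100","00100","00100","10101","01110","00100"),
    landmark = parse("11111","10001","11111","10001","11111","10001","11111")
  )
  g$arrow_up <- g$arrow_down[7:1, ]
  g
})

# round half up: parity-stable glyph placement (base round() is half-to-even)
ri <- function(v) floor(v + 0.5)

# stamp a glyph bitmap (scaled) centered at (x, y); returns canvas + box.
# odd-height scaled glyphs center exactly on integer targets.
stamp_glyph <- function(canvas, glyph, x, y, scale = 2, intensity = 0) {
  bm <- glyph_bitmaps[[glyph]]
  big <- bm[rep(seq_len(nrow(bm)), each = scale),
            rep(seq_len(ncol(bm)), each = scale)]
  h <- nrow(big); w <- ncol(big)
  r0 <- ri(y - (h - 1) / 2)
  c0 <- ri(x - (w - 1) / 2)
  rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
  keep_r <- rows >= 1 & rows <= nrow(canvas)
  keep_c <- cols >= 1 & cols <= ncol(canvas)
  sub <- canvas[rows[keep_r], cols[keep_c], drop = FALSE]
  ink <- big[keep_r, keep_c, drop = FALSE] == 1
  sub[ink] <- intensity
  canvas[rows[keep_r], cols[keep_c]] <- sub
  list(canvas = canvas,
       box = new_boxes("glyph", x_center = c0 + (w - 1) / 2,
                       y_center = r0 + (h - 1) / 2, width = w, height = h))
}

draw_hline <- function(canvas, y, x0, x1, intensity = 205) {
  y <- ri(y)
  if (y >= 1 && y <= nrow(canvas)) {
    seg <- canvas[y, ri(x0):ri(x1)]
    canvas[y, ri(x0):ri(x1)] <- pmin(seg, intensity)
  }
  canvas
}

draw_vline <- function(canvas, x, y0, y1, intensity = 205) {
  x <- ri(x)
  if (x >= 1 && x <= ncol(canvas)) {
    seg <- canvas[ri(y0):ri(y1), x]
    canvas[ri(y0):ri(y1), x] <- pmin(seg, intensity)
  }
  canvas
}

draw_rect_outline <- function(canvas, x0, y0, x1, y1, intensity = 120) {
  canvas <- draw_hline(canvas, y0, x0, x1, intensity)
  canvas <- draw_hline(canvas, y1, x0, x1, intensity)
  canvas <- draw_vline(canvas, x0, y0, y1, intensity)
  draw_vline(canvas, x1, y0, y1, intensity)
}

# --- synthetic chart specification ----------------------------------------

#' Specify a synthetic chart
#'
#' Bundles a layout, ground-truth contents and photographic distortion into
#' one seeded, fully deterministic description of a synthetic chart. Missing
#' truth components are generated (seeded) at plausible densities: the
#' default sheet carries 17 blood-pressure epochs and about 35
#' physiological datapoints, mirroring the density used for best-case
#' synthetic evaluation sheets.
#'
#' @param layout a `chart_layout` (default [chuk_layout()]).
#' @param seed integer seed driving all generated content.
#' @param bp_truth tibble `epoch` (0-based, strictly increasing), `systolic`,
#'   `diastolic` (mmHg); `NULL` to generate.
#' @param physio_truth named list, row name -> integer vector, for SpO2,
#'   EtCO2, FiO2, tidal_volume and respiratory_rate (the last two are
#'   written together as "TVxRR"); `NULL` to generate.
#' @param checkbox_truth named logical over the layout's labels; `NULL` to
#'   generate.
#' @param distortion a [distortion_spec()].
#' @return A list with class `synth_spec`.
#' @export
synth_spec <- function(layout = chuk_layout(), seed = 1L, bp_truth = NULL,
                       physio_truth = NULL, checkbox_truth = NULL,
                       distortion = distortion_spec()) {
  seed <- as.integer(seed)
  if (is.null(bp_truth)) bp_truth <- random_bp_truth(seed)
  if (is.null(physio_truth)) physio_truth <- random_physio_truth(seed)
  if (is.null(checkbox_truth)) {
    labels <- unlist(purrr::map(layout$checkbox_columns, "labels"))
    checkbox_truth <- with_seed(seed + 3L, {
      stats::setNames(stats::runif(length(labels)) < 0.5, labels)
    })
  }
  stopifnot(all(diff(bp_truth$epoch) > 0), all(bp_truth$epoch >= 0))
  structure(
    list(layout = layout, seed = seed, bp_truth = bp_truth,
         physio_truth = physio_truth, checkbox_truth = checkbox_truth,
         distortion = distortion),
    class = "synth_spec"
  )
}

random_bp_truth <- function(seed, n_epochs = 17L) {
  with_seed(seed + 1L, {
    # random walk over 5-min epochs; ~15% of steps skip one epoch
    steps <- ifelse(stats::runif(n_epochs - 1) < 0.15, 2L, 1L)
    epochs <- cumsum(c(0L, steps))
    sys <- round(pmin(180, pmax(85, cumsum(c(120, stats::rnorm(n_epochs - 1, 0, 6))))))
    dia <- round(pmin(110, pmax(45, sys - 40 + stats::rnorm(n_epochs, 0, 5))))
    tibble::tibble(epoch = epochs, systolic = as.numeric(sys),
                   diastolic = as.numeric(dia))
  })
}

random_physio_truth <- function(seed) {
  with_seed(seed + 2L, {
    spo2 <- pmin(100, pmax(90, round(98 + cumsum(stats::rnorm(8, 0, 0.8)))))
    etco2 <- pmin(55, pmax(25, round(35 + cumsum(stats::rnorm(8, 0, 1.5)))))
    fio2 <- pmin(100, pmax(30, round(50 + cumsum(stats::rnorm(8, 0, 3)))))
    tv <- pmin(650, pmax(350, round(450 + cumsum(stats::rnorm(5, 0, 15)))))
    rr <- pmin(20, pmax(10, round(12 + cumsum(stats::rnorm(5, 0, 0.8)))))
    list(SpO2 = as.integer(spo2), EtCO2 = as.integer(etco2),
         FiO2 = as.integer(fio2), tidal_volume = as.integer(tv),
         respiratory_rate = as.integer(rr))
  })
}

#' Photographic distortion specification
#'
#' @param corner_shift_frac maximum inward corner displacement as a fraction
#'   of the image diagonal (perspective warp — an off-angle camera leaves
#'   the page a convex quad inside the frame); 0 disables the warp.
#' @param shadow_gradient peak intensity (0-255) of an additive
#'   left-to-right darkening gradient; 0 disables it.
#' @param blur_sigma Gaussian blur sigma in px; 0 disables blur.
#' @return A list with class `distortion_spec`.
#' @export
distortion_spec <- function(corner_shift_frac = 0, shadow_gradient = 0,
                            blur_sigma = 0) {
  stopifnot(corner_shift_frac >= 0, corner_shift_frac < 0.2,
            shadow_gradient >= 0, blur_sigma >= 0)
  structure(list(corner_shift_frac = corner_shift_frac,
                 shadow_gradient = shadow_gradient,
                 blur_sigma = blur_sigma),
            class = "distortion_spec")
}

# section-local render geometry; the blood-pressure grid is 1 mmHg per px
synth_geometry <- function(layout) {
  bp <- layout$sections[layout$sections$name == "blood_pressure", ]
  ph <- layout$sections[layout$sections$name == "physiology", ]
  cb <- layout$sections[layout$sections$name == "checkboxes", ]
  list(
    bp = list(width = bp$width, height = bp$height,
              y_200 = 40, y_30 = 210, epoch_x0 = 70, epoch_dx = 9),
    physio = list(width = ph$width, height = ph$height,
                  x0 = c(SpO2 = 30, EtCO2 = 30, FiO2 = 30, tidal_volume = 30),
                  dx = c(SpO2 = 65, EtCO2 = 65, FiO2 = 65, tidal_volume = 95),
                  digit_pitch = 12, tv_pitch = 11),
    checkbox = list(width = cb$width, height = cb$height,
                    col_x0 = 30, col_dx = 85, row_y0 = 30, row_dy = 60,
                    box_size = 14)
  )
}

#' Render a synthetic chart with exact ground truth
#'
#' Draws a simplified CHUK-style chart in the undistorted reference frame:
#' grid lines, the "200"/"30" legend, arrow glyphs at calibrated mmHg
#' positions (downward = systolic, upward = diastolic), digit glyphs for the
#' physiological rows (tidal volume written "TVxRR"), checkbox squares with
#' check strokes, and the four corner landmark marks. Every rendered glyph
#' yields exactly one ground-truth box, in section-local coordinates
#' (landmarks in chart coordinates). Small seeded positional jitter (about
#' 2 px) on digits emulates handwriting wobble; rendering is deterministic
#' per spec.
#'
#' @param spec a [synth_spec()].
#' @return A `synth_chart`: `list(image =, truth =)`. `truth` carries the
#'   layout, per-section ground-truth boxes, the truth tables of `spec`, and
#'   (after [distort()]) the true homography.
#' @export
render_chart <- function(spec) {
  layout <- spec$layout
  geo <- synth_geometry(layout)
  W <- layout$reference_width; H <- layout$reference_height
  canvas <- matrix(255, H, W)
  truth <- list(layout = layout, spec = spec, homography = NULL,
                landmarks = NULL, bp = NULL, physio = NULL, checkboxes = NULL,
                bp_truth = spec$bp_truth, physio_truth = spec$physio_truth,
                checkbox_truth = spec$checkbox_truth)

  for (i in seq_len(nrow(layout$sections))) {
    s <- layout$sections[i, ]
    canvas <- draw_rect_outline(canvas, s$x, s$y, s$x + s$width,
                                s$y + s$height, 160)
  }

  lm_boxes <- list()
  for (i in seq_len(nrow(layout$landmarks))) {
    lm <- layout$landmarks[i, ]
    st <- stamp_glyph(canvas, "landmark", lm$x, lm$y, scale = 3)
    canvas <- st$canvas
    b <- st$box; b$label <- lm$name
    lm_boxes[[i]] <- b
  }
  truth$landmarks <- dplyr::bind_rows(lm_boxes)

  jit <- local({
    rng <- with_seed(spec$seed + 10L, stats::runif(5000, -2, 2))
    i <- 0L
    function() {
      i <<- i + 1L
      rng[(i - 1L) %% length(rng) + 1L]
    }
  })

  # --- blood pressure section ---------------------------------------------
  bp_sec <- layout$sections[layout$sections$name == "blood_pressure", ]
  off <- c(bp_sec$x, bp_sec$y)
  g <- geo$bp
  for (mmhg in seq(30, 200, by = 10)) {
    canvas <- draw_hline(canvas, off[2] + g$y_200 + (200 - mmhg),
                         off[1] + 60, off[1] + g$width - 5, 225)
  }
  for (e in 0:50) {
    canvas <- draw_vline(canvas, off[1] + g$epoch_x0 + e * g$epoch_dx,
                         off[2] + g$y_200 - 10, off[2] + g$y_30 + 10, 235)
  }
  # legend markers; scale 3 gives odd glyph height so centers land exactly
  legend <- list()
  for (lab in c("200", "30")) {
    digs <- strsplit(lab, "")[[1]]
    y <- if (lab == "200") g$y_200 else g$y_30
    xs <- 12 + (seq_along(digs) - 1) * 18
    boxes <- list()
    for (k in seq_along(digs)) {
      st <- stamp_glyph(canvas, digs[k], off[1] + xs[k], off[2] + y, scale = 3)
      canvas <- st$canvas
      boxes[[k]] <- st$box
    }
    bb <- dplyr::bind_rows(boxes)
    legend[[lab]] <- new_boxes(lab,
                               x_center = mean(range(bb$x_center)) - off[1],
                               y_center = mean(bb$y_center) - off[2],
                               width = diff(range(bb$x_center)) + bb$width[1],
                               height = max(bb$height))
  }
  arrows_s <- list(); arrows_d <- list()
  for (i in seq_len(nrow(spec$bp_truth))) {
    r <- spec$bp_truth[i, ]
    x <- g$epoch_x0 + r$epoch * g$epoch_dx
    for (side in c("systolic", "diastolic")) {
      glyph <- if (side == "systolic") "arrow_down" else "arrow_up"
      v <- r[[side]]
      st <- stamp_glyph(canvas, glyph, off[1] + x,
                        off[2] + g$y_200 + (200 - v), scale = 1)
      canvas <- st$canvas
      b <- st$box; b$label <- "arrow"
      b$x_center <- b$x_center - off[1]; b$y_center <- b$y_center - off[2]
      b$mmHg_true <- v
      if (side == "systolic") {
        arrows_s[[i]] <- b
      } else {
        arrows_d[[i]] <- b
      }
    }
  }
  truth$bp <- list(
    systolic = dplyr::bind_rows(arrows_s),
    diastolic = dplyr::bind_rows(arrows_d),
    legend = dplyr::bind_rows(legend),
    y_200 = g$y_200, y_30 = g$y_30
  )

  # --- physiology section --------------------------------------------------
  ph_sec <- layout$sections[layout$sections$name == "physiology", ]
  off <- c(ph_sec$x, ph_sec$y)
  gp <- geo$physio
  rows <- layout$physio_rows
  digit_boxes <- list()
  add_digit <- function(ch, x, y, row, obs, is_x = FALSE) {
    st <- stamp_glyph(canvas, ch, off[1] + x + jit(), off[2] + y + jit(),
                      scale = 2)
    canvas <<- st$canvas
    b <- st$box
    b$label <- "digit"
    b$x_center <- b$x_center - off[1]; b$y_center <- b$y_center - off[2]
    b$digit <- if (is_x) NA_integer_ else as.integer(ch)
    b$is_x <- is_x
    b$row <- row; b$obs <- obs
    digit_boxes[[length(digit_boxes) + 1L]] <<- b
  }
  for (name in c("SpO2", "EtCO2", "FiO2")) {
    r <- rows[rows$name == name, ]
    y_mid <- (r$y_min + r$y_max) / 2
    vals <- spec$physio_truth[[name]]
    for (j in seq_along(vals)) {
      digs <- strsplit(as.character(vals[j]), "")[[1]]
      x0 <- gp$x0[[name]] + (j - 1) * gp$dx[[name]]
      for (k in seq_along(digs)) {
        add_digit(digs[k], x0 + (k - 1) * gp$digit_pitch, y_mid, name, j)
      }
    }
  }
  tv_row <- rows[rows$name == "tidal_volume", ]
  y_mid <- (tv_row$y_min + tv_row$y_max) / 2
  tvs <- spec$physio_truth$tidal_volume
  rrs <- spec$physio_truth$respiratory_rate
  for (j in seq_along(tvs)) {
    glyphs <- c(strsplit(as.character(tvs[j]), "")[[1]], "x",
                strsplit(as.character(rrs[j]), "")[[1]])
    x0 <- gp$x0[["tidal_volume"]] + (j - 1) * gp$dx[["tidal_volume"]]
    for (k in seq_along(glyphs)) {
      add_digit(glyphs[k], x0 + (k - 1) * gp$tv_pitch, y_mid,
                "tidal_volume", j, is_x = glyphs[k] == "x")
    }
  }
  truth$physio <- dplyr::bind_rows(digit_boxes)

  # --- checkbox section ----------------------------------------------------
  cb_sec <- layout$sections[layout$sections$name == "checkboxes", ]
  off <- c(cb_sec$x, cb_sec$y)
  gc <- geo$checkbox
  cb_boxes <- list()
  for (ci in seq_along(layout$checkbox_columns)) {
    col <- layout$checkbox_columns[[ci]]
    x <- gc$col_x0 + (ci - 1) * gc$col_dx
    for (rj in seq_along(col$labels)) {
      y <- gc$row_y0 + (rj - 1) * gc$row_dy
      half <- gc$box_size / 2
      canvas <- draw_rect_outline(canvas, off[1] + x - half, off[2] + y - half,
                                  off[1] + x + half, off[2] + y + half, 100)
      checked <- isTRUE(spec$checkbox_truth[[col$labels[rj]]])
      if (checked) {
        st <- stamp_glyph(canvas, "check", off[1] + x, off[2] + y, scale = 2)
        canvas <- st$canvas
      }
      cb_boxes[[length(cb_boxes) + 1L]] <- tibble::tibble(
        label = if (checked) "checked" else "unchecked",
        x_center = x + jit() / 2, y_center = y + jit() / 2,
        width = gc$box_size + 6, height = gc$box_size + 6,
        score = 1,
        true_label = col$labels[rj]
      )
    }
  }
  truth$checkboxes <- dplyr::bind_rows(cb_boxes)

  structure(list(image = canvas, truth = truth), class = "synth_chart")
}

#' Apply photographic distortion to a rendered chart
#'
#' Applies a perspective warp (seeded inward corner displacements, so the
#' page stays a convex quad inside the frame), an additive left-to-right
#' illumination gradient, and optional Gaussian blur. The exact
#' reference-to-photo homography is recorded in the returned truth so
#' registration can be tested against it.
#'
#' @param chart a `synth_chart` from [render_chart()].
#' @param distortion a [distortion_spec()]; defaults to the one in the
#'   chart's spec.
#' @param seed seed for the corner displacements; defaults to the spec seed.
#' @return A `synth_chart` whose `image` is the distorted photo and whose
#'   `truth$homography` maps reference coordinates to photo coordinates.
#' @export
distort <- function(chart, distortion = NULL, seed = NULL) {
  spec <- chart$truth$spec
  if (is.null(distortion)) distortion <- spec$distortion
  if (is.null(seed)) seed <- spec$seed
  layout <- chart$truth$layout
  W <- layout$reference_width; H <- layout$reference_height
  img <- chart$image
  truth <- chart$truth
  if (distortion$corner_shift_frac > 0) {
    diag_len <- sqrt(W^2 + H^2)
    shift <- distortion$corner_shift_frac * diag_len
    corners <- landmark_set(c("tl", "tr", "br", "bl"),
                            c(1, W, W, 1), c(1, 1, H, H))
    moved <- with_seed(seed + 20L, {
      m <- corners
      inward_x <- c(1, -1, -1, 1)   # push each corner toward the interior
      inward_y <- c(1, 1, -1, -1)
      m$x <- m$x + inward_x * stats::runif(4, 0, shift)
      m$y <- m$y + inward_y * stats::runif(4, 0, shift)
      m
    })
    if (!is_convex_quad(moved$x, moved$y)) {
      stop("corner displacements produce a non-convex quadrilateral",
           call. = FALSE)
    }
    h <- compute_homography(corners, moved)
    img <- warp_image(img, h, W, H)
    truth$homography <- h
  }
  if (distortion$shadow_gradient > 0) {
    ramp <- matrix(rep(seq(0, distortion$shadow_gradient,
                           length.out = ncol(img)),
                       each = nrow(img)), nrow(img), ncol(img))
    img <- clamp255(img - ramp)
  }
  if (distortion$blur_sigma > 0) {
    img <- t(EBImage::imageData(
      EBImage::gblur(EBImage::Image(t(img) / 255), distortion$blur_sigma)
    )) * 255
  }
  structure(list(image = img, truth = truth), class = "synth_chart")
}

is_convex_quad <- function(x, y) {
  cross <- numeric(4)
  for (i in 1:4) {
    j <- i %% 4 + 1; k <- j %% 4 + 1
    cross[i] <- (x[j] - x[i]) * (y[k] - y[j]) - (y[j] - y[i]) * (x[k] - x[j])
  }
  all(cross > 0) || all(cross < 0)
}

#' Map reference-frame ground truth into the photo frame
#'
#' Pushes every ground-truth box through the recorded reference-to-photo
#' homography, yielding the truth a pixel-based detector would report on the
#' distorted photograph (section-local coordinates keep the layout's section
#' origins, which is where an uncorrected pipeline crops). Box sizes scale
#' with the local magnification. Identity if the chart was never warped.
#'
#' @param truth a `ground_truth` list with a recorded homography.
#' @return A truth list of the same shape in photo-frame coordinates.
#' @export
as_photo_frame <- function(truth) {
  h <- truth$homography
  if (is.null(h)) return(truth)
  layout <- truth$layout
  sec_offset <- function(name) {
    s <- layout$sections[layout$sections$name == name, ]
    c(s$x, s$y)
  }
  map_boxes <- function(boxes, offset = c(0, 0)) {
    if (is.null(boxes) || nrow(boxes) == 0) return(boxes)
    mapped <- apply_homography(h, tibble::tibble(
      x = boxes$x_center + offset[1], y = boxes$y_center + offset[2]))
    p1 <- apply_homography(h, tibble::tibble(
      x = boxes$x_center + offset[1] - boxes$width / 2,
      y = boxes$y_center + offset[2] - boxes$height / 2))
    p2 <- apply_homography(h, tibble::tibble(
      x = boxes$x_center + offset[1] + boxes$width / 2,
      y = boxes$y_center + offset[2] + boxes$height / 2))
    boxes$x_center <- mapped$x - offset[1]
    boxes$y_center <- mapped$y - offset[2]
    boxes$width <- pmax(1e-6, abs(p2$x - p1$x))
    boxes$height <- pmax(1e-6, abs(p2$y - p1$y))
    boxes
  }
  out <- truth
  out$landmarks <- map_boxes(truth$landmarks)
  out$bp$systolic <- map_boxes(truth$bp$systolic, sec_offset("blood_pressure"))
  out$bp$diastolic <- map_boxes(truth$bp$diastolic,
                                sec_offset("blood_pressure"))
  out$bp$legend <- map_boxes(truth$bp$legend, sec_offset("blood_pressure"))
  out$physio <- map_boxes(truth$physio, sec_offset("physiology"))
  out$checkboxes <- map_boxes(truth$checkboxes, sec_offset("checkboxes"))
  out
}

#' Build the pipeline's fixture detectors and classifier from ground truth
#'
#' @param truth a `ground_truth` list (reference frame, or [as_photo_frame()]
#'   output for runs without perspective correction).
#' @param noise a [fixture_noise()] applied to every detector.
#' @param landmark_truth optional box tibble overriding the landmark ground
#'   truth. Landmarks are detected on the raw photograph while the section
#'   detectors run on the dewarped image, so a homography-on run against a
#'   distorted chart pairs reference-frame section truth with
#'   `as_photo_frame(truth)$landmarks` here.
#' @return A named list of detector contracts (`landmarks`, `bp_arrows`,
#'   `bp_legend`, `physio_digits`, `checkboxes`) plus `classifier`.
#' @export
fixture_detectors <- function(truth, noise = fixture_noise(),
                              landmark_truth = NULL) {
  if (is.null(landmark_truth)) landmark_truth <- truth$landmarks
  bp_sec <- truth$layout$sections[
    truth$layout$sections$name == "blood_pressure", ]
  cols <- c("label", "x_center", "y_center", "width", "height", "score")
  list(
    landmarks = fixture_detector(landmark_truth[cols], noise),
    bp_arrows = fixture_detector(truth$bp$systolic[cols], noise,
                                 flipped_truth = truth$bp$diastolic[cols],
                                 frame_height = bp_sec$height),
    bp_legend = fixture_detector(truth$bp$legend[cols], noise),
    physio_digits = fixture_detector(truth$physio[cols], noise),
    checkboxes = fixture_detector(truth$checkboxes[cols], noise),
    classifier = fixture_classifier(truth$physio, noise)
  )
}

#' Export detection fixtures and truth as JSON
#'
#' Writes one detection-fixture JSON per section (the shared schema: a list
#' of `label`, `x_center`, `y_center`, `width`, `height`, `score` records,
#' seeded noise applied on export) plus a `truth.json` with the true values
#' for scoring. Repeated calls with identical inputs produce byte-identical
#' files.
#'
#' @param truth a `ground_truth` list.
#' @param noise a [fixture_noise()].
#' @param path output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
export_fixtures <- function(truth, noise = fixture_noise(), path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cols <- c("label", "x_center", "y_center", "width", "height", "score")
  apply_noise <- function(boxes) {
    det <- fixture_detector(boxes[cols], noise)
    det$detect(NULL, window = c(0, 0, 1e6, 1e6))
  }
  sets <- list(
    landmarks = truth$landmarks,
    bp_systolic = truth$bp$systolic,
    bp_diastolic = truth$bp$diastolic,
    bp_legend = truth$bp$legend,
    physio_digits = truth$physio,
    checkboxes = truth$checkboxes
  )
  files <- character()
  for (nm in names(sets)) {
    f <- file.path(path, paste0(nm, ".json"))
    out <- apply_noise(sets[[nm]])
    jsonlite::write_json(as.data.frame(out[cols]), f, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  # classifier fixture: digit boxes with their true labels and X flags
  cf <- file.path(path, "classifier.json")
  jsonlite::write_json(
    as.data.frame(truth$physio[c(cols, "digit", "is_x")]),
    cf, digits = NA, pretty = TRUE
  )
  tf <- file.path(path, "truth.json")
  jsonlite::write_json(
    list(bp = as.data.frame(truth$bp_truth),
         physio = truth$physio_truth,
         checkboxes = as.list(truth$checkbox_truth)),
    tf, digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(files, cf, tf))
}

#' Rebuild pipeline detectors from an exported fixture directory
#'
#' Reads the JSON files written by [export_fixtures()] and assembles the
#' detector/classifier set [digitize()] expects.
#'
#' @param dir fixture directory.
#' @param layout the matching `chart_layout` (supplies the blood-pressure
#'   section height for the flip pass).
#' @return A named list as from [fixture_detectors()].
#' @export
fixture_detectors_from_dir <- function(dir, layout) {
  f <- function(name) read_fixture_boxes(file.path(dir, paste0(name, ".json")))
  bp_sec <- layout$sections[layout$sections$name == "blood_pressure", ]
  clf_raw <- jsonlite::read_json(file.path(dir, "classifier.json"),
                                 simplifyVector = TRUE)
  clf_tbl <- if (length(clf_raw) == 0 || is.null(clf_raw$label)) {
    tibble::tibble(label = character(), x_center = numeric(),
                   y_center = numeric(), width = numeric(),
                   height = numeric(), score = numeric(),
                   digit = integer(), is_x = logical())
  } else {
    out <- tibble::as_tibble(clf_raw)
    out$digit <- as.integer(out$digit)
    out$is_x <- as.logical(out$is_x)
    out
  }
  list(
    landmarks = fixture_detector(f("landmarks")),
    bp_arrows = fixture_detector(f("bp_systolic"),
                                 flipped_truth = f("bp_diastolic"),
                                 frame_height = bp_sec$height),
    bp_legend = fixture_detector(f("bp_legend")),
    physio_digits = fixture_detector(f("physio_digits")),
    checkboxes = fixture_detector(f("checkboxes")),
    classifier = fixture_classifier(clf_tbl)
  )
}

#' Read an exported truth JSON
#' @param path path to a `truth.json` written by [export_fixtures()].
#' @return A list with `bp_truth`, `physio_truth`, `checkbox_truth` suitable
#'   for [evaluate()].
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    bp_truth = tibble::as_tibble(raw$bp),
    physio_truth = lapply(raw$physio, as.numeric),
    checkbox_truth = unlist(raw$checkboxes)
  )
}

#' Read a detection-fixture JSON into a box tibble
#' @param path fixture file path.
#' @return A box tibble.
#' @export
read_fixture_boxes <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0 || is.null(df$label)) return(new_boxes())
  new_boxes(df$label, df$x_center, df$y_center, df$width, df$height, df$score)
}
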