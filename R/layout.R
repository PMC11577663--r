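#' Chart layout objects
#'
#' A `chart_layout` captures everything the pipeline needs to know about one
#' hospital's chart design: the control-frame dimensions, the four corner
#' landmark coordinates, the section rectangles, the approximate positions of
#' the "200"/"30" blood-pressure legend markers, the physiological row bands
#' with their plausible-value ranges, and the checkbox column schema. Layout
#' is configuration, not code: a different hospital's chart needs only a new
#' YAML file.
#'
#' @param path path to a layout YAML file.
#' @return A list with class `chart_layout`; components `reference_width`,
#'   `reference_height`, `landmarks` (tibble `name`, `x`, `y`), `sections`
#'   (tibble `name`, `x`, `y`, `width`, `height`), `bp_legend` (box tibble
#'   labeled `"200"`/`"30"` in blood-pressure-section coordinates),
#'   `physio_rows` (tibble of row specs), `checkbox_columns` (list of
#'   `name`/`labels`), `expected_checkbox_count`.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  raw <- fix_yaml_keys(yaml::read_yaml(path))
  layout_from_list(raw)
}

# YAML 1.1 reads a bare key `y` as boolean TRUE; restore it recursively
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x))) names(x)[names(x) == "TRUE"] <- "y"
  lapply(x, fix_yaml_keys)
}

layout_from_list <- function(raw) {
  need <- c("reference_width", "reference_height", "landmarks", "sections",
            "physio_rows", "checkbox_columns", "expected_checkbox_count")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("layout is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  landmarks <- landmark_set(
    names(raw$landmarks),
    unname(vapply(raw$landmarks, function(p) p$x, numeric(1))),
    unname(vapply(raw$landmarks, function(p) p$y, numeric(1)))
  )
  sections <- tibble::tibble(
    name = names(raw$sections),
    x = unname(vapply(raw$sections, function(s) as.numeric(s$x), numeric(1))),
    y = unname(vapply(raw$sections, function(s) as.numeric(s$y), numeric(1))),
    width = unname(vapply(raw$sections, function(s) as.numeric(s$width), numeric(1))),
    height = unname(vapply(raw$sections, function(s) as.numeric(s$height), numeric(1)))
  )
  bp_legend <- if (is.null(raw$bp_legend)) {
    new_boxes()
  } else {
    new_boxes(
      label = names(raw$bp_legend),
      x_center = unname(vapply(raw$bp_legend, function(b) as.numeric(b$x), numeric(1))),
      y_center = unname(vapply(raw$bp_legend, function(b) as.numeric(b$y), numeric(1))),
      width = unname(vapply(raw$bp_legend, function(b) as.numeric(b$width), numeric(1))),
      height = unname(vapply(raw$bp_legend, function(b) as.numeric(b$height), numeric(1)))
    )
  }
  physio_rows <- dplyr::bind_rows(purrr::map(raw$physio_rows, function(r) {
    tibble::tibble(
      name = r$name,
      y_min = as.numeric(r$y_band[[1]]), y_max = as.numeric(r$y_band[[2]]),
      lo = as.numeric(r$value_range[[1]]), hi = as.numeric(r$value_range[[2]]),
      d_min = as.integer(r$digit_count_range[[1]]),
      d_max = as.integer(r$digit_count_range[[2]]),
      max_step = as.numeric(r$max_step)
    )
  }))
  checkbox_columns <- purrr::map(raw$checkbox_columns, function(col) {
    list(name = col$name, labels = as.character(col$labels))
  })
  layout <- structure(
    list(
      reference_width = as.integer(raw$reference_width),
      reference_height = as.integer(raw$reference_height),
      landmarks = landmarks,
      sections = sections,
      bp_legend = bp_legend,
      physio_rows = physio_rows,
      checkbox_columns = checkbox_columns,
      expected_checkbox_count = as.integer(raw$expected_checkbox_count)
    ),
    class = "chart_layout"
  )
  validate_layout(layout)
}

#' @rdname load_layout
#' @param layout a `chart_layout` object.
#' @export
validate_layout <- function(layout) {
  with(layout, {
    if (reference_width < 1 || reference_height < 1) {
      stop("layout error in reference dimensions: must be positive",
           call. = FALSE)
    }
    bad <- sections$x < 0 | sections$y < 0 |
      sections$x + sections$width > reference_width |
      sections$y + sections$height > reference_height
    if (any(bad)) {
      stop("layout error in sections: '",
           paste(sections$name[bad], collapse = "', '"),
           "' extend outside the reference frame", call. = FALSE)
    }
    if (any(physio_rows$y_min >= physio_rows$y_max)) {
      stop("layout error in physio_rows: y_band must have y_min < y_max",
           call. = FALSE)
    }
    if (any(physio_rows$lo > physio_rows$hi)) {
      stop("layout error in physio_rows: value_range must have lo <= hi",
           call. = FALSE)
    }
    if (any(physio_rows$d_min < 1 | physio_rows$d_min > physio_rows$d_max)) {
      stop("layout error in physio_rows: digit_count_range needs ",
           "1 <= d_min <= d_max", call. = FALSE)
    }
    if (any(physio_rows$max_step <= 0)) {
      stop("layout error in physio_rows: max_step must be positive",
           call. = FALSE)
    }
    n <- nrow(physio_rows)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (physio_rows$y_min[i] <= physio_rows$y_max[j] &&
              physio_rows$y_min[j] <= physio_rows$y_max[i]) {
            stop("layout error: physio row y-bands of '",
                 physio_rows$name[i], "' and '", physio_rows$name[j],
                 "' overlap", call. = FALSE)
          }
        }
      }
    }
    labels <- unlist(purrr::map(checkbox_columns, "labels"))
    if (anyDuplicated(labels)) {
      stop("layout error: duplicated checkbox label(s): ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "),
           call. = FALSE)
    }
    if (length(labels) != expected_checkbox_count) {
      stop("layout error in expected_checkbox_count: schema has ",
           length(labels), " labels but expected_checkbox_count is ",
           expected_checkbox_count, call. = FALSE)
    }
  })
  layout
}

#' @rdname load_layout
#' @export
write_layout <- function(layout, path) {
  raw <- list(
    reference_width = layout$reference_width,
    reference_height = layout$reference_height,
    landmarks = stats::setNames(
      purrr::map2(layout$landmarks$x, layout$landmarks$y,
                  function(x, y) list(x = x, y = y)),
      layout$landmarks$name
    ),
    sections = stats::setNames(
      purrr::pmap(layout$sections[, c("x", "y", "width", "height")], list),
      layout$sections$name
    ),
    bp_legend = stats::setNames(
      purrr::pmap(
        list(layout$bp_legend$x_center, layout$bp_legend$y_center,
             layout$bp_legend$width, layout$bp_legend$height),
        function(x, y, width, height) list(x = x, y = y, width = width,
                                           height = height)
      ),
      layout$bp_legend$label
    ),
    physio_rows = purrr::pmap(layout$physio_rows, function(name, y_min, y_max,
                                                           lo, hi, d_min,
                                                           d_max, max_step) {
      list(name = name, y_band = c(y_min, y_max), value_range = c(lo, hi),
           digit_count_range = c(d_min, d_max), max_step = max_step)
    }),
    checkbox_columns = layout$checkbox_columns,
    expected_checkbox_count = layout$expected_checkbox_count
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' The bundled CHUK-style reference layout
#'
#' Loads the example layout shipped with the package: a 1000x700 px control
#' frame with the four corner landmarks, seven sections, a blood-pressure
#' grid calibrated at 1 mmHg per pixel, five physiological rows, and a
#' 16-checkbox four-column schema. The real chart's pixel geometry is not
#' published, so this layout is a plausible stand-in with the same structure.
#'
#' @return A `chart_layout`.
#' @export
chuk_layout <- function() {
  load_layout(system.file("extdata", "chuk_layout.yaml",
                          package = "chartdigitizer", mustWork = TRUE))
}

#' Look up one physiological row spec by name
#' @param layout a `chart_layout`.
#' @param name row name, e.g. `"SpO2"`.
#' @return The matching one-row slice of `layout$physio_rows`.
#' @export
row_spec <- function(layout, name) {
  r <- layout$physio_rows[layout$physio_rows$name == name, ]
  if (nrow(r) == 0) stop("unknown physio row: ", name, call. = FALSE)
  r
}
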