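#' Digitized-record objects
#'
#' The JSON-serializable result of digitizing one chart: the blood-pressure
#' series, the physiological series with per-value flags, the checkbox map,
#' and provenance (preprocessing toggles, seeds, detector identifier,
#' warnings).
#'
#' @param bp tibble `t_minutes`, `systolic`, `diastolic`.
#' @param physio tibble `row`, `index`, `value`, `flag`.
#' @param checkboxes tibble `label`, `checked`, or `NULL` when the checkbox
#'   section failed its count guard.
#' @param provenance named list of scalars/strings.
#' @return A list with class `digitized_record`.
#' @export
digitized_record <- function(bp = NULL, physio = NULL, checkboxes = NULL,
                             provenance = list()) {
  bp_cols <- c("t_minutes", "systolic", "diastolic")
  bp <- if (is.null(bp) || !all(bp_cols %in% names(bp))) {
    tibble::tibble(t_minutes = numeric(), systolic = numeric(),
                   diastolic = numeric())
  } else {
    tibble::as_tibble(bp)[, bp_cols]
  }
  ph_cols <- c("row", "index", "value", "flag")
  physio <- if (is.null(physio) || !all(ph_cols %in% names(physio))) {
    tibble::tibble(row = character(), index = numeric(),
                   value = numeric(), flag = character())
  } else {
    tibble::as_tibble(physio)[, ph_cols]
  }
  if (!is.null(checkboxes)) {
    checkboxes <- tibble::as_tibble(checkboxes)[, c("label", "checked")]
  }
  structure(list(bp = bp, physio = physio, checkboxes = checkboxes,
                 provenance = provenance),
            class = "digitized_record")
}

#' Write / read a digitized record as JSON
#'
#' Keys are written in a stable order (`bp_series`, `physio`, `checkboxes`,
#' `provenance`); reading the file back yields an equal record.
#'
#' @param record a `digitized_record`.
#' @param path output path.
#' @return `write_record()` invisibly returns `path`; `read_record()`
#'   returns a `digitized_record`.
#' @export
write_record <- function(record, path) {
  payload <- list(
    bp_series = as.data.frame(record$bp),
    physio = as.data.frame(record$physio),
    checkboxes = if (is.null(record$checkboxes)) NULL
                 else as.data.frame(record$checkboxes),
    provenance = record$provenance
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(df, template) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0) ||
        length(df) == 0) {
      return(template)
    }
    out <- tibble::as_tibble(df)
    for (nm in names(template)) {
      if (!nm %in% names(out)) out[[nm]] <- template[[nm]][0]
      mode_fun <- if (is.character(template[[nm]])) as.character
                  else if (is.logical(template[[nm]])) as.logical
                  else as.numeric
      out[[nm]] <- mode_fun(out[[nm]])
    }
    out[, names(template)]
  }
  bp_template <- tibble::tibble(t_minutes = numeric(), systolic = numeric(),
                                diastolic = numeric())
  ph_template <- tibble::tibble(row = character(), index = numeric(),
                                value = numeric(), flag = character())
  cb_template <- tibble::tibble(label = character(), checked = logical())
  checkboxes <- if (is.null(raw$checkboxes)) NULL
                else as_tbl(raw$checkboxes, cb_template)
  digitized_record(
    bp = as_tbl(raw$bp_series, bp_template),
    physio = as_tbl(raw$physio, ph_template),
    checkboxes = checkboxes,
    provenance = raw$provenance
  )
}

#' @export
print.digitized_record <- function(x, ...) {
  cat("<digitized_record>\n")
  cat("  blood pressure: ", nrow(x$bp), " reading(s)\n", sep = "")
  cat("  physiology:     ", nrow(x$physio), " value(s) in ",
      length(unique(x$physio$row)), " row(s)\n", sep = "")
  if (is.null(x$checkboxes)) {
    cat("  checkboxes:     failed count guard\n")
  } else {
    cat("  checkboxes:     ", sum(x$checkboxes$checked), "/",
        nrow(x$checkboxes), " checked\n", sep = "")
  }
  n_warn <- length(x$provenance$warnings)
  if (n_warn > 0) cat("  warnings:       ", n_warn, "\n", sep = "")
  invisible(x)
}

#' Tidy a digitized record into one long tibble
#'
#' @param x a `digitized_record`.
#' @param ... unused.
#' @return A tibble `section`, `item`, `index`, `value`, `flag` covering
#'   every extracted quantity.
#' @export
tidy.digitized_record <- function(x, ...) {
  bp_long <- dplyr::bind_rows(
    tibble::tibble(section = "blood_pressure", item = "systolic",
                   index = x$bp$t_minutes, value = x$bp$systolic,
                   flag = "observed"),
    tibble::tibble(section = "blood_pressure", item = "diastolic",
                   index = x$bp$t_minutes, value = x$bp$diastolic,
                   flag = "observed")
  )
  ph_long <- tibble::tibble(section = "physiology", item = x$physio$row,
                            index = x$physio$index, value = x$physio$value,
                            flag = x$physio$flag)
  cb_long <- if (is.null(x$checkboxes)) {
    tibble::tibble(section = character(), item = character(),
                   index = numeric(), value = numeric(), flag = character())
  } else {
    tibble::tibble(section = "checkboxes", item = x$checkboxes$label,
                   index = seq_len(nrow(x$checkboxes)),
                   value = as.numeric(x$checkboxes$checked),
                   flag = "observed")
  }
  dplyr::bind_rows(bp_long, ph_long, cb_long)
}

#' One-row summary of a digitized record
#'
#' @param x a `digitized_record`.
#' @param ... unused.
#' @return A one-row tibble with counts of readings, values, flagged and
#'   imputed entries, checked boxes and recorded warnings.
#' @export
glance.digitized_record <- function(x, ...) {
  tibble::tibble(
    n_bp_readings = nrow(x$bp),
    n_bp_complete = sum(!is.na(x$bp$systolic) & !is.na(x$bp$diastolic)),
    n_physio_values = nrow(x$physio),
    n_flagged = sum(x$physio$flag %in%
                      c("implausible_range", "implausible_step")),
    n_imputed = sum(x$physio$flag == "imputed"),
    n_checkboxes = if (is.null(x$checkboxes)) NA_integer_
                   else nrow(x$checkboxes),
    n_checked = if (is.null(x$checkboxes)) NA_integer_
                else sum(x$checkboxes$checked),
    n_warnings = length(x$provenance$warnings)
  )
}

#' Plot the blood-pressure series of a digitized record
#'
#' @param object a `digitized_record`.
#' @param ... unused.
#' @return A ggplot of systolic/diastolic mmHg against minutes.
#' @export
autoplot.digitized_record <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$section == "blood_pressure" & !is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$item)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "time (min)", y = "blood pressure (mmHg)",
                  colour = NULL)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
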