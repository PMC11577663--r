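#' Detection box tibbles
#'
#' Every detection in the package is an axis-aligned box in continuous pixel
#' coordinates (origin top-left, x rightward, y downward), stored center+size
#' in a tibble with columns `label`, `x_center`, `y_center`, `width`,
#' `height`, `score`. `new_boxes()` builds and validates such a tibble;
#' `validate_boxes()` checks an existing one.
#'
#' @param label character class name per box.
#' @param x_center,y_center box center in pixels.
#' @param width,height box size in pixels; must be strictly positive.
#' @param score detection confidence in \[0, 1\].
#' @return A tibble with the six box columns, one row per detection.
#' @examples
#' new_boxes("arrow", x_center = 10, y_center = 20, width = 5, height = 7)
#' @export
new_boxes <- function(label = character(), x_center = numeric(),
                      y_center = numeric(), width = numeric(),
                      height = numeric(), score = numeric()) {
  # the coordinate vectors set the box count; label/size/score recycle
  n <- max(length(x_center), length(y_center))
  if (n > 0 && length(score) == 0) score <- 1
  if (n > 0 && length(label) == 0) label <- "object"
  if (n == 0) {
    label <- character(); x_center <- y_center <- numeric()
    width <- height <- score <- numeric()
  }
  out <- tibble::tibble(
    label = rep_len(as.character(label), n),
    x_center = rep_len(as.numeric(x_center), n),
    y_center = rep_len(as.numeric(y_center), n),
    width = rep_len(as.numeric(width), n),
    height = rep_len(as.numeric(height), n),
    score = rep_len(as.numeric(score), n)
  )
  validate_boxes(out)
}

#' @rdname new_boxes
#' @param boxes a tibble of boxes as produced by `new_boxes()`.
#' @export
validate_boxes <- function(boxes) {
  cols <- c("label", "x_center", "y_center", "width", "height", "score")
  missing <- setdiff(cols, names(boxes))
  if (length(missing) > 0) {
    stop("box tibble is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- boxes[c("x_center", "y_center", "width", "height", "score")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop("box coordinates, sizes and scores must all be finite", call. = FALSE)
  }
  if (any(boxes$width <= 0) || any(boxes$height <= 0)) {
    stop("box width and height must be strictly positive", call. = FALSE)
  }
  if (any(boxes$score < 0 | boxes$score > 1)) {
    stop("box scores must lie in [0, 1]", call. = FALSE)
  }
  boxes
}

# corner representation used internally: xmin/xmax/ymin/ymax
box_corners <- function(boxes) {
  tibble::tibble(
    xmin = boxes$x_center - boxes$width / 2,
    xmax = boxes$x_center + boxes$width / 2,
    ymin = boxes$y_center - boxes$height / 2,
    ymax = boxes$y_center + boxes$height / 2
  )
}

#' Plot detection boxes over an optional image
#'
#' @param boxes a box tibble (see [new_boxes()]).
#' @param image optional grayscale matrix (0-255) drawn under the boxes.
#' @return A ggplot object; y is reversed so the plot matches image
#'   coordinates (origin top-left).
#' @export
plot_boxes <- function(boxes, image = NULL) {
  corners <- dplyr::bind_cols(boxes, box_corners(boxes))
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    df <- tibble::tibble(
      x = rep(seq_len(ncol(image)), each = nrow(image)),
      y = rep(seq_len(nrow(image)), times = ncol(image)),
      value = as.vector(image)
    )
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)
    ) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, 255), guide = "none")
  }
  p +
    ggplot2::geom_rect(
      data = corners,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$label),
      fill = NA, linewidth = 0.4
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL)
}
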