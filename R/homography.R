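#' Landmark sets
#'
#' The four control landmarks printed in the corners of the chart ("Total",
#' "Time", "Procedure Details", "Patient Position") anchor the perspective
#' correction. A landmark set is a tibble with columns `name`, `x`, `y`; the
#' correspondence point of a detected landmark is its box center.
#'
#' @param name character vector of landmark names.
#' @param x,y landmark coordinates in pixels.
#' @return A tibble with columns `name`, `x`, `y`.
#' @export
landmark_set <- function(name, x, y) {
  pts <- tibble::tibble(name = as.character(name),
                        x = as.numeric(x), y = as.numeric(y))
  if (anyDuplicated(pts$name)) {
    stop("duplicated landmark name(s): ",
         paste(unique(pts$name[duplicated(pts$name)]), collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(pts[, c("x", "y")]))
  diag(d) <- Inf
  if (nrow(pts) > 1 && min(d) < 1e-9) {
    stop("two landmarks coincide", call. = FALSE)
  }
  pts
}

#' The canonical corner-landmark names
#' @return Character vector of the four landmark names.
#' @export
chart_landmark_names <- function() {
  c("Total", "Time", "Procedure Details", "Patient Position")
}

#' Check that a landmark set contains all four corner landmarks
#'
#' @param landmarks a landmark tibble.
#' @param error if `TRUE`, raise an error naming the missing landmark(s) —
#'   the observed real-world failure modes are landmarks obscured by writing,
#'   covered by other paper, or out of frame.
#' @return `TRUE`/`FALSE` (invisibly `TRUE` when `error = TRUE` and complete).
#' @export
landmarks_complete <- function(landmarks, error = FALSE) {
  missing <- setdiff(chart_landmark_names(), landmarks$name)
  if (length(missing) == 0) return(TRUE)
  if (error) {
    stop("incomplete landmark set; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  FALSE
}

#' Compute the exact four-point planar homography
#'
#' Solves the direct linear transform for the 3x3 projective matrix H mapping
#' each source point onto the destination point with the same name. Exactly
#' four correspondences are required; no estimation or outlier handling is
#' done — with four named landmarks there is nothing to vote over, and a
#' degenerate configuration is surfaced as an error rather than estimated
#' around.
#'
#' @param src,dst landmark tibbles (see [landmark_set()]) sharing the same
#'   four names.
#' @return A 3x3 matrix with bottom-right entry 1, class `homography`.
#' @examples
#' sq <- landmark_set(paste0("p", 1:4), c(0, 1, 1, 0), c(0, 0, 1, 1))
#' compute_homography(sq, sq)  # identity
#' @export
compute_homography <- function(src, dst) {
  if (nrow(src) != 4 || nrow(dst) != 4) {
    stop("exactly four landmark correspondences are required", call. = FALSE)
  }
  missing <- setdiff(src$name, dst$name)
  if (length(missing) > 0) {
    stop("destination set is missing landmark(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dst <- dst[match(src$name, dst$name), ]
  check_not_collinear(src, "source")
  check_not_collinear(dst, "destination")
  x <- src$x; y <- src$y; u <- dst$x; v <- dst$y
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    A[2 * i - 1, ] <- c(x[i], y[i], 1, 0, 0, 0, -u[i] * x[i], -u[i] * y[i])
    A[2 * i, ] <- c(0, 0, 0, x[i], y[i], 1, -v[i] * x[i], -v[i] * y[i])
    b[2 * i - 1] <- u[i]
    b[2 * i] <- v[i]
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate landmark configuration: ", conditionMessage(e),
         call. = FALSE)
  })
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12) {
    stop("computed homography is singular", call. = FALSE)
  }
  structure(H, class = c("homography", "matrix", "array"))
}

check_not_collinear <- function(pts, which) {
  combs <- utils::combn(nrow(pts), 3)
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    area <- abs(
      (pts$x[i[2]] - pts$x[i[1]]) * (pts$y[i[3]] - pts$y[i[1]]) -
        (pts$x[i[3]] - pts$x[i[1]]) * (pts$y[i[2]] - pts$y[i[1]])
    ) / 2
    if (area < 1e-9) {
      stop("three ", which, " landmarks are collinear (",
           paste(pts$name[i], collapse = ", "), ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Apply a homography to points
#'
#' @param h a 3x3 homography matrix.
#' @param points a tibble/data frame with columns `x`, `y` (extra columns are
#'   preserved).
#' @return The input with `x`, `y` replaced by their images under `h`.
#' @export
apply_homography <- function(h, points) {
  p <- rbind(points$x, points$y, 1)
  q <- unclass(h) %*% p
  points$x <- q[1, ] / q[3, ]
  points$y <- q[2, ] / q[3, ]
  points
}

#' Invert a homography
#' @param h a homography matrix.
#' @return The inverse, normalized so the bottom-right entry is 1.
#' @export
invert_homography <- function(h) {
  inv <- solve(unclass(h))
  inv <- inv / inv[3, 3]
  structure(inv, class = c("homography", "matrix", "array"))
}

#' Warp an image through a homography
#'
#' `warp_image()` maps input-image coordinates to output coordinates through
#' `h` and resamples bilinearly (each output pixel looks up its pre-image
#' under the inverse map). Pixels that fall outside the source fill white
#' (255, blank paper). `warp_to_reference()` is the pipeline entry point: it
#' warps a photograph into the control frame defined by a chart layout.
#'
#' @param image grayscale matrix.
#' @param h homography mapping input coordinates to output coordinates.
#' @param width,height output dimensions in pixels.
#' @param fill intensity used outside the source image.
#' @return A height-by-width matrix.
#' @export
warp_image <- function(image, h, width, height, fill = 255) {
  hinv <- solve(unclass(h))
  xs <- rep(seq_len(width), each = height)
  ys <- rep(seq_len(height), times = width)
  denom <- hinv[3, 1] * xs + hinv[3, 2] * ys + hinv[3, 3]
  sx <- (hinv[1, 1] * xs + hinv[1, 2] * ys + hinv[1, 3]) / denom
  sy <- (hinv[2, 1] * xs + hinv[2, 2] * ys + hinv[2, 3]) / denom
  out <- bilinear_sample(image, sx, sy, fill)
  matrix(out, nrow = height, ncol = width)
}

bilinear_sample <- function(image, sx, sy, fill) {
  H <- nrow(image); W <- ncol(image)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  # clamp the four taps so edge pixels interpolate against themselves
  cx0 <- pmin(pmax(x0, 1), W); cx1 <- pmin(pmax(x0 + 1, 1), W)
  cy0 <- pmin(pmax(y0, 1), H); cy1 <- pmin(pmax(y0 + 1, 1), H)
  idx <- function(r, c) image[cbind(r, c)]
  v <- (1 - fx) * (1 - fy) * idx(cy0, cx0) +
    fx * (1 - fy) * idx(cy0, cx1) +
    (1 - fx) * fy * idx(cy1, cx0) +
    fx * fy * idx(cy1, cx1)
  v[!inside] <- fill
  v
}

#' @rdname warp_image
#' @param layout a `chart_layout`; supplies the reference dimensions.
#' @export
warp_to_reference <- function(image, h, layout) {
  warp_image(image, h, layout$reference_width, layout$reference_height)
}

#' Crop named sections out of a chart image
#'
#' Each crop carries its integer pixel offset (`x`, `y` of its top-left
#' corner, 0-based) so detections made inside the crop can be lifted back
#' into the chart frame. Boxes extending past the image edge are clipped,
#' with a warning recorded in the returned object.
#'
#' @param image grayscale matrix in the chart frame.
#' @param sections a tibble with columns `name`, `x`, `y`, `width`, `height`
#'   (top-left corner + size), e.g. `layout$sections`.
#' @return A named list of `list(image =, offset = c(x, y), clipped =)`.
#' @export
crop_sections <- function(image, sections) {
  out <- list()
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    x0 <- max(0L, as.integer(floor(s$x)))
    y0 <- max(0L, as.integer(floor(s$y)))
    x1 <- as.integer(ceiling(s$x + s$width))
    y1 <- as.integer(ceiling(s$y + s$height))
    clipped <- x1 > ncol(image) || y1 > nrow(image) || s$x < 0 || s$y < 0
    x1 <- min(x1, ncol(image))
    y1 <- min(y1, nrow(image))
    if (clipped) {
      warning("section '", s$name, "' extends past the image edge; clipped",
              call. = FALSE)
    }
    out[[s$name]] <- list(
      image = image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE],
      offset = c(x = x0, y = y0),
      clipped = clipped
    )
  }
  out
}
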