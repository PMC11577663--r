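#' Half-stride tile grids
#'
#' Tiling divides a section into overlapping sub-images so small handwritten
#' symbols occupy a useful fraction of each detector input. The window slides
#' by half its width/height each step, so any object no larger than the
#' stride that sits on the edge of one tile is near the center of the next;
#' the final row/column is clamped to the image edge so coverage is complete
#' and every tile pixel is a real image pixel.
#'
#' @param tile_width,tile_height tile size in pixels.
#' @return A list with class `tile_grid` (tile size plus the implied
#'   half-strides).
#' @export
tile_grid <- function(tile_width = 128L, tile_height = 128L) {
  tile_width <- as.integer(tile_width)
  tile_height <- as.integer(tile_height)
  if (tile_width < 2L || tile_height < 2L) {
    stop("tile dimensions must be at least 2 px", call. = FALSE)
  }
  structure(
    list(tile_width = tile_width, tile_height = tile_height,
         stride_x = tile_width %/% 2L, stride_y = tile_height %/% 2L),
    class = "tile_grid"
  )
}

tile_offsets_1d <- function(extent, tile, stride) {
  if (tile >= extent) return(0L)
  last <- extent - tile
  offs <- seq(0L, last, by = stride)
  if (offs[length(offs)] < last) offs <- c(offs, last)
  as.integer(offs)
}

#' Cut an image into half-stride tiles
#'
#' @param image grayscale matrix.
#' @param grid a [tile_grid()].
#' @return A list of `list(image =, offset = c(x, y))`, offsets 0-based. If
#'   the tile exceeds the image in either dimension, a single whole-image
#'   tile is returned with a warning.
#' @export
make_tiles <- function(image, grid) {
  if (grid$tile_width > ncol(image) || grid$tile_height > nrow(image)) {
    warning("tile larger than image; using a single whole-image tile",
            call. = FALSE)
    return(list(list(image = image, offset = c(x = 0L, y = 0L))))
  }
  xs <- tile_offsets_1d(ncol(image), grid$tile_width, grid$stride_x)
  ys <- tile_offsets_1d(nrow(image), grid$tile_height, grid$stride_y)
  out <- vector("list", length(xs) * length(ys))
  k <- 1L
  for (y0 in ys) {
    for (x0 in xs) {
      out[[k]] <- list(
        image = image[(y0 + 1):(y0 + grid$tile_height),
                      (x0 + 1):(x0 + grid$tile_width), drop = FALSE],
        offset = c(x = x0, y = y0)
      )
      k <- k + 1L
    }
  }
  out
}

#' Lift tile-local detections into section coordinates
#'
#' @param per_tile a list of `list(boxes =, offset = c(x, y))` with boxes in
#'   tile-local coordinates.
#' @return One box tibble in section coordinates; scores and labels
#'   preserved.
#' @export
lift_detections <- function(per_tile) {
  lifted <- purrr::map(per_tile, function(t) {
    b <- t$boxes
    if (is.null(b) || nrow(b) == 0) return(NULL)
    b$x_center <- b$x_center + t$offset[["x"]]
    b$y_center <- b$y_center + t$offset[["y"]]
    b
  })
  out <- dplyr::bind_rows(lifted)
  if (nrow(out) == 0) new_boxes() else out
}

#' Intersection over union of axis-aligned boxes
#'
#' @param a,b box tibbles of equal length (or length 1, recycled).
#' @return Numeric vector of IoU values in \[0, 1\]; disjoint boxes give 0.
#' @examples
#' b1 <- new_boxes("x", 0, 0, 2, 2)
#' b2 <- new_boxes("x", 1, 0, 2, 2)
#' iou(b1, b2)  # 1/3
#' @export
iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ca <- box_corners(a); cb <- box_corners(b)
  ix <- pmax(0, pmin(ca$xmax, cb$xmax) - pmax(ca$xmin, cb$xmin))
  iy <- pmax(0, pmin(ca$ymax, cb$ymax) - pmax(ca$ymin, cb$ymin))
  inter <- ix * iy
  union <- a$width * a$height + b$width * b$height - inter
  rep_len(inter / union, n)
}

iou_matrix <- function(boxes) {
  n <- nrow(boxes)
  c1 <- box_corners(boxes)
  ix <- pmax(0, outer(c1$xmax, c1$xmax, pmin) - outer(c1$xmin, c1$xmin, pmax))
  iy <- pmax(0, outer(c1$ymax, c1$ymax, pmin) - outer(c1$ymin, c1$ymin, pmax))
  inter <- ix * iy
  area <- boxes$width * boxes$height
  inter / (outer(area, area, "+") - inter)
}

#' Merge duplicated detections from overlapping tiles
#'
#' Because adjacent tiles overlap by half their size, most objects are
#' detected twice. Same-label boxes whose IoU exceeds `iou_threshold` are
#' linked, connected components of that graph are found with union-find, and
#' each component is replaced by one box: the score-weighted mean of centers
#' and sizes (or the max-score member, with `method = "max_score"`), with
#' score equal to the component maximum. Output is ordered by `x_center`,
#' then `y_center`, so results are deterministic.
#'
#' @param boxes a box tibble in one shared coordinate frame.
#' @param iou_threshold IoU above which two same-label boxes are considered
#'   the same physical object; strictly between 0 and 1. The handwritten
#'   symbols on the chart are well separated and never overlap, so any
#'   moderate value distinguishes true neighbors from self-duplicates.
#' @param method how to combine a component into one box.
#' @return A box tibble with one row per physical object.
#' @export
merge_duplicates <- function(boxes, iou_threshold = 0.4,
                             method = c("weighted_mean", "max_score")) {
  method <- match.arg(method)
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must be strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(boxes)
  if (n <= 1) {
    return(dplyr::arrange(boxes, .data$x_center, .data$y_center))
  }
  M <- iou_matrix(boxes)
  same <- outer(boxes$label, boxes$label, "==")
  adj <- M > iou_threshold & same
  comp <- union_find_components(adj)
  merged <- purrr::map(split(seq_len(n), comp), function(i) {
    b <- boxes[i, ]
    if (method == "max_score" || nrow(b) == 1) {
      out <- b[which.max(b$score), ]
      out$score <- max(b$score)
      return(out)
    }
    w <- b$score / sum(b$score)
    tibble::tibble(
      label = b$label[1],
      x_center = sum(w * b$x_center), y_center = sum(w * b$y_center),
      width = sum(w * b$width), height = sum(w * b$height),
      score = max(b$score)
    )
  })
  dplyr::arrange(dplyr::bind_rows(merged), .data$x_center, .data$y_center)
}

# union-find over an adjacency matrix; returns component id per node
union_find_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Run a detector over tiles and merge the results
#'
#' The standard small-object detection path: tile the image with a
#' half-stride sliding window, query the detector on every tile, lift the
#' tile-local boxes back to section coordinates, and merge duplicates.
#'
#' @param image section image (grayscale matrix).
#' @param detector a detector contract object (see [fixture_detector()]).
#' @param grid a [tile_grid()].
#' @param iou_threshold passed to [merge_duplicates()].
#' @param orientation `"normal"` or `"flipped"`; forwarded to the detector so
#'   orientation-aware fixtures can answer flipped-pass queries.
#' @return A merged box tibble in section coordinates.
#' @export
tiled_detect <- function(image, detector, grid = tile_grid(),
                         iou_threshold = 0.4, orientation = "normal") {
  tiles <- suppressWarnings(make_tiles(image, grid))
  per_tile <- purrr::map(tiles, function(t) {
    win <- c(t$offset[["x"]], t$offset[["y"]],
             ncol(t$image), nrow(t$image))
    list(boxes = detector$detect(t$image, window = win,
                                 orientation = orientation),
         offset = t$offset)
  })
  merge_duplicates(lift_detections(per_tile), iou_threshold)
}
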