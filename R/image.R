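#' Grayscale chart images
#'
#' Images are plain numeric matrices with `nrow = height`, `ncol = width`,
#' intensities in \[0, 255\] (0 = ink, 255 = paper). `read_chart_image()`
#' decodes a PNG file into this representation; `to_grayscale()` collapses a
#' color array with the usual luminance weights.
#'
#' @param path path to a PNG file.
#' @return A numeric height-by-width matrix with values in \[0, 255\].
#' @export
read_chart_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  arr <- png::readPNG(path)
  to_grayscale(arr * 255)
}

#' @rdname read_chart_image
#' @param image either a height-by-width matrix (already gray) or a
#'   height-by-width-by-channel array (RGB or RGBA) with values in \[0, 255\].
#' @export
to_grayscale <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  if (is.matrix(image)) {
    return(clamp255(image))
  }
  if (length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc == 1) return(clamp255(image[, , 1]))
    # ITU-R BT.601 luminance weights; alpha channel ignored
    g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    return(clamp255(g))
  }
  stop("image must be a matrix or a height x width x channel array",
       call. = FALSE)
}

clamp255 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

#' Write a grayscale matrix to PNG
#'
#' @param image height-by-width matrix, values in \[0, 255\].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_chart_image <- function(image, path) {
  png::writePNG(clamp255(image) / 255, path)
  invisible(path)
}

#' Min-max intensity normalization
#'
#' Rescales intensities linearly so the darkest pixel maps to 0 and the
#' brightest to 255. A constant image maps to all-255 (blank paper); this
#' degenerate case avoids a divide by zero and matches the convention that
#' featureless regions are background.
#'
#' @param image grayscale matrix (0-255).
#' @return Matrix of the same dimensions spanning \[0, 255\].
#' @export
normalize_intensity <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  rng <- range(image)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    image[] <- 255
    return(image)
  }
  (image - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Shadow-removal parameters
#'
#' Kernel sizes for the morphological shadow-removal recipe. Both must be odd
#' and at least 3, with the median-blur kernel at least as large as the
#' dilation kernel so the background estimate is smooth at the scale of the
#' dilated strokes. Defaults are calibrated for a ~1000 px wide working image
#' and scale linearly with width via `scale_shadow_params()`.
#'
#' @param dilate_kernel odd integer, side of the square dilation kernel (px).
#' @param blur_kernel odd integer, side of the median-blur window (px).
#' @return A list with class `shadow_params`.
#' @export
shadow_params <- function(dilate_kernel = 7L, blur_kernel = 21L) {
  dilate_kernel <- as.integer(dilate_kernel)
  blur_kernel <- as.integer(blur_kernel)
  if (dilate_kernel < 3L || dilate_kernel %% 2L == 0L) {
    stop("dilate_kernel must be an odd integer >= 3", call. = FALSE)
  }
  if (blur_kernel < 3L || blur_kernel %% 2L == 0L) {
    stop("blur_kernel must be an odd integer >= 3", call. = FALSE)
  }
  if (blur_kernel < dilate_kernel) {
    stop("blur_kernel must be >= dilate_kernel", call. = FALSE)
  }
  structure(list(dilate_kernel = dilate_kernel, blur_kernel = blur_kernel),
            class = "shadow_params")
}

#' @rdname shadow_params
#' @param width image width the kernels should be rescaled for.
#' @param reference_width width at which the defaults were calibrated.
#' @export
scale_shadow_params <- function(width, reference_width = 1000) {
  odd <- function(k) {
    k <- max(3L, as.integer(round(k)))
    if (k %% 2L == 0L) k + 1L else k
  }
  f <- width / reference_width
  shadow_params(odd(7 * f), odd(21 * f))
}

#' Morphological shadow removal
#'
#' Estimates the illumination background of a grayscale document image by
#' grayscale dilation (which erases thin dark ink strokes) followed by a
#' median blur, then takes the absolute pixel-wise difference between the
#' original and the background. The difference is inverted so ink is dark on
#' a light page, and min-max normalized to \[0, 255\]. Shadows and smooth
#' lighting gradients live in the background estimate and cancel in the
#' difference; ink strokes survive.
#'
#' @param image grayscale matrix (0-255), strictly larger than `blur_kernel`
#'   in both dimensions.
#' @param params a [shadow_params()] object; `NULL` scales the defaults to
#'   the image width.
#' @param invert if `TRUE` (default) return dark-ink-on-white; if `FALSE`
#'   return the raw normalized difference (ink bright on dark).
#' @return Matrix of the same dimensions, values in \[0, 255\].
#' @export
remove_shadows <- function(image, params = NULL, invert = TRUE) {
  if (is.null(params)) params <- scale_shadow_params(ncol(image))
  if (nrow(image) <= params$blur_kernel || ncol(image) <= params$blur_kernel) {
    stop("image must be larger than blur_kernel in both dimensions",
         call. = FALSE)
  }
  # EBImage stores images width-first; transpose in and out
  img <- EBImage::Image(t(image) / 255)
  bg <- EBImage::dilate(img, EBImage::makeBrush(params$dilate_kernel, "box"))
  bg <- EBImage::medianFilter(bg, (params$blur_kernel - 1L) / 2L)
  diff <- abs(t(EBImage::imageData(img) - EBImage::imageData(bg))) * 255
  out <- if (invert) 255 - diff else diff
  normalize_intensity(out)
}

#' Flip an image upside down
#'
#' Used by the blood-pressure flip trick: a detector trained on downward
#' arrows finds upward (diastolic) arrows on the flipped image.
#'
#' @param image grayscale matrix.
#' @return The vertically mirrored matrix.
#' @export
flip_vertical <- function(image) {
  image[rev(seq_len(nrow(image))), , drop = FALSE]
}
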