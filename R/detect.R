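#' Fixture noise model
#'
#' Describes the error modes of a detector/classifier fixture: Gaussian
#' jitter on box centers, independent false-negative drops, spurious
#' false-positive boxes, and a row-stochastic 10x10 digit confusion matrix.
#' All randomness is derived from `seed`, so a fixture with the same noise
#' model returns byte-identical output on every query.
#'
#' @param jitter_sigma standard deviation (px) of center jitter.
#' @param false_negative_rate,false_positive_rate probabilities in \[0, 1\].
#'   False positives are drawn per ground-truth box, so their expected count
#'   scales with object density.
#' @param digit_confusion 10x10 row-stochastic matrix; entry (i, j) is the
#'   probability that true digit i-1 is read as j-1.
#' @param seed integer RNG seed.
#' @return A list with class `fixture_noise`.
#' @export
fixture_noise <- function(jitter_sigma = 0, false_negative_rate = 0,
                          false_positive_rate = 0,
                          digit_confusion = diag(10), seed = 1L) {
  stopifnot(jitter_sigma >= 0)
  if (false_negative_rate < 0 || false_negative_rate > 1 ||
      false_positive_rate < 0 || false_positive_rate > 1) {
    stop("false negative/positive rates must lie in [0, 1]", call. = FALSE)
  }
  digit_confusion <- as.matrix(digit_confusion)
  if (!all(dim(digit_confusion) == c(10, 10)) ||
      any(digit_confusion < 0) ||
      any(abs(rowSums(digit_confusion) - 1) > 1e-8)) {
    stop("digit_confusion must be a 10x10 row-stochastic matrix",
         call. = FALSE)
  }
  structure(
    list(jitter_sigma = jitter_sigma,
         false_negative_rate = false_negative_rate,
         false_positive_rate = false_positive_rate,
         digit_confusion = digit_confusion,
         seed = as.integer(seed)),
    class = "fixture_noise"
  )
}

noise_is_null <- function(noise) {
  noise$jitter_sigma == 0 && noise$false_negative_rate == 0 &&
    noise$false_positive_rate == 0
}

# deterministic per-query seed: mixes the fixture seed with the query window
# and orientation so different tiles see different (but reproducible) noise
query_seed <- function(seed, window, orientation) {
  mix <- sum(c(31, 17, 7, 3) * window) + 7919 * (orientation == "flipped")
  as.integer((abs(seed) * 2654435 + mix) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic fixture detector
#'
#' Builds a detector contract object from ground-truth boxes. Queries return
#' the ground-truth boxes that fall inside the queried window (translated to
#' window-local coordinates), minus seeded false-negative drops, plus seeded
#' false-positive boxes, with Gaussian center jitter. Identical fixture and
#' query always yield identical output.
#'
#' The contract surface is `detect(image, window = NULL, orientation =
#' "normal")` returning a box tibble in query-local coordinates. `window`
#' gives the query's origin and size `c(x0, y0, w, h)` in the fixture's
#' frame (used by the tiling path); `orientation = "flipped"` answers the
#' blood-pressure flip pass. A pixel-based adapter would ignore both and
#' read the image; the fixture is pixels-blind and uses them instead.
#'
#' @param ground_truth box tibble in the fixture's (section) frame.
#' @param noise a [fixture_noise()].
#' @param flipped_truth optional box tibble answering flipped-orientation
#'   queries (e.g. upward arrows that a downward-arrow detector sees on the
#'   flipped image); its boxes are reported at `y' = frame_height - y`.
#' @param frame_height section height in px, required with `flipped_truth`.
#' @return A list with class `detector_contract`: `class_names` and
#'   `detect(image, window, orientation)`.
#' @export
fixture_detector <- function(ground_truth, noise = fixture_noise(),
                             flipped_truth = NULL, frame_height = NULL) {
  validate_boxes(ground_truth)
  if (!is.null(flipped_truth) && is.null(frame_height)) {
    stop("frame_height is required when flipped_truth is given",
         call. = FALSE)
  }
  class_names <- unique(c(ground_truth$label,
                          if (!is.null(flipped_truth)) flipped_truth$label))
  detect <- function(image, window = NULL, orientation = "normal") {
    truth <- if (orientation == "flipped") {
      if (is.null(flipped_truth)) {
        new_boxes()
      } else {
        ft <- flipped_truth
        ft$y_center <- frame_height - ft$y_center
        ft
      }
    } else {
      ground_truth
    }
    if (is.null(window)) {
      window <- c(0, 0,
                  if (!is.null(image)) ncol(image) else Inf,
                  if (!is.null(image)) nrow(image) else Inf)
    }
    corners <- box_corners(truth)
    inside <- corners$xmin >= window[1] & corners$xmax <= window[1] + window[3] &
      corners$ymin >= window[2] & corners$ymax <= window[2] + window[4]
    out <- truth[inside, ]
    out$x_center <- out$x_center - window[1]
    out$y_center <- out$y_center - window[2]
    if (!noise_is_null(noise) && nrow(out) > 0) {
      out <- with_seed(query_seed(noise$seed, window, orientation), {
        keep <- stats::runif(nrow(out)) >= noise$false_negative_rate
        kept <- out[keep, ]
        if (noise$jitter_sigma > 0 && nrow(kept) > 0) {
          kept$x_center <- kept$x_center +
            stats::rnorm(nrow(kept), 0, noise$jitter_sigma)
          kept$y_center <- kept$y_center +
            stats::rnorm(nrow(kept), 0, noise$jitter_sigma)
        }
        n_fp <- stats::rbinom(1, nrow(out), noise$false_positive_rate)
        if (n_fp > 0) {
          fp <- new_boxes(
            label = sample(class_names, n_fp, replace = TRUE),
            x_center = stats::runif(n_fp, 0, window[3]),
            y_center = stats::runif(n_fp, 0, window[4]),
            width = sample(out$width, n_fp, replace = TRUE),
            height = sample(out$height, n_fp, replace = TRUE),
            score = stats::runif(n_fp, 0.3, 0.7)
          )
          kept <- dplyr::bind_rows(kept, fp)
        }
        kept
      })
    }
    out
  }
  structure(list(class_names = class_names, detect = detect),
            class = "detector_contract")
}

#' Deterministic fixture digit classifier
#'
#' Builds a digit-classifier contract object keyed by position: a query box
#' is matched to the nearest ground-truth digit box (within `match_tol` px of
#' center distance) and the label is sampled from that digit's row of the
#' confusion matrix. With the identity confusion matrix the classifier is
#' perfect. `x_mark()` reports whether the matched ground-truth glyph is the
#' "X" separator of the tidal-volume row.
#'
#' The contract surface is `classify(crop, box)` returning
#' `list(digit, confidence)` and `x_mark(crop, box)` returning a logical. A
#' pixel-based adapter would use `crop`; the fixture uses `box` (the query
#' box in the fixture's frame).
#'
#' @param ground_truth a tibble of digit boxes with columns of [new_boxes()]
#'   plus `digit` (0-9, `NA` for non-digit glyphs) and `is_x` (logical).
#' @param noise a [fixture_noise()]; only `digit_confusion` and `seed` are
#'   used.
#' @param match_tol maximum center distance (px) for matching a query to a
#'   ground-truth glyph.
#' @return A list with class `classifier_contract`.
#' @export
fixture_classifier <- function(ground_truth, noise = fixture_noise(),
                               match_tol = 6) {
  if (!all(c("digit", "is_x") %in% names(ground_truth))) {
    stop("classifier ground truth needs `digit` and `is_x` columns",
         call. = FALSE)
  }
  match_truth <- function(box) {
    if (nrow(ground_truth) == 0) return(NULL)
    d <- sqrt((ground_truth$x_center - box$x_center)^2 +
                (ground_truth$y_center - box$y_center)^2)
    i <- which.min(d)
    if (d[i] > match_tol) return(NULL)
    ground_truth[i, ]
  }
  identity_confusion <- all(noise$digit_confusion == diag(10))
  classify <- function(crop = NULL, box) {
    gt <- match_truth(box)
    if (is.null(gt) || is.na(gt$digit)) {
      return(list(digit = NA_integer_, confidence = 0))
    }
    true_digit <- as.integer(gt$digit)
    if (identity_confusion) {
      return(list(digit = true_digit, confidence = 1))
    }
    probs <- noise$digit_confusion[true_digit + 1L, ]
    seed <- query_seed(noise$seed,
                       c(box$x_center, box$y_center, box$width, box$height),
                       "normal")
    digit <- with_seed(seed, sample(0:9, 1, prob = probs))
    list(digit = as.integer(digit),
         confidence = probs[digit + 1L])
  }
  x_mark <- function(crop = NULL, box) {
    gt <- match_truth(box)
    !is.null(gt) && isTRUE(gt$is_x)
  }
  structure(list(classify = classify, x_mark = x_mark),
            class = "classifier_contract")
}
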