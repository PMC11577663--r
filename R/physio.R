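#' Exact 1-D k-means
#'
#' In one dimension the optimal k-means clusters are contiguous in sorted
#' order, so the global optimum is found by dynamic programming over
#' split points (O(k n^2) with prefix sums) — deterministic, no random
#' initialization. Used for both the row assignment (y-centers) and
#' observation clustering (x-centers).
#'
#' @param x numeric vector.
#' @param k number of clusters; must not exceed the number of distinct
#'   values.
#' @return `list(cluster =, centers =)` with integer cluster ids ordered so
#'   centers increase.
#' @keywords internal
kmeans_1d <- function(x, k) {
  n <- length(x)
  if (k > length(unique(x))) {
    stop("k exceeds number of distinct values", call. = FALSE)
  }
  if (k == 1) {
    return(list(cluster = rep(1L, n), centers = mean(x)))
  }
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # within-cluster sum of squares of xs[i..j]
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; arg <- m
        for (i in m:j) {
          c_ <- cost[m - 1, i - 1] + sse(i, j)
          if (c_ < best) {
            best <- c_; arg <- i
          }
        }
        cost[m, j] <- best
        back[m, j] <- arg
      }
    }
  }
  cl_sorted <- integer(n)
  centers <- numeric(k)
  end <- n
  for (m in k:1) {
    start <- if (m == 1) 1L else back[m, end]
    cl_sorted[start:end] <- m
    centers[m] <- mean(xs[start:end])
    end <- start - 1L
  }
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  list(cluster = cluster, centers = centers)
}

#' Mean silhouette score of a clustering
#'
#' Standard silhouette: for each point, `s = (b - a) / max(a, b)` where `a`
#' is the mean distance to the point's own cluster and `b` the smallest mean
#' distance to another cluster. Singleton clusters score 0, as does the
#' degenerate case `max(a, b) = 0` (duplicated points split across
#' clusters). Defined for 2 <= k <= n - 1; `NA` otherwise.
#'
#' @param x numeric vector (1-D data).
#' @param cluster integer cluster assignment.
#' @return The mean silhouette width in \[-1, 1\], or `NA`.
#' @export
silhouette_score <- function(x, cluster) {
  n <- length(x)
  k <- length(unique(cluster))
  if (k < 2 || k > n - 1) return(NA_real_)
  d <- abs(outer(x, x, "-"))
  sizes <- table(cluster)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster[i]
    if (sizes[[as.character(own)]] == 1) {
      s[i] <- 0
      next
    }
    a <- sum(d[i, cluster == own]) / (sizes[[as.character(own)]] - 1)
    b <- min(vapply(setdiff(unique(cluster), own), function(cl) {
      mean(d[i, cluster == cl])
    }, numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

# run kmeans_1d over a k range and keep the silhouette-maximal clustering.
# k = 1 is selected only when the range forces it or every candidate
# silhouette is negative/undefined.
best_kmeans_1d <- function(x, k_range) {
  n <- length(x)
  ks <- seq(max(1L, k_range[1]), min(k_range[2], length(unique(x))))
  best <- NULL
  for (k in ks) {
    if (k == 1 || k >= n) next
    fit <- kmeans_1d(x, k)
    sil <- silhouette_score(x, fit$cluster)
    if (is.na(sil)) next
    if (is.null(best) || sil > best$silhouette + 1e-12) {
      best <- list(cluster = fit$cluster, centers = fit$centers,
                   k = k, silhouette = sil)
    }
  }
  if (is.null(best) || best$silhouette < 0) {
    if (1 %in% ks || is.null(best)) {
      return(list(cluster = rep(1L, n), centers = mean(x), k = 1L,
                  silhouette = NA_real_))
    }
  }
  best
}

#' Assign digit boxes to physiological rows
#'
#' Digits are grouped by the y-centers of their boxes. If the y spread is
#' within a single-row threshold (a quarter of the narrowest row band — the
#' "only a few pixels" special case for charts with 0 or 1 rows filled), all
#' digits form one cluster; otherwise 1-D k-means runs for k in 2..7
#' (clipped to n - 1) and the silhouette-maximal k wins. Each cluster is
#' assigned to the row whose y-band contains its centroid; clusters whose
#' centroid falls in no band are discarded with a warning.
#'
#' @param digits box tibble of digit detections (section frame); extra
#'   columns are preserved.
#' @param rows the layout's `physio_rows` tibble (disjoint y-bands).
#' @return A named list, row name -> box tibble (possibly empty names
#'   dropped). Attribute `discarded` counts dropped clusters.
#' @export
assign_rows <- function(digits, rows) {
  if (nrow(digits) == 0) {
    out <- list()
    attr(out, "discarded") <- 0L
    return(out)
  }
  y <- digits$y_center
  band_height <- min(rows$y_max - rows$y_min)
  if (stats::sd(y) < 0.25 * band_height || nrow(digits) < 3) {
    cluster <- rep(1L, nrow(digits))
  } else {
    fit <- best_kmeans_1d(y, c(2L, 7L))
    cluster <- fit$cluster
  }
  out <- list()
  discarded <- 0L
  for (cl in sort(unique(cluster))) {
    members <- digits[cluster == cl, ]
    centroid <- mean(members$y_center)
    hit <- which(rows$y_min <= centroid & centroid <= rows$y_max)
    if (length(hit) == 0) {
      discarded <- discarded + 1L
      warning("digit cluster centroid at y = ", round(centroid, 1),
              " falls in no physio row band; cluster discarded",
              call. = FALSE)
      next
    }
    name <- rows$name[hit[1]]
    out[[name]] <- dplyr::bind_rows(out[[name]], members)
  }
  attr(out, "discarded") <- discarded
  out
}

#' Plausible k range for observation clustering
#'
#' With `n` digit boxes on a row whose values have between `d_min` and
#' `d_max` digits, the number of observations must lie near
#' `[n / d_max, n / d_min]`; a 10% margin on either side absorbs missed and
#' spurious detections: `k_lo = floor(n / d_max) - ceiling(0.1 n)`,
#' `k_hi = ceiling(n / d_min) + ceiling(0.1 n)`, clipped to \[1, n\].
#'
#' @param n number of digit boxes assigned to the row.
#' @param spec one row of the layout's `physio_rows` tibble.
#' @return Integer vector `c(k_lo, k_hi)`.
#' @examples
#' \dontrun{k_range_for(6, row_spec(chuk_layout(), "SpO2"))  # c(1, 4)}
#' @export
k_range_for <- function(n, spec) {
  margin <- ceiling(0.1 * n)
  k_lo <- floor(n / spec$d_max) - margin
  k_hi <- ceiling(n / spec$d_min) + margin
  c(max(1L, as.integer(k_lo)), min(as.integer(n), as.integer(k_hi)))
}

#' Cluster a row's digit boxes into multi-digit observations
#'
#' 1-D k-means on x-centers over the [k_range_for()] range, silhouette
#' maximal k (k = 1 only when the range forces it or all silhouettes are
#' negative). Members of each cluster are ordered by x-center.
#'
#' @param row_digits box tibble of one row's digits.
#' @param spec the row's spec (one row of `physio_rows`).
#' @return A list of box tibbles, one per observation, ordered left to
#'   right; attribute `k_search` records `k_range`, `chosen_k`,
#'   `silhouette`.
#' @export
cluster_observations <- function(row_digits, spec) {
  n <- nrow(row_digits)
  if (n == 0) return(list())
  kr <- k_range_for(n, spec)
  fit <- best_kmeans_1d(row_digits$x_center, kr)
  clusters <- split(seq_len(n), fit$cluster)
  # order clusters by centroid x, members by x
  cent <- vapply(clusters, function(i) mean(row_digits$x_center[i]),
                 numeric(1))
  clusters <- clusters[order(cent)]
  out <- purrr::map(clusters, function(i) {
    m <- row_digits[i, ]
    dplyr::arrange(m, .data$x_center)
  })
  out <- unname(out)
  attr(out, "k_search") <- list(k_range = kr, chosen_k = fit$k,
                                silhouette = fit$silhouette)
  out
}

#' Assemble an observation's digits into one value
#'
#' Classifies each member box and concatenates the digits in x order.
#'
#' @param members box tibble of one observation, ordered by x.
#' @param classifier a classifier contract (see [fixture_classifier()]).
#' @return `list(value =, confidence =)`; `value` is `NA` if any member
#'   fails to classify.
#' @export
assemble_value <- function(members, classifier) {
  members <- dplyr::arrange(members, .data$x_center)
  res <- purrr::map(seq_len(nrow(members)), function(i) {
    classifier$classify(crop = NULL, box = members[i, ])
  })
  digits <- vapply(res, function(r) as.integer(r$digit), integer(1))
  if (any(is.na(digits))) {
    return(list(value = NA_integer_, confidence = 0))
  }
  list(value = as.integer(paste(digits, collapse = "")),
       confidence = min(vapply(res, function(r) r$confidence, numeric(1))))
}

#' Split a tidal-volume observation at the X mark
#'
#' The tidal-volume row writes "TVxRR" (e.g. 450x12): tidal volume in mL, an
#' "X" separator, respiratory rate in breaths/min. Members are split at the
#' X mark found by the classifier's one-vs-rest `x_mark()`; digits left of it
#' form the tidal volume, digits right of it the respiratory rate. With no X
#' detected, the fallback uses the fact that tidal volume is nearly always
#' three digits and respiratory rate two: the last two digits are the rate.
#' An X at an extreme position leaves that side absent and flagged.
#'
#' @param members box tibble of the observation's glyphs, ordered by x.
#' @param classifier a classifier contract.
#' @return `list(tidal_volume =, respiratory_rate =, flags =)` where each
#'   value is an integer or `NA` and `flags` notes an empty side or
#'   fallback split.
#' @export
split_tidal_volume <- function(members, classifier) {
  members <- dplyr::arrange(members, .data$x_center)
  n <- nrow(members)
  is_x <- vapply(seq_len(n), function(i) {
    isTRUE(classifier$x_mark(crop = NULL, box = members[i, ]))
  }, logical(1))
  flags <- character()
  if (any(is_x)) {
    cut <- which(is_x)[1]
    left <- members[seq_len(cut - 1), , drop = FALSE]
    right <- members[setdiff(seq_len(n), seq_len(cut)), , drop = FALSE]
    right <- right[!is_x[setdiff(seq_len(n), seq_len(cut))], , drop = FALSE]
  } else if (n >= 3) {
    flags <- c(flags, "no_x_fallback_split")
    left <- members[seq_len(n - 2), , drop = FALSE]
    right <- members[(n - 1):n, , drop = FALSE]
  } else {
    flags <- c(flags, "no_x_fallback_split", "respiratory_rate_absent")
    left <- members
    right <- members[0, , drop = FALSE]
  }
  tv <- if (nrow(left) == 0) {
    flags <- c(flags, "tidal_volume_absent")
    NA_integer_
  } else {
    assemble_value(left, classifier)$value
  }
  rr <- if (nrow(right) == 0) {
    flags <- unique(c(flags, "respiratory_rate_absent"))
    NA_integer_
  } else {
    assemble_value(right, classifier)$value
  }
  list(tidal_volume = tv, respiratory_rate = rr, flags = flags)
}

#' Flag physiologically implausible values
#'
#' Two filters run in order. Range: a value outside the row's plausible
#' range (e.g. SpO2 outside \[75, 100\]) is flagged `implausible_range`.
#' Step: a value whose difference from its neighboring plausible values
#' exceeds the row's one-sided tolerance bound `max_step` is flagged
#' `implausible_step` — a true 99 misread as 79 between a 98 and a 100 drops
#' and recovers faster than the physiology allows. Step outliers are
#' identified by iterative consensus: a value qualifies only when all its
#' available unflagged neighbors disagree with it by more than `max_step`,
#' and the most deviant value is flagged first so a single misread never
#' drags its correct neighbors down with it.
#'
#' @param values ordered (by x, i.e. temporal order) numeric vector.
#' @param spec the row's spec.
#' @return Character vector of flags: `observed`, `implausible_range` or
#'   `implausible_step`.
#' @export
flag_implausible <- function(values, spec) {
  n <- length(values)
  flags <- rep("observed", n)
  flags[is.na(values)] <- "implausible_range"
  flags[!is.na(values) & (values < spec$lo | values > spec$hi)] <-
    "implausible_range"
  repeat {
    ok <- which(flags == "observed")
    if (length(ok) < 2) break
    deviation <- rep(NA_real_, n)
    for (idx in seq_along(ok)) {
      i <- ok[idx]
      neigh <- c(if (idx > 1) values[ok[idx - 1]],
                 if (idx < length(ok)) values[ok[idx + 1]])
      diffs <- abs(values[i] - neigh)
      if (length(diffs) > 0 && all(diffs > spec$max_step)) {
        deviation[i] <- max(diffs)
      }
    }
    if (all(is.na(deviation))) break
    flags[which.max(deviation)] <- "implausible_step"
  }
  flags
}

#' Impute flagged values by local linear regression
#'
#' Each flagged value is predicted from an ordinary least-squares line fit
#' on (index, value) of up to the two previous and two next plausible
#' values; at least two such neighbors are required, otherwise the value
#' stays flagged. Predictions are rounded half away from zero and clipped
#' to the row's plausible range. Neighbors are always originally-plausible
#' values — imputed values never feed later imputations, so one misread
#' cannot cascade.
#'
#' @param values numeric vector (temporal order).
#' @param flags flags from [flag_implausible()].
#' @param spec the row's spec.
#' @return `list(values =, flags =)` with imputed entries replaced and
#'   flagged `imputed`.
#' @export
impute <- function(values, flags, spec) {
  plausible <- which(flags == "observed")
  out_values <- values
  out_flags <- flags
  for (i in which(flags != "observed")) {
    prev <- utils::tail(plausible[plausible < i], 2)
    nxt <- utils::head(plausible[plausible > i], 2)
    idx <- c(prev, nxt)
    if (length(idx) < 2) next
    x <- idx; y <- values[idx]
    # closed-form OLS on <= 4 points
    xb <- mean(x); yb <- mean(y)
    slope <- if (sum((x - xb)^2) == 0) 0 else {
      sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    }
    pred <- yb + slope * (i - xb)
    pred <- round_half_away(pred)
    pred <- min(max(pred, spec$lo), spec$hi)
    out_values[i] <- pred
    out_flags[i] <- "imputed"
  }
  list(values = out_values, flags = out_flags)
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Index-wise mean absolute error with list truncation
#'
#' Predicted and ground-truth value lists are matched by index; the longer
#' list is truncated to the length of the shorter before averaging. The
#' worked example: (99, 98, 97) against (98, 99, 100) scores
#' (|99-98| + |98-99| + |97-100|) / 3 = 5/3.
#'
#' @param predicted,truth numeric vectors; at least one non-empty.
#' @return The mean absolute error over the matched prefix.
#' @export
physio_mae <- function(predicted, truth) {
  if (length(predicted) == 0 && length(truth) == 0) {
    stop("both lists are empty", call. = FALSE)
  }
  n <- min(length(predicted), length(truth))
  if (n == 0) return(NA_real_)
  mean(abs(predicted[seq_len(n)] - truth[seq_len(n)]))
}
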