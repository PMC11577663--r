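# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation they check.

# brute-force duplicate grouping: boolean IoU/label adjacency closed to a
# fixpoint with Floyd-Warshall-style transitive closure
oracle_merge_groups <- function(boxes, threshold) {
  n <- nrow(boxes)
  if (n == 0) return(integer())
  x1 <- boxes$x_center - boxes$width / 2; x2 <- boxes$x_center + boxes$width / 2
  y1 <- boxes$y_center - boxes$height / 2; y2 <- boxes$y_center + boxes$height / 2
  area <- boxes$width * boxes$height
  pair_iou <- function(i, j) {
    ix <- max(0, min(x2[i], x2[j]) - max(x1[i], x1[j]))
    iy <- max(0, min(y2[i], y2[j]) - max(y1[i], y1[j]))
    inter <- ix * iy
    inter / (area[i] + area[j] - inter)
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        adj[i, j] <- TRUE
      } else if (boxes$label[i] == boxes$label[j] &&
                 pair_iou(i, j) > threshold) {
        adj[i, j] <- TRUE
      }
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  # component id = smallest member index reachable
  apply(adj, 1, function(r) min(which(r)))
}

# partition equality up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# loop-based O(n^2) silhouette, straight from the definition
oracle_silhouette <- function(x, cluster) {
  n <- length(x)
  ids <- unique(cluster)
  if (length(ids) < 2 || length(ids) > n - 1) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster[i]
    own_others <- which(cluster == own & seq_len(n) != i)
    if (length(own_others) == 0) {
      s[i] <- 0
      next
    }
    a <- 0
    for (j in own_others) a <- a + abs(x[i] - x[j])
    a <- a / length(own_others)
    b <- Inf
    for (cl in setdiff(ids, own)) {
      members <- which(cluster == cl)
      m <- 0
      for (j in members) m <- m + abs(x[i] - x[j])
      b <- min(b, m / length(members))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# cluster assignment from the package's exact 1-D k-means
kmeans_1d_for_test <- function(x, k) {
  chartdigitizer:::kmeans_1d(x, k)$cluster
}

# random non-degenerate quad: perturbed unit-square corners, rejected if any
# triple is nearly collinear
random_quad <- function(scale = 100) {
  repeat {
    pts <- tibble::tibble(
      name = paste0("p", 1:4),
      x = c(0, 1, 1, 0) * scale + stats::runif(4, -0.2, 0.2) * scale,
      y = c(0, 0, 1, 1) * scale + stats::runif(4, -0.2, 0.2) * scale
    )
    areas <- utils::combn(4, 3, function(i) {
      abs((pts$x[i[2]] - pts$x[i[1]]) * (pts$y[i[3]] - pts$y[i[1]]) -
            (pts$x[i[3]] - pts$x[i[1]]) * (pts$y[i[2]] - pts$y[i[1]])) / 2
    })
    if (min(areas) > 0.01 * scale^2) return(pts)
  }
}

# intersection of segments p1-p3 and p2-p4 (diagonals of a quad); the
# projective image of a square's center is the intersection of the image
# quad's diagonals
diagonal_intersection <- function(x, y) {
  d1 <- c(x[3] - x[1], y[3] - y[1])
  d2 <- c(x[4] - x[2], y[4] - y[2])
  rhs <- c(x[2] - x[1], y[2] - y[1])
  A <- cbind(d1, -d2)
  t <- solve(A, rhs)
  unname(c(x[1] + t[1] * d1[1], y[1] + t[1] * d1[2]))
}

# synthetic gradient + ink-stroke fixture for shadow-removal tests;
# returns the image and logical masks for background and strokes
gradient_stroke_fixture <- function(height = 120, width = 400,
                                    bright = 255, dark = 120,
                                    ink = 30) {
  img <- matrix(rep(seq(bright, dark, length.out = width), each = height),
                height, width)
  stroke <- matrix(FALSE, height, width)
  for (x0 in seq(20, width - 20, by = 30)) {
    stroke[30:90, x0:(x0 + 1)] <- TRUE
    stroke[60:61, (x0 - 5):(x0 + 6)] <- TRUE
  }
  img[stroke] <- ink
  list(image = img, stroke = stroke, background = !stroke)
}

# seeded checkbox detections on a clean column grid matching a layout schema
checkbox_grid <- function(layout, jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    boxes <- list()
    truth <- list()
    for (ci in seq_along(layout$checkbox_columns)) {
      col <- layout$checkbox_columns[[ci]]
      for (ri in seq_along(col$labels)) {
        checked <- stats::runif(1) < 0.5
        boxes[[length(boxes) + 1L]] <- new_boxes(
          label = if (checked) "checked" else "unchecked",
          x_center = 30 + (ci - 1) * 85 + stats::runif(1, -jitter, jitter),
          y_center = 30 + (ri - 1) * 60 + stats::runif(1, -jitter, jitter),
          width = 20, height = 20
        )
        truth[[length(truth) + 1L]] <- tibble::tibble(
          label = col$labels[ri], checked = checked)
      }
    }
    list(detections = dplyr::bind_rows(boxes),
         truth = dplyr::bind_rows(truth))
  })
}

# a small valid random digitized record for round-trip property tests
random_record <- function() {
  n_bp <- sample(0:8, 1)
  bp <- tibble::tibble(
    t_minutes = if (n_bp > 0) cumsum(c(0, sample(c(5, 10), n_bp - 1, TRUE)))
                else numeric(),
    systolic = round(stats::runif(n_bp, 80, 180)),
    diastolic = round(stats::runif(n_bp, 40, 110))
  )
  n_ph <- sample(0:10, 1)
  physio <- tibble::tibble(
    row = sample(c("SpO2", "EtCO2", "FiO2"), n_ph, TRUE),
    index = seq_len(n_ph) + 0,
    value = round(stats::runif(n_ph, 20, 100)),
    flag = sample(c("observed", "implausible_range", "implausible_step",
                    "imputed"), n_ph, TRUE)
  )
  labels <- paste0("box_", 1:6)
  checkboxes <- tibble::tibble(label = labels,
                               checked = stats::runif(6) < 0.5)
  digitized_record(
    bp = bp, physio = physio, checkboxes = checkboxes,
    provenance = list(deshadow = TRUE, homography_requested = TRUE,
                      homography_applied = FALSE, seed = 1L,
                      detector = "fixture", warnings = character())
  )
}
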