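test_that("tile offsets advance by half-tile and clamp at the edge", {
  img100 <- matrix(0, 100, 100)
  g <- tile_grid(100, 100)
  t1 <- make_tiles(img100, g)
  expect_length(t1, 1)
  expect_equal(t1[[1]]$offset, c(x = 0L, y = 0L))

  img200 <- matrix(0, 100, 200)
  t2 <- make_tiles(img200, g)
  expect_equal(sort(unique(vapply(t2, function(t) t$offset[["x"]],
                                  integer(1)))), c(0L, 50L, 100L))

  img250 <- matrix(0, 100, 250)
  t3 <- make_tiles(img250, g)
  expect_equal(sort(unique(vapply(t3, function(t) t$offset[["x"]],
                                  integer(1)))), c(0L, 50L, 100L, 150L))

  expect_warning(make_tiles(matrix(0, 50, 50), g), "single whole-image tile")
})

test_that("detections lift from tile-local to section coordinates", {
  b <- new_boxes("digit", 10, 10, 4, 4)
  out <- lift_detections(list(list(boxes = b, offset = c(x = 50L, y = 0L))))
  expect_equal(out$x_center, 60)
  expect_equal(out$y_center, 10)

  expect_equal(nrow(lift_detections(list())), 0)

  # one physical object straddling a tile boundary appears in two tiles
  left <- new_boxes("digit", 95, 20, 10, 10)    # tile at offset 0
  right <- new_boxes("digit", 45, 20, 10, 10)   # same object, tile at 50
  both <- lift_detections(list(
    list(boxes = left, offset = c(x = 0L, y = 0L)),
    list(boxes = right, offset = c(x = 50L, y = 0L))
  ))
  expect_gt(iou(both[1, ], both[2, ]), 0.9)
})

test_that("iou matches hand computations and is symmetric and bounded", {
  a <- new_boxes("x", 0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  far <- new_boxes("x", 100, 0, 2, 2)
  expect_equal(iou(a, far), 0)
  shifted <- new_boxes("x", 1, 0, 2, 2)
  expect_equal(iou(a, shifted), 1 / 3)  # intersection 2, union 6

  set.seed(4)
  for (i in 1:50) {
    b1 <- new_boxes("x", runif(1, 0, 50), runif(1, 0, 50),
                    runif(1, 1, 20), runif(1, 1, 20))
    b2 <- new_boxes("x", runif(1, 0, 50), runif(1, 0, 50),
                    runif(1, 1, 20), runif(1, 1, 20))
    v <- iou(b1, b2)
    expect_equal(v, iou(b2, b1))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("duplicate merging groups transitively and combines scores", {
  single <- new_boxes("a", 5, 5, 4, 4, 0.8)
  expect_equal(merge_duplicates(single), single)

  twins <- dplyr::bind_rows(new_boxes("a", 5, 5, 4, 4, 0.6),
                            new_boxes("a", 5, 5, 4, 4, 0.9))
  m <- merge_duplicates(twins)
  expect_equal(nrow(m), 1)
  expect_equal(m$x_center, 5)
  expect_equal(m$score, 0.9)

  # chain: A overlaps B, B overlaps C, A and C disjoint -> one component
  chain <- dplyr::bind_rows(new_boxes("a", 0, 0, 10, 10),
                            new_boxes("a", 6, 0, 10, 10),
                            new_boxes("a", 12, 0, 10, 10))
  expect_equal(nrow(merge_duplicates(chain, 0.2)), 1)
  expect_true(same_partition(oracle_merge_groups(chain, 0.2), rep(1, 3)))

  # different labels never merge
  mixed <- dplyr::bind_rows(new_boxes("a", 5, 5, 4, 4),
                            new_boxes("b", 5, 5, 4, 4))
  expect_equal(nrow(merge_duplicates(mixed)), 2)

  expect_error(merge_duplicates(single, iou_threshold = 1.2),
               "strictly between")
})

test_that("merging equals the brute-force union-find oracle on 200 seeded sets", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(1:100, 1)
    boxes <- new_boxes(
      label = sample(c("a", "b"), n, TRUE),
      x_center = runif(n, 0, 150), y_center = runif(n, 0, 150),
      width = runif(n, 4, 30), height = runif(n, 4, 30),
      score = runif(n, 0.2, 1)
    )
    merged <- merge_duplicates(boxes, 0.4)
    oracle <- oracle_merge_groups(boxes, 0.4)
    expect_equal(nrow(merged), length(unique(oracle)))
  }
})

test_that("merging is idempotent in the well-separated duplicate regime", {
  # the chart's symbols never overlap; duplicates are near-coincident
  # re-detections of the same glyph from adjacent tiles
  set.seed(23)
  for (rep in 1:50) {
    n_obj <- sample(5:30, 1)
    centers_x <- runif(n_obj, 0, 2000)
    centers_y <- runif(n_obj, 0, 400)
    boxes <- list()
    for (i in seq_len(n_obj)) {
      n_dup <- sample(1:3, 1)
      boxes[[i]] <- new_boxes("digit",
                              x_center = centers_x[i] + runif(n_dup, -1, 1),
                              y_center = centers_y[i] + runif(n_dup, -1, 1),
                              width = 10, height = 14,
                              score = runif(n_dup, 0.5, 1))
    }
    boxes <- dplyr::bind_rows(boxes)
    merged <- merge_duplicates(boxes, 0.4)
    expect_equal(merge_duplicates(merged, 0.4), merged)
  }
})

test_that("every sub-stride object is fully contained in at least one tile", {
  set.seed(22)
  g <- tile_grid(128, 128)
  W <- 500L; H <- 400L
  tiles <- make_tiles(matrix(0, H, W), g)
  offs <- t(vapply(tiles, function(t) t$offset, c(x = 0L, y = 0L)))
  hits <- 0L
  for (i in 1:1000) {
    w <- runif(1, 1, g$stride_x)
    h <- runif(1, 1, g$stride_y)
    cx <- runif(1, w / 2, W - w / 2)
    cy <- runif(1, h / 2, H - h / 2)
    contained <- any(
      cx - w / 2 >= offs[, "x"] & cx + w / 2 <= offs[, "x"] + g$tile_width &
      cy - h / 2 >= offs[, "y"] & cy + h / 2 <= offs[, "y"] + g$tile_height
    )
    hits <- hits + contained
  }
  expect_equal(hits, 1000L)
})
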