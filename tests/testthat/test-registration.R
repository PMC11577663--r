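test_that("four-point homography reproduces identity and translation exactly", {
  sq <- landmark_set(paste0("p", 1:4), c(0, 100, 100, 0), c(0, 0, 100, 100))
  h_id <- compute_homography(sq, sq)
  expect_equal(unclass(h_id), diag(3), tolerance = 1e-10)

  shifted <- sq
  shifted$x <- shifted$x + 10
  shifted$y <- shifted$y + 5
  h_t <- compute_homography(sq, shifted)
  set.seed(1)
  pts <- tibble::tibble(x = runif(20, -50, 150), y = runif(20, -50, 150))
  moved <- apply_homography(h_t, pts)
  expect_equal(moved$x, pts$x + 10, tolerance = 1e-9)
  expect_equal(moved$y, pts$y + 5, tolerance = 1e-9)
})

test_that("unit square to perspective quad maps the center onto the diagonal intersection", {
  sq <- landmark_set(paste0("p", 1:4), c(0, 1, 0.9, 0.1), c(0, 0, 1.1, 1))
  src <- landmark_set(paste0("p", 1:4), c(0, 1, 1, 0), c(0, 0, 1, 1))
  h <- compute_homography(src, sq)
  corners <- apply_homography(h, tibble::tibble(x = c(0, 1, 1, 0),
                                                y = c(0, 0, 1, 1)))
  expect_equal(corners$x, sq$x, tolerance = 1e-9)
  expect_equal(corners$y, sq$y, tolerance = 1e-9)
  center <- apply_homography(h, tibble::tibble(x = 0.5, y = 0.5))
  oracle <- diagonal_intersection(sq$x, sq$y)
  expect_equal(c(center$x, center$y), oracle, tolerance = 1e-9)
})

test_that("homography recovery is exact over 500 seeded random quads", {
  set.seed(11)
  worst <- 0
  for (i in 1:500) {
    src <- random_quad()
    dst <- random_quad()
    h <- compute_homography(src, dst)
    mapped <- apply_homography(h, src)
    err <- max(sqrt((mapped$x - dst$x)^2 + (mapped$y - dst$y)^2))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("homographies compose on the landmarks", {
  set.seed(12)
  a <- random_quad(); b <- random_quad(); c <- random_quad()
  h_ab <- compute_homography(a, b)
  h_bc <- compute_homography(b, c)
  h_ac <- compute_homography(a, c)
  composed <- apply_homography(h_bc, apply_homography(h_ab, a))
  direct <- apply_homography(h_ac, a)
  expect_equal(composed$x, direct$x, tolerance = 1e-6)
  expect_equal(composed$y, direct$y, tolerance = 1e-6)
})

test_that("degenerate and incomplete landmark configurations are errors", {
  col3 <- landmark_set(paste0("p", 1:4), c(0, 1, 2, 0), c(0, 1, 2, 5))
  ok <- landmark_set(paste0("p", 1:4), c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_error(compute_homography(col3, ok), "collinear")
  expect_error(compute_homography(ok[1:3, ], ok), "four landmark")

  partial <- landmark_set(c("Total", "Time", "Procedure Details"),
                          c(0, 1, 2), c(0, 1, 0))
  expect_false(landmarks_complete(partial))
  expect_error(landmarks_complete(partial, error = TRUE), "Patient Position")
})

test_that("warping with the identity homography is pixel-identical", {
  layout <- chuk_layout()
  img <- matrix(round(seq(0, 255, length.out = 700 * 1000)), 700, 1000)
  h <- structure(diag(3), class = c("homography", "matrix", "array"))
  out <- warp_to_reference(img, h, layout)
  expect_identical(out, img)
})

test_that("warp then inverse warp restores the image away from boundaries", {
  ch <- render_chart(synth_spec(seed = 3L))
  img <- ch$image
  src <- landmark_set(paste0("p", 1:4), c(1, 1000, 1000, 1), c(1, 1, 700, 700))
  dst <- src
  dst$x <- dst$x + c(25, -18, -30, 12)
  dst$y <- dst$y + c(20, 14, -22, -15)
  h <- compute_homography(src, dst)
  fwd <- warp_image(img, h, 1000, 700)
  back <- warp_image(fwd, invert_homography(h), 1000, 700)
  interior <- back[60:640, 60:940] - img[60:640, 60:940]
  expect_lt(mean(abs(interior)), 3)
})

test_that("a 90%-scale homography lands tracked pixels on their targets", {
  src <- landmark_set(paste0("p", 1:4), c(0, 1000, 1000, 0), c(0, 0, 700, 700))
  dst <- src
  dst$x <- dst$x * 0.9
  dst$y <- dst$y * 0.9
  h <- compute_homography(src, dst)
  pts <- tibble::tibble(x = c(100, 500, 900), y = c(100, 350, 600))
  mapped <- apply_homography(h, pts)
  expect_equal(mapped$x, pts$x * 0.9, tolerance = 0.5)
  expect_equal(mapped$y, pts$y * 0.9, tolerance = 0.5)
})

test_that("section crops carry offsets that reassemble the source exactly", {
  img <- matrix(seq_len(200 * 300) %% 251, 200, 300)
  secs <- tibble::tibble(name = c("a", "b"),
                         x = c(10, 150), y = c(20, 100),
                         width = c(100, 120), height = c(80, 90))
  crops <- crop_sections(img, secs)
  for (nm in names(crops)) {
    cr <- crops[[nm]]
    rows <- (cr$offset[["y"]] + 1):(cr$offset[["y"]] + nrow(cr$image))
    cols <- (cr$offset[["x"]] + 1):(cr$offset[["x"]] + ncol(cr$image))
    expect_identical(cr$image, img[rows, cols])
  }

  full <- crop_sections(img, tibble::tibble(name = "all", x = 0, y = 0,
                                            width = 300, height = 200))
  expect_identical(full$all$image, img)
  expect_equal(full$all$offset, c(x = 0L, y = 0L))

  expect_warning(
    clipped <- crop_sections(img, tibble::tibble(name = "edge", x = 250,
                                                 y = 0, width = 55,
                                                 height = 50)),
    "clipped"
  )
  expect_true(clipped$edge$clipped)
  expect_equal(ncol(clipped$edge$image), 50)
})
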