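spo2_spec <- function() row_spec(chuk_layout(), "SpO2")
tv_spec <- function() row_spec(chuk_layout(), "tidal_volume")

digit_row <- function(xs, ys = 100, digits = NULL, is_x = NULL) {
  ys <- rep_len(ys, length(xs))
  b <- new_boxes("digit", x_center = xs, y_center = ys, width = 10,
                 height = 14)
  b$digit <- if (is.null(digits)) rep(NA_integer_, length(xs)) else digits
  b$is_x <- if (is.null(is_x)) rep(FALSE, length(xs)) else is_x
  b
}

test_that("k range reproduces the printed formula", {
  sp <- spo2_spec()
  expect_equal(k_range_for(6, sp), c(1L, 4L))
  expect_equal(k_range_for(1, sp), c(1L, 1L))
  expect_equal(k_range_for(30, sp), c(7L, 18L))
  # enumerated check against a direct evaluation of the formula
  for (n in 1:60) {
    expected_lo <- max(1, floor(n / 3) - ceiling(0.1 * n))
    expected_hi <- min(n, ceiling(n / 2) + ceiling(0.1 * n))
    expect_equal(k_range_for(n, sp), c(expected_lo, expected_hi),
                 info = paste("n =", n))
  }
})

test_that("silhouette matches independent oracles", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(6:40, 1)
    x <- c(rnorm(n %/% 2, 0, 2), rnorm(n - n %/% 2, 20, 2))
    k <- sample(2:4, 1)
    cl <- kmeans_1d_for_test(x, k)
    ours <- silhouette_score(x, cl)
    expect_equal(ours, oracle_silhouette(x, cl), tolerance = 1e-9)
    sil <- cluster::silhouette(cl, stats::dist(x))
    expect_equal(ours, mean(sil[, "sil_width"]), tolerance = 1e-9)
  }
  expect_true(is.na(silhouette_score(c(1, 2), c(1, 2))))
})

test_that("row assignment handles empty, single-row and multi-row cases", {
  layout <- chuk_layout()
  rows <- layout$physio_rows
  expect_equal(length(assign_rows(digit_row(numeric(0)), rows)), 0)

  # six digits within a few px of y = 20: the single-row special case
  single <- digit_row(xs = seq(10, 60, 10), ys = 20 + runif(6, -2, 2))
  out <- assign_rows(single, rows)
  expect_equal(names(out), "SpO2")
  expect_equal(nrow(out$SpO2), 6)

  # two tight bands land in their own rows, k chosen by silhouette
  set.seed(52)
  two <- digit_row(xs = rep(seq(10, 100, 10), 2),
                   ys = c(rnorm(10, 20, 2), rnorm(10, 100, 2)))
  out2 <- assign_rows(two, rows)
  expect_setequal(names(out2), c("SpO2", "FiO2"))
  expect_equal(nrow(out2$SpO2), 10)
  expect_equal(nrow(out2$FiO2), 10)

  # a cluster centroid outside every band is discarded with a warning
  stray <- digit_row(xs = c(rep(seq(10, 100, 10), 2), seq(10, 100, 10)),
                     ys = c(rnorm(10, 20, 1), rnorm(10, 100, 1),
                            rnorm(10, 290, 1)))
  expect_warning(out3 <- assign_rows(stray, rows), "no physio row band")
  expect_setequal(names(out3), c("SpO2", "FiO2"))
  expect_equal(attr(out3, "discarded"), 1L)
})

test_that("observation clustering finds the true groups", {
  sp <- spo2_spec()
  # two digits close together: one observation
  one <- cluster_observations(digit_row(c(10, 15)), sp)
  expect_length(one, 1)

  # three groups of two: intra gap 8, inter gap 60
  xs <- c(10, 18, 78, 86, 146, 154)
  three <- cluster_observations(digit_row(xs), sp)
  expect_length(three, 3)
  expect_equal(vapply(three, nrow, integer(1)), c(2L, 2L, 2L))
  ks <- attr(three, "k_search")
  expect_equal(ks$chosen_k, 3L)
  # the chosen k beats every other candidate under the oracle silhouette
  for (k in 2:5) {
    cl <- kmeans_1d_for_test(xs, k)
    expect_lte(oracle_silhouette(xs, cl),
               oracle_silhouette(xs, kmeans_1d_for_test(xs, 3)) + 1e-12)
  }

  # groups of 3 and 2 (e.g. 100 then 98): chosen k = 2
  xs2 <- c(10, 22, 34, 100, 112)
  two <- cluster_observations(digit_row(xs2), sp)
  expect_length(two, 2)
  expect_equal(attr(two, "k_search")$chosen_k, 2L)
  expect_equal(vapply(two, nrow, integer(1)), c(3L, 2L))
})

test_that("values assemble by decimal concatenation in x order", {
  gt <- digit_row(c(10, 20), digits = c(9L, 8L))
  clf <- fixture_classifier(gt)
  expect_equal(assemble_value(gt, clf)$value, 98L)

  gt1 <- digit_row(5, digits = 7L)
  expect_equal(assemble_value(gt1, fixture_classifier(gt1))$value, 7L)

  gt100 <- digit_row(c(5, 12, 19), digits = c(1L, 0L, 0L))
  expect_equal(assemble_value(gt100, fixture_classifier(gt100))$value, 100L)

  # assembly order follows x, not input order
  shuffled <- gt100[c(3, 1, 2), ]
  expect_equal(assemble_value(shuffled, fixture_classifier(gt100))$value, 100L)
})

test_that("tidal volume splits at the X mark with a 3/2 fallback", {
  glyphs <- digit_row(seq(10, 60, 10),
                      digits = c(4L, 5L, 0L, NA, 1L, 2L),
                      is_x = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  clf <- fixture_classifier(glyphs)
  sp <- split_tidal_volume(glyphs, clf)
  expect_equal(sp$tidal_volume, 450L)
  expect_equal(sp$respiratory_rate, 12L)
  expect_length(sp$flags, 0)

  no_x <- digit_row(seq(10, 50, 10), digits = c(4L, 5L, 0L, 1L, 2L))
  sp2 <- split_tidal_volume(no_x, fixture_classifier(no_x))
  expect_equal(sp2$tidal_volume, 450L)
  expect_equal(sp2$respiratory_rate, 12L)
  expect_true("no_x_fallback_split" %in% sp2$flags)

  x_first <- digit_row(c(10, 20, 30), digits = c(NA, 1L, 2L),
                       is_x = c(TRUE, FALSE, FALSE))
  sp3 <- split_tidal_volume(x_first, fixture_classifier(x_first))
  expect_true(is.na(sp3$tidal_volume))
  expect_equal(sp3$respiratory_rate, 12L)
  expect_true("tidal_volume_absent" %in% sp3$flags)
})

test_that("plausibility flags reproduce the misread-saturation scenario", {
  sp <- spo2_spec()
  # a true 99 misread as 79 between 98 and 100: only the middle is flagged
  expect_equal(flag_implausible(c(98, 79, 100), sp),
               c("observed", "implausible_step", "observed"))
  expect_equal(flag_implausible(c(72), sp), "implausible_range")
  expect_equal(flag_implausible(c(97, 98, 98, 99), sp), rep("observed", 4))
  # range flags take precedence and are assessed first
  expect_equal(flag_implausible(c(98, 60, 99), sp),
               c("observed", "implausible_range", "observed"))
})

test_that("imputation fits a local least-squares line and clips to range", {
  sp <- spo2_spec()
  vals <- c(96, 97, 79, 99, 100)
  flags <- flag_implausible(vals, sp)
  expect_equal(flags[3], "implausible_step")
  out <- impute(vals, flags, sp)
  expect_equal(out$values[3], 98)
  expect_equal(out$flags[3], "imputed")

  const <- impute(c(98, 98, 60, 98, 98),
                  c("observed", "observed", "implausible_range",
                    "observed", "observed"), sp)
  expect_equal(const$values[3], 98)

  # boundary: only two following neighbors -> two-point extrapolation
  edge <- impute(c(60, 98, 100),
                 c("implausible_range", "observed", "observed"), sp)
  expect_equal(edge$values[1], 96)

  # a single plausible neighbor is not enough
  lone <- impute(c(60, 98), c("implausible_range", "observed"), sp)
  expect_equal(lone$flags[1], "implausible_range")
  expect_equal(lone$values[1], 60)
})

test_that("collinear neighbors impute exactly for seeded lines", {
  sp <- tibble::tibble(name = "wide", y_min = 0, y_max = 1, lo = -1e6,
                       hi = 1e6, d_min = 1L, d_max = 6L, max_step = 1e5)
  set.seed(61)
  for (i in 1:100) {
    a <- sample(-50:50, 1)
    b <- sample(-20:20, 1)
    idx <- 1:5
    line <- a + b * idx
    vals <- line
    vals[3] <- line[3] + 1e4  # force a step flag via a huge spike
    flags <- c("observed", "observed", "implausible_step",
               "observed", "observed")
    out <- impute(vals, flags, sp)
    expect_equal(out$values[3], line[3])
  }
})

test_that("physio MAE truncates the longer list then averages", {
  expect_equal(physio_mae(c(99, 98, 97), c(98, 99, 100)), 5 / 3)
  expect_equal(physio_mae(c(99, 98), c(99, 98)), 0)
  expect_equal(physio_mae(c(99, 98, 97, 96), c(99, 98)), 0)
  expect_error(physio_mae(numeric(), numeric()), "empty")
})

test_that("clustering recovery holds over 200 seeded synthetic rows", {
  sp <- spo2_spec()
  set.seed(71)
  exact <- 0L
  for (rep in 1:200) {
    n_obs <- sample(3:8, 1)
    n_digits <- sample(2:3, n_obs, TRUE)
    pitch <- 10
    xs <- numeric(0); truth_id <- integer(0)
    x <- runif(1, 0, 20)
    for (ob in seq_len(n_obs)) {
      xs <- c(xs, x + (seq_len(n_digits[ob]) - 1) * pitch)
      truth_id <- c(truth_id, rep(ob, n_digits[ob]))
      # inter-observation gap at least 3x the digit pitch
      x <- x + (n_digits[ob] - 1) * pitch + runif(1, 3 * pitch, 6 * pitch)
    }
    obs <- cluster_observations(digit_row(xs), sp)
    got <- integer(length(xs))
    for (i in seq_along(obs)) {
      got[match(round(obs[[i]]$x_center, 6), round(xs, 6))] <- i
    }
    if (length(obs) == n_obs && same_partition(got, truth_id)) {
      exact <- exact + 1L
    }
  }
  expect_gte(exact / 200, 0.99)
})
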