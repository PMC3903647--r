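test_that("threshold is the interpolated 10th percentile of presence values", {
  v <- matrix(seq(0.1, 1.0, by = 0.1), 2, 5)
  g <- grid_from(v)
  th <- threshold_from_presences(g, 1:10)
  expect_equal(th$tau, 0.19)

  # degenerate distribution
  g2 <- grid_from(matrix(0.4, 2, 2))
  expect_equal(threshold_from_presences(g2, 1:4)$tau, 0.4)

  # large uniform sample: tau near 0.10
  withr::with_seed(11, {
    v3 <- matrix(stats::runif(1000), 20, 50)
    tau <- threshold_from_presences(grid_from(v3), 1:1000)$tau
  })
  expect_lt(abs(tau - 0.10), 0.03)

  expect_error(threshold_from_presences(g, 1L), "at least 2")
  gna <- grid_from(matrix(c(NA, 0.5, 0.6, 0.7), 2, 2))
  expect_error(threshold_from_presences(gna, c(1L, 2L)), "nodata")
})

test_that("at most ceil(n/10) presences fall strictly below the threshold", {
  withr::with_seed(21, {
    for (i in 1:40) {
      n <- sample(2:60, 1)
      v <- stats::rbeta(n, 2, 2)
      g <- grid_from(matrix(c(v, rep(NA, 60 - n)), 6, 10))
      tau <- threshold_from_presences(g, seq_len(n))$tau
      expect_lte(sum(v < tau), ceiling(0.1 * n))
      expect_gte(tau, min(v))
      expect_lte(tau, max(v))
    }
  })
})

test_that("binarization uses >= tau and preserves nodata", {
  g <- grid_from(matrix(c(0.05, 0.19, 0.50, NA), 1, 4))
  b <- binarize(g, 0.19)
  expect_identical(as.vector(b$presence), c(FALSE, TRUE, TRUE, NA))

  expect_true(all(binarize(g, 0)$presence[1:3]))
  expect_error(binarize(g, 1.2), "\\[0, 1\\]")

  withr::with_seed(5, v <- matrix(stats::runif(400), 20, 20))
  tau <- stats::median(v)
  b2 <- binarize(grid_from(v), tau)
  expect_equal(sum(b2$presence), sum(v >= tau))
})

test_that("raising the threshold never increases the suitable-cell count", {
  withr::with_seed(9, v <- matrix(stats::runif(200), 10, 20))
  g <- grid_from(v)
  taus <- sort(stats::runif(10))
  counts <- vapply(taus, function(t) sum(binarize(g, t)$presence), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("change classification follows the present/future truth table", {
  p <- bin_from(matrix(c(TRUE, TRUE, FALSE, FALSE, NA), 1, 5))
  f <- bin_from(matrix(c(FALSE, TRUE, TRUE, FALSE, NA), 1, 5))
  cc <- classify_change(p, f, "sp", "A2a")
  expect_identical(as.vector(cc$classes),
                   c("loss", "maintain", "gain", "unsuitable", NA))
})

test_that("every valid cell gets exactly one class and classes partition", {
  withr::with_seed(13, {
    for (i in 1:10) {
      m <- matrix(stats::runif(150), 10, 15)
      m[sample.int(150, 12)] <- NA
      p <- binarize(grid_from(m), stats::runif(1))
      m2 <- m + matrix(stats::rnorm(150, sd = 0.2), 10, 15)
      m2 <- pmin(pmax(m2, 0), 1)
      m2[is.na(m)] <- NA
      f <- binarize(grid_from(m2), stats::runif(1))
      cc <- classify_change(p, f)
      n_valid <- sum(!is.na(m))
      tab <- table(cc$classes)
      expect_equal(sum(tab), n_valid)
      expect_equal(sum(tab) + sum(is.na(cc$classes)), 150)
      # gain cells are present-unsuitable; loss+maintain = present-suitable
      expect_false(any(cc$classes == "gain" & p$presence, na.rm = TRUE))
      suitable_now <- sum(p$presence, na.rm = TRUE)
      expect_equal(sum(tab[c("loss", "maintain")], na.rm = TRUE), suitable_now)
    }
  })
})

test_that("classification requires matching masks", {
  p <- bin_from(matrix(c(TRUE, NA, TRUE, TRUE), 2, 2))
  f <- bin_from(matrix(c(TRUE, TRUE, NA, TRUE), 2, 2))
  expect_error(classify_change(p, f), "mask")
})

test_that("richness delta counts gains minus losses per cell", {
  mk_map <- function(cls, sc = "A2a")
    structure(list(classes = cls, species_id = "x", scenario_id = sc),
              class = "change_class_map")
  one <- mk_map(matrix("loss", 1, 1))
  expect_equal(richness_delta(list(one))[1, 1], -1)

  allm <- mk_map(matrix("maintain", 2, 2))
  expect_true(all(richness_delta(list(allm)) == 0))

  c1 <- matrix(c("gain", "loss", "maintain", "unsuitable"), 2, 2)
  c2 <- matrix(c("gain", "gain", "loss", "loss"), 2, 2)
  c3 <- matrix(c("loss", "maintain", "gain", "gain"), 2, 2)
  d <- richness_delta(list(mk_map(c1), mk_map(c2), mk_map(c3)))
  # per-cell tallies: (+1+1-1, -1+1+0, 0-1+1, 0-1+1)
  expect_equal(as.vector(d), c(1, 0, 0, 0))
  expect_error(richness_delta(list(mk_map(c1, "A2a"), mk_map(c2, "B2a"))),
               "scenario")
})
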