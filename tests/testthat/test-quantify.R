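test_that("components below 3 pixels are removed, 3-pixel shapes kept", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE                      # isolated pixel
  m[5, 5] <- m[6, 6] <- TRUE           # 2-px diagonal pair (8-connected)
  m[8, 2] <- m[8, 3] <- m[9, 2] <- TRUE  # 3-px L
  seg <- clean_marker_mask(m)
  expect_equal(seg$A_M, 3)
  expect_true(all(seg$M[cbind(c(8, 8, 9), c(2, 3, 2))]))
})

test_that("cleaning handles every <=4-pixel component shape correctly", {
  # exhaustive scan over all subsets of a 3x3 neighbourhood with <= 4 pixels
  cells <- expand.grid(r = 1:3, c = 1:3)
  for (k in 1:4) {
    combos <- utils::combn(9, k)
    for (j in seq_len(ncol(combos))) {
      m <- matrix(FALSE, 7, 7)
      m[cbind(cells$r[combos[, j]] + 2L, cells$c[combos[, j]] + 2L)] <- TRUE
      seg <- clean_marker_mask(m)
      lab <- brute_label8(m)
      sizes <- tabulate(lab[lab > 0])
      expect_equal(seg$A_M, sum(sizes[sizes >= 3]))
      # idempotence
      expect_equal(clean_marker_mask(seg$M)$M, seg$M)
      # anti-extensive
      expect_true(all(seg$M <= m))
    }
  }
})

test_that("marker density is the area ratio, with ROI clipping", {
  tmask <- matrix(FALSE, 40, 50); tmask[1:40, 1:25] <- TRUE   # TA = 1000
  m <- matrix(FALSE, 40, 50)
  m[1:2, 1:5] <- TRUE                                          # 10 px, one blob
  seg <- clean_marker_mask(m)
  d <- marker_density(seg, tissue_region(tmask))
  expect_equal(d$percent, 1.0)
  # ROI of a quarter of the tissue holding half the markers
  roi <- matrix(FALSE, 40, 50); roi[1:10, 1:25] <- TRUE
  dr <- marker_density(seg, roi)
  expect_equal(dr$DM_T, sum(m & roi) / sum(roi))
  expect_error(marker_density(seg, matrix(FALSE, 40, 50)), "zero-area")
})

test_that("empty markers give zero density", {
  seg <- clean_marker_mask(matrix(FALSE, 5, 5))
  expect_equal(marker_density(seg, matrix(TRUE, 5, 5))$DM_T, 0)
})

test_that("minimum-distance histograms match brute force and the band filter", {
  border <- matrix(FALSE, 20, 20); border[, 1] <- TRUE
  m <- matrix(FALSE, 20, 20)
  m[cbind(c(3, 9, 4, 11), c(2, 2, 4, 4))] <- TRUE   # distances 1,1,3,3
  h <- min_distance_histogram(m, border)
  expect_equal(sum(h$frequencies), 1)
  expect_equal(h$frequencies[c(2, 4)], c(0.5, 0.5))   # bins [1,2) and [3,4)
  # band limit 2 keeps only the two distance-1 pixels
  h2 <- min_distance_histogram(m, border, band_limit_px = 2)
  expect_equal(h2$n, 2)
  expect_equal(h2$frequencies[2], 1)
  # all markers on the border: all mass in bin 0
  h3 <- min_distance_histogram(border, border)
  expect_equal(h3$frequencies[1], 1)
  expect_error(min_distance_histogram(m, matrix(FALSE, 20, 20)), "empty border")
  expect_error(min_distance_histogram(m, border, band_limit_px = 0.5),
               "within the band")
})

test_that("random histograms equal the all-pairs brute force", {
  set.seed(71)
  for (i in 1:5) {
    border <- random_mask(30, 30, 0.05)
    m <- random_mask(30, 30, 0.1)
    if (!any(border) || !any(m)) next
    h <- min_distance_histogram(m, border)
    ref <- brute_min_dist(which(m, arr.ind = TRUE), border)
    rc <- tabulate(floor(ref) + 1L, nbins = length(h$frequencies))
    expect_equal(h$frequencies, rc / sum(rc), tolerance = 1e-12)
  }
})

test_that("mean histograms average per-bin with equal image weights", {
  mk <- function(f) structure(list(breaks = seq(0, length(f)), mids = seq_along(f) - 0.5,
                                   frequencies = f, n = 10, bin_width_px = 1,
                                   band_limit_px = Inf), class = "distance_histogram")
  h1 <- mk(c(1, 0)); h2 <- mk(c(0, 1))
  m <- mean_histogram(list(h1, h2))
  expect_equal(m$frequencies, c(0.5, 0.5))
  expect_equal(mean_histogram(list(h1, h1))$frequencies, h1$frequencies)
  set.seed(72)
  fs <- lapply(1:3, function(i) { x <- runif(4); x / sum(x) })
  m3 <- mean_histogram(lapply(fs, mk))
  expect_equal(m3$frequencies, Reduce(`+`, fs) / 3)
  expect_equal(sum(m3$frequencies), 1)
  hbad <- mk(c(1, 0)); hbad$bin_width_px <- 2
  expect_error(mean_histogram(list(h1, hbad)), "mixed")
})

test_that("histogram intersection has the similarity-measure properties", {
  mk <- function(f) structure(list(breaks = seq(0, length(f)), mids = seq_along(f) - 0.5,
                                   frequencies = f, n = 10, bin_width_px = 1,
                                   band_limit_px = Inf), class = "distance_histogram")
  h1 <- mk(c(0.7, 0.3)); h2 <- mk(c(0.4, 0.6))
  expect_equal(histogram_intersection(h1, h2), 0.7)
  expect_equal(histogram_intersection(h1, h1), 1)
  expect_equal(histogram_intersection(mk(c(1, 0)), mk(c(0, 1))), 0)
  set.seed(73)
  for (i in 1:20) {
    a <- mk({ x <- runif(5); x / sum(x) })
    b <- mk({ x <- runif(5); x / sum(x) })
    s <- histogram_intersection(a, b)
    expect_equal(s, histogram_intersection(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    if (s == 1) expect_equal(a$frequencies, b$frequencies)
  }
})
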