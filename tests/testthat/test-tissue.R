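test_that("smoothing is the identity on constant images", {
  img <- array(128, c(60, 60, 3))
  sm <- smooth_gray(img)
  expect_equal(max(abs(sm$gray - 128)), 0, tolerance = 1e-6)
})

test_that("salt noise is removed by the wide median filter", {
  img <- array(40, c(80, 80, 3))
  img[40, 40, ] <- 255
  sm <- smooth_gray(img)
  expect_lt(max(abs(sm$gray - 40)), 1)
})

test_that("oversized images are downsampled to the dimension limit", {
  img <- array(100, c(30, 120, 3))
  sm <- smooth_gray(img, downsample_limit = 50, median_size = 3)
  expect_lte(max(dim(sm$gray)), 50)
  # aspect ratio preserved within rounding
  expect_equal(dim(sm$gray)[1] / dim(sm$gray)[2], 30 / 120, tolerance = 0.1)
})

test_that("Otsu separates a bimodal image at the oracle threshold", {
  set.seed(21)
  g <- matrix(sample(c(50, 220), 400, replace = TRUE), 20, 20)
  img <- array(rep(g, 3), c(20, 20, 3))
  sm <- smooth_gray(img, median_size = 1, gaussian_sigma = 0)
  mask <- otsu_tissue_mask(sm)
  # exhaustive Otsu criterion scan: best threshold must split the two modes
  vals <- as.vector(g)
  between <- function(t) {
    w0 <- mean(vals <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(vals[vals <= t]) - mean(vals[vals > t]))^2
  }
  best <- which.max(vapply(0:254, between, numeric(1))) - 1
  expect_true(best >= 50 && best < 220)
  expect_equal(mask, g == 50, ignore_attr = TRUE)
})

test_that("a dark disk on a white field is recovered", {
  img <- array(245, c(120, 120, 3))
  rr <- matrix(seq_len(120), 120, 120) - 60
  cc <- t(rr)
  disk <- sqrt(rr^2 + cc^2) <= 35
  for (k in 1:3) { pl <- img[, , k]; pl[disk] <- 90; img[, , k] <- pl }
  mask <- otsu_tissue_mask(smooth_gray(img))
  expect_gte(dice(mask, disk), 0.95)
})

test_that("constant images raise a no-tissue error", {
  img <- array(100, c(20, 20, 3))
  expect_error(otsu_tissue_mask(smooth_gray(img, median_size = 1)), "constant")
})

test_that("border refinement removes exactly the pixels brighter than the cut", {
  # constructed background stats: mean 240, sd 10 -> cut at 245
  mask <- matrix(FALSE, 10, 10); mask[3:8, 3:8] <- TRUE
  gray <- matrix(240, 10, 10)
  gray[3, 3] <- 246   # above cut: removed
  gray[4, 4] <- 200   # kept
  st <- list(mean_back = 240, std_back = 10)
  out <- refine_border(mask, gray, stats = st)
  expect_false(out[3, 3])
  expect_true(out[4, 4])
  expect_equal(out, mask & gray <= 245, ignore_attr = TRUE)
})

test_that("refinement is anti-extensive and idempotent for fixed stats", {
  set.seed(22)
  mask <- random_mask(30, 30, 0.5)
  gray <- matrix(runif(900, 0, 255), 30, 30)
  st <- list(mean_back = 150, std_back = 20)
  once <- refine_border(mask, gray, stats = st)
  expect_true(all(once <= mask))
  expect_equal(refine_border(once, gray, stats = st), once)
})

test_that("zero background spread keeps darker-than-mean tissue untouched", {
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  gray <- matrix(200, 8, 8); gray[mask] <- 100
  out <- refine_border(mask, gray, stats = list(mean_back = 200, std_back = 0))
  expect_equal(out, mask, ignore_attr = TRUE)
})

test_that("cleaning fills holes, drops specks and filaments, and crops tight", {
  m <- matrix(FALSE, 100, 100)
  m[20:59, 20:59] <- TRUE          # 1600-px blob
  m[30, 30] <- FALSE               # small hole -> filled
  m[80, 80] <- TRUE                # 1-px speck -> removed (area)
  m[90, 5:95] <- TRUE              # filament: compactness ~ 4*pi*91/184^2 < 0.05
  tr <- clean_mask(m, min_area_frac = 0.0005, min_compactness = 0.05)
  expect_equal(tr$TA, 1600)
  expect_true(tr$mask[30, 30])
  expect_false(tr$mask[80, 80])
  expect_false(any(tr$mask[90, ]))
  expect_equal(tr$crop_box, c(20, 20, 59, 59))
  expect_equal(sum(tr$cropped), tr$TA)   # cropping preserves TA
  expect_error(clean_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("end-to-end tissue segmentation reaches Dice >= 0.95 on fixtures", {
  set.seed(30)
  for (seed in c(101, 202, 303)) {
    sec <- generate_section(synthetic_spec(seed = seed))
    tr <- segment_tissue(sec$image)
    expect_gte(dice(tr$mask, sec$tissue), 0.95)
  }
})
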