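test_that("distance maps match brute force and mask semantics", {
  set.seed(91)
  tmask <- matrix(TRUE, 32, 32)
  m <- random_mask(32, 32, 0.03)
  if (!any(m)) m[10, 10] <- TRUE
  d <- distance_map(tmask, m)
  coords <- which(tmask, arr.ind = TRUE)
  expect_equal(d[coords], brute_min_dist(coords, m), tolerance = 1e-12)
  expect_true(all(d[m] == 0))
  # all-marker tissue: all zero
  expect_true(all(distance_map(tmask, tmask) == 0))
  # outside tissue is NA
  tm2 <- matrix(FALSE, 32, 32); tm2[1:16, ] <- TRUE
  d2 <- distance_map(tm2, m)
  expect_true(all(is.na(d2[17:32, ])))
  expect_error(distance_map(tmask, matrix(FALSE, 32, 32)), "empty marker")
})

test_that("R estimation: cap binds for sparse markers, not for dense ones", {
  # constructed map: peak of the histogram far out, cumulative cap binding
  tmask <- matrix(TRUE, 64, 64)
  m <- matrix(FALSE, 64, 64); m[32, 32] <- m[32, 33] <- m[33, 32] <- TRUE
  d <- distance_map(tmask, m)
  A_M <- 3
  est <- estimate_R(d, A_M)
  # by construction #\{d < r\} grows ~ pi r^2; cap 50*3 = 150 -> R_LIMIT ~ 7
  cum <- vapply(1:30, function(r) sum(d < r), numeric(1))
  expect_equal(est$R_LIMIT, max(which(cum < 50 * A_M)))
  expect_equal(est$R, min(est$R_LIMIT, est$R_MAX))
  expect_lt(est$R, est$R_MAX)    # the cap binds here
  # dense markers: A_M >= tissue/50 means the cap can never bind
  md <- matrix(FALSE, 64, 64); md[seq(2, 63, 4), seq(2, 63, 4)] <- TRUE
  dd <- distance_map(tmask, md)
  estd <- estimate_R(dd, sum(md) * 50)   # inflate A_M so cap is unreachable
  expect_equal(estd$R, max(1, estd$R_MAX))
})

test_that("a uniform dot grid with spacing d peaks near d/2", {
  tmask <- matrix(TRUE, 96, 96)
  m <- matrix(FALSE, 96, 96)
  m[seq(4, 93, 12), seq(4, 93, 12)] <- TRUE   # spacing 12
  d <- distance_map(tmask, m)
  est <- estimate_R(d, sum(m))
  expect_gte(est$R_MAX, 4); expect_lte(est$R_MAX, 8)
})

test_that("planted clusters yield exactly two concentration regions", {
  sec <- fixture_cluster_section()
  seg <- clean_marker_mask(sec$marker)
  dmap <- distance_map(sec$tissue, seg)
  est <- estimate_R(dmap, seg$A_M)
  cr <- concentration_regions(sec$tissue, seg, est)
  expect_length(cr$CA_i, 2)
  expect_true(all(cr$CA_i >= 20 * est$R^2))
  # nesting: filtered core within regions within the R-dilation
  expect_true(all(cr$mask[cr$core & cr$mask]))
  expect_true(all((!is.na(dmap) & dmap < est$R)[cr$mask]))
  # every region contains at least one marker pixel
  for (j in seq_along(cr$CA_i)) expect_gt(sum(seg$M[cr$labels == j]), 0)
  # IoU >= 0.8 against ground-truth cluster discs dilated by R
  for (k in 1:2) {
    dots <- sec$dot_centers[sec$dot_cluster == k, , drop = FALSE]
    dm <- matrix(FALSE, 320, 320); dm[dots] <- TRUE
    gtm <- distance_to_mask(dm) < est$R + 1 & sec$tissue
    ious <- vapply(seq_along(cr$CA_i), function(j) {
      reg <- cr$labels == j
      sum(reg & gtm) / sum(reg | gtm)
    }, numeric(1))
    expect_gte(max(ious), 0.8)
  }
})

test_that("a single tiny dot yields no region; empty markers give empty sets", {
  tmask <- matrix(TRUE, 64, 64)
  m <- matrix(FALSE, 64, 64); m[30, 30] <- m[30, 31] <- m[31, 30] <- TRUE
  cr <- concentration_regions(tmask, m, R = 12)
  expect_length(cr$CA_i, 0)   # core area ~ pi*(R/2)^2 < 10 (R/2)^2
  expect_equal(cr$CA, 0)
  cr0 <- concentration_regions(tmask, matrix(FALSE, 64, 64))
  expect_length(cr0$CA_i, 0)
})

test_that("identical sections with identical regions give wMean_AVG = 100%", {
  sec <- fixture_cluster_section()
  seg <- clean_marker_mask(sec$marker)
  # identical sections and identical concentration regions that contain the
  # markers: every percentage is forced to 1 by the definitions
  reg_mask <- distance_to_mask(seg$M) < 8 & sec$tissue
  mk <- structure(list(labels = matrix(as.integer(reg_mask), nrow(reg_mask)),
                       mask = reg_mask, CA = sum(reg_mask), CA_i = sum(reg_mask),
                       R = 8, core = reg_mask), class = "concentration_regions")
  rs <- list(tissue_masks = list(sec$tissue, sec$tissue),
             marker_masks = list(seg$M, seg$M))
  rep <- coexistence_report(rs, regions = list(mk, mk))
  expect_equal(rep$pairs$w, 1)
  expect_equal(rep$pairs$PM_iInCj, 1)
  expect_equal(rep$pairs$PM_jInCi, 1)
  expect_equal(rep$pairs$wMean_AVG_percent, 100)
  # with automatically extracted regions the measures stay symmetric
  rep2 <- coexistence_report(rs)
  expect_equal(rep2$pairs$w, 1)
  expect_equal(rep2$pairs$PM_iInCj, rep2$pairs$PM_jInCi)
})

test_that("co-existence fields equal a brute-force counting oracle", {
  set.seed(92)
  for (i in 1:5) {
    tmask <- matrix(TRUE, 48, 48)
    m1 <- random_mask(48, 48, 0.05); m2 <- random_mask(48, 48, 0.07)
    c1 <- matrix(FALSE, 48, 48); c1[10:30, 10:30] <- TRUE
    c2 <- matrix(FALSE, 48, 48); c2[20:44, 18:40] <- TRUE
    mk_regions <- function(mask) structure(
      list(labels = matrix(as.integer(mask), 48, 48), mask = mask,
           CA = sum(mask), CA_i = sum(mask), R = 5, core = mask),
      class = "concentration_regions")
    rs <- list(tissue_masks = list(tmask, tmask),
               marker_masks = list(m1, m2))
    rep <- coexistence_report(rs, regions = list(mk_regions(c1), mk_regions(c2)))
    # oracle by explicit pixel counting
    A1 <- sum(m1); A2 <- sum(m2); CA1 <- sum(c1); CA2 <- sum(c2)
    A12 <- sum(m1 & c2); A21 <- sum(m2 & c1)
    expect_equal(rep$per_marker$DM_T, c(A1, A2) / (48 * 48), tolerance = 1e-12)
    expect_equal(rep$per_marker$DM_C, c(A1 / CA1, A2 / CA2), tolerance = 1e-12)
    p <- rep$pairs
    expect_equal(p$DM_iInCj, A12 / CA2, tolerance = 1e-12)
    expect_equal(p$DM_jInCi, A21 / CA1, tolerance = 1e-12)
    expect_equal(p$PM_iInCj, A12 / A1, tolerance = 1e-12)
    expect_equal(p$PM_jInCi, A21 / A2, tolerance = 1e-12)
    w <- min(A1 / CA1, A2 / CA2) / max(A1 / CA1, A2 / CA2)
    expect_equal(p$w, w, tolerance = 1e-12)
    expect_equal(p$wMean_Dens, w * (A12 / CA2 + A21 / CA1) / 2, tolerance = 1e-12)
    expect_equal(p$wMean_AVG, w * (A12 / A1 + A21 / A2) / 2, tolerance = 1e-12)
  }
})

test_that("the balance weight w follows the density-ratio formula", {
  # densities like the published concentration-region example (6.98% vs 9.44%)
  expect_equal(min(6.98, 9.44) / max(6.98, 9.44), 6.98 / 9.44)
  w <- min(0.0698, 0.0944) / max(0.0698, 0.0944)
  expect_equal(w, 0.7394, tolerance = 1e-4)
})

test_that("undefined measures are NA, never zero, and ROI restricts denominators", {
  tmask <- matrix(TRUE, 32, 32)
  m1 <- matrix(FALSE, 32, 32); m1[5:8, 5:8] <- TRUE
  m2 <- matrix(FALSE, 32, 32)                      # empty second marker
  rs <- list(tissue_masks = list(tmask, tmask), marker_masks = list(m1, m2))
  rep <- coexistence_report(rs)
  expect_true(is.na(rep$pairs$PM_jInCi))
  expect_true(is.na(rep$pairs$w))
  # ROI: denominators switch to the ROI area
  m2b <- matrix(FALSE, 32, 32); m2b[6:9, 6:9] <- TRUE
  rs2 <- list(tissue_masks = list(tmask, tmask), marker_masks = list(m1, m2b))
  roi <- c(1, 1, 16, 16)
  rep2 <- coexistence_report(rs2, roi = roi)
  expect_equal(rep2$per_marker$TA, c(256, 256))
  expect_equal(rep2$per_marker$DM_T[1], 16 / 256)
})
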