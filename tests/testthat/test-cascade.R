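test_that("per-fold sample counts follow the cardinality formulas", {
  expect_equal(fold_negative_count(100, 10000, 10), 500)  # min(1000, 500)
  expect_equal(fold_negative_count(100, 3000, 10), 300)   # min(300, 500)
  set.seed(61)
  for (i in 1:30) {
    Npos <- sample(1:500, 1); Nneg <- sample(1:20000, 1)
    folds <- sample(c(2, 10), 1)
    expect_equal(fold_negative_count(Npos, Nneg, folds),
                 min(ceiling(Nneg / folds), 5 * Npos, Nneg))
    expect_equal(fold_positive_count(Npos, folds),
                 min(Npos, ceiling(Npos / folds)))
  }
})

test_that("hard-negative mining returns exactly the false positives", {
  fx <- fixture_trained_cascade()
  layer1 <- fx$model$layers[[1]]
  neg <- fx$training_set$obvious_negatives
  mined <- mine_hard_negatives(layer1, neg)
  pred <- histoquant:::predict_layer(layer1, neg)
  expect_equal(nrow(mined), sum(pred == "1"))
  # empty input passes through
  expect_equal(nrow(mine_hard_negatives(layer1, neg[0, , drop = FALSE])), 0)
})

test_that("layer training subsets are nested by construction", {
  fx <- fixture_trained_cascade()
  counts <- vapply(fx$model$layers, function(l) l$counts[["Nneg"]], numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], fx$training_set$Nneg)
})

test_that("training is deterministic under a fixed seed", {
  ts <- fixture_trained_cascade()$training_set
  m1 <- train_cascade(ts, seed = 17)
  m2 <- train_cascade(ts, seed = 17)
  f1 <- tempfile(); f2 <- tempfile()
  save_cascade(m1, f1); save_cascade(m2, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("models serialize and reload intact", {
  fx <- fixture_trained_cascade()
  f <- tempfile(fileext = ".rds")
  save_cascade(fx$model, f)
  m <- load_cascade(f)
  sec <- fixture_section(11)
  expect_identical(apply_cascade(m, sec$image, sec$tissue, planes = fx$planes),
                   apply_cascade(fx$model, sec$image, sec$tissue, planes = fx$planes))
  unlink(f)
})

test_that("cascade acceptance equals the intersection of layer acceptances", {
  fx <- fixture_trained_cascade()
  sec <- generate_section(synthetic_spec(seed = 77))
  planes <- compute_feature_planes(sec$image)
  mask <- apply_cascade(fx$model, sec$image, sec$tissue, planes = planes)
  coords <- which(sec$tissue, arr.ind = TRUE)
  X <- extract_vectors(planes, coords)
  inter <- rep(TRUE, nrow(X))
  for (i in 1:4) {
    Xi <- if (fx$model$layers[[i]]$type == "knn") X[, c("R", "G", "B")] else X
    inter <- inter & (histoquant:::predict_layer(fx$model$layers[[i]], Xi) == "1")
  }
  got <- mask[coords]
  expect_equal(got, inter)
  # monotone workload is implied: acceptance shrinks layer by layer
  expect_true(all(!mask[!sec$tissue]))
})

test_that("empty tissue gives an empty marker mask", {
  fx <- fixture_trained_cascade()
  sec <- fixture_section(11)
  empty <- matrix(FALSE, nrow(sec$tissue), ncol(sec$tissue))
  expect_equal(sum(apply_cascade(fx$model, sec$image, empty)), 0)
})

test_that("feature-configuration mismatches are detected", {
  fx <- fixture_trained_cascade()
  sec <- fixture_section(11)
  planes_wrong <- compute_feature_planes(sec$image, sizes = 3)
  expect_error(apply_cascade(fx$model, sec$image, sec$tissue,
                             planes = planes_wrong), "mismatch")
})

test_that("held-out recovery: F1 >= 0.95 and distractor FPR <= 1%", {
  fx <- fixture_trained_cascade()
  for (seed in c(99, 123)) {
    sec <- generate_section(synthetic_spec(seed = seed))
    seg <- clean_marker_mask(apply_cascade(fx$model, sec$image, sec$tissue))
    tp <- sum(seg$M & sec$marker)
    fp <- sum(seg$M & !sec$marker)
    fn <- sum(!seg$M & sec$marker)
    f1 <- 2 * tp / (2 * tp + fp + fn)
    expect_gte(f1, 0.95)
    expect_lte(mean(seg$M[sec$classes$distractor]), 0.01)
  }
})
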