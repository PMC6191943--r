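#' Stacked cost-sensitive marker-pixel classifier
#'
#' The classifier is a rejection cascade of four layers: two cost-sensitive
#' decision trees, a cost-sensitive RBF support vector machine, and a plain
#' K-nearest-neighbour classifier (K = 3) working on raw RGB only. Each layer
#' discards the pixels it recognises as not-marker and passes the surviving
#' candidates on; a pixel is a marker pixel only if all four layers accept
#' it. Layers after the first are trained by hard-negative mining: only the
#' obvious negatives that earlier layers misclassify (false positives) are
#' kept, together with all positives and all critical negatives, so each
#' layer concentrates on the mistakes of its predecessors.
#'
#' @name cascade-classifier
NULL

as_label_factor <- function(labels) factor(labels, levels = c("0", "1"))

train_one_dt <- function(X, y, cost) {
  df <- data.frame(X, check.names = FALSE)
  names(df) <- make.names(names(df))
  df$.y <- as_label_factor(y)
  model <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(loss = cost))
  # drop the construction environment so models serialize compactly and
  # reproducibly; prediction only needs the frame/terms structure
  attr(model$terms, ".Environment") <- globalenv()
  model$call <- quote(rpart::rpart())
  model
}

predict_dt <- function(model, X) {
  df <- data.frame(X, check.names = FALSE)
  names(df) <- make.names(names(df))
  as.character(stats::predict(model, df, type = "class"))
}

#' Cross-validated training of one cost-sensitive layer
#'
#' Builds `folds` candidate classifiers. Each candidate is trained on
#' ceiling(Npos/folds) randomly selected positives and
#' min(ceiling(Nneg/folds), 5 * Npos) randomly selected negatives; all
#' remaining samples form its validation set. The candidate with the maximum
#' (plain, unweighted) validation accuracy is returned; ties go to the first
#' candidate. A fold that ends up with an empty class is redrawn, up to 5
#' attempts.
#'
#' @param positives,negatives feature matrices (rows = samples).
#' @param cost 2 x 2 cost matrix from [cost_matrix()].
#' @param folds number of candidates (10 for the decision trees, 2 for the
#'   SVM).
#' @param trainer function(X, y, cost) -> model; `predictor`
#'   function(model, X) -> character labels.
#' @param predictor see `trainer`.
#' @return list with `model`, `accuracy`, `fold_sizes`.
#' @export
train_layer_cv <- function(positives, negatives, cost, folds,
                           trainer = train_one_dt, predictor = predict_dt) {
  Npos <- nrow(positives); Nneg <- nrow(negatives)
  if (Npos == 0 || Nneg == 0) stop("train_layer_cv(): a class is empty")
  n_pos_fold <- fold_positive_count(Npos, folds)
  n_neg_fold <- fold_negative_count(Npos, Nneg, folds)
  best <- NULL
  for (f in seq_len(folds)) {
    for (attempt in 1:5) {
      ip <- sample.int(Npos, n_pos_fold)
      ineg <- sample.int(Nneg, n_neg_fold)
      if (length(ip) && length(ineg)) break
      if (attempt == 5) stop("train_layer_cv(): empty class in fold after 5 attempts")
    }
    Xtr <- rbind(positives[ip, , drop = FALSE], negatives[ineg, , drop = FALSE])
    ytr <- c(rep("1", length(ip)), rep("0", length(ineg)))
    Xva <- rbind(positives[-ip, , drop = FALSE], negatives[-ineg, , drop = FALSE])
    yva <- c(rep("1", Npos - length(ip)), rep("0", Nneg - length(ineg)))
    if (!nrow(Xva)) { Xva <- Xtr; yva <- ytr }   # degenerate tiny sets
    model <- trainer(Xtr, ytr, cost)
    acc <- mean(predictor(model, Xva) == yva)
    if (is.null(best) || acc > best$accuracy)
      best <- list(model = model, accuracy = acc,
                   fold_sizes = c(pos = n_pos_fold, neg = n_neg_fold))
  }
  best
}

#' @describeIn train_layer_cv Positives per fold: ceiling(Npos / folds).
#' @param Npos,Nneg class cardinalities.
#' @export
fold_positive_count <- function(Npos, folds) min(Npos, ceiling(Npos / folds))

#' @describeIn train_layer_cv Negatives per fold:
#'   min(ceiling(Nneg / folds), 5 * Npos).
#' @export
fold_negative_count <- function(Npos, Nneg, folds)
  min(ceiling(Nneg / folds), 5 * Npos, Nneg)

svm_trainer <- function(C_grid = c(1, 10, 100), gamma_grid = NULL) {
  function(X, y, cost) {
    w <- c("0" = cost["0", "1"], "1" = cost["1", "0"])
    if (all(w == 0)) w <- c("0" = 1, "1" = 1)
    w <- w / max(w)
    gs <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-8))
    gammas <- if (is.null(gamma_grid)) unique(c(gs, 0.01, 0.1)) else gamma_grid
    best <- NULL
    yf <- as_label_factor(y)
    for (C in C_grid) for (g in gammas) {
      m <- e1071::svm(X, yf, kernel = "radial", cost = C, gamma = g,
                      class.weights = w, scale = TRUE)
      acc <- mean(as.character(stats::predict(m, X)) == y)
      if (is.null(best) || acc > best$acc) best <- list(m = m, acc = acc)
    }
    best$m$call <- quote(e1071::svm())
    best$m
  }
}

predict_svm <- function(model, X) as.character(stats::predict(model, X))

knn_layer <- function(positives_rgb, critical_rgb, mined_rgb) {
  train <- rbind(positives_rgb, critical_rgb, mined_rgb)
  labels <- as_label_factor(c(rep("1", nrow(positives_rgb)),
                              rep("0", nrow(critical_rgb) + nrow(mined_rgb))))
  list(train = train, labels = labels, k = 3L)
}

predict_knn <- function(layer, X3) {
  as.character(class::knn(layer$train, X3, layer$labels, k = layer$k,
                          use.all = TRUE))
}

#' Hard-negative mining: keep the false positives of a layer
#'
#' @param layer a trained cascade layer (list with `type` and `model`).
#' @param negatives feature matrix of negatives in the layer's feature space.
#' @return the rows of `negatives` that the layer classifies as positive.
#' @export
mine_hard_negatives <- function(layer, negatives) {
  if (!nrow(negatives)) return(negatives)
  keep <- predict_layer(layer, negatives) == "1"
  negatives[keep, , drop = FALSE]
}

predict_layer <- function(layer, X) {
  switch(layer$type,
         dt = predict_dt(layer$model, X),
         svm = predict_svm(layer$model, X),
         knn = predict_knn(layer$model, X),
         stop("unknown layer type ", layer$type))
}

rgb_cols <- function(X) X[, c("R", "G", "B"), drop = FALSE]

#' Train the four-layer cascade
#'
#' Layer 1 (decision tree) sees all positives and all negatives (critical +
#' obvious) and is selected by 10-fold cross-validation. The obvious
#' negatives it misclassifies are the only obvious negatives kept for layer 2
#' (decision tree, 10-fold); those layer 2 misclassifies feed the SVM
#' (2-fold, RBF kernel, small C/gamma grid); those the SVM misclassifies
#' feed the KNN, which is trained on raw RGB with K = 3 and no cost
#' sensitivity. All positives and all critical negatives are kept at every
#' layer, and every layer's cost matrix is recomputed from its actual class
#' counts. Obvious negatives reaching the SVM are capped at `svm_neg_cap *
#' Npos` by seeded subsampling to bound training cost.
#'
#' @param ts a `training_set` from [assemble_training_set()].
#' @param sizes neighbourhood sizes the feature vectors were computed with
#'   (stored in the model so prediction always agrees with training).
#' @param seed integer seed; the same seed gives an identical model.
#' @param svm_neg_cap cap on obvious negatives entering the SVM, in units of
#'   Npos.
#' @return object of class `cascade_model`.
#' @export
train_cascade <- function(ts, sizes = c(3, 7), seed = 1L, svm_neg_cap = 20) {
  stopifnot(inherits(ts, "training_set"))
  set.seed(seed)
  pos <- ts$positives
  crit <- ts$critical_negatives
  obv <- ts$obvious_negatives
  layers <- vector("list", 4)

  with_crit <- function(mined) rbind(crit, mined)
  counts <- function(mined) c(Npos = nrow(pos), Ncrit = nrow(crit),
                              Nneg = nrow(mined))

  train_dt_layer <- function(mined_obv, folds) {
    cost <- cost_matrix(nrow(pos), nrow(mined_obv), nrow(crit))
    negs <- with_crit(mined_obv)
    if (!nrow(negs)) stop("train_cascade(): no negatives at a DT layer")
    fit <- train_layer_cv(pos, negs, cost, folds)
    list(type = "dt", model = fit$model, cost = cost, counts = counts(mined_obv),
         cv_accuracy = fit$accuracy, fold_sizes = fit$fold_sizes)
  }

  # layer 1: DT on the full, unbalanced set
  layers[[1]] <- train_dt_layer(obv, folds = 10)
  mined1 <- mine_hard_negatives(layers[[1]], obv)

  # layer 2: DT on positives + criticals + layer-1 false positives
  if (!nrow(mined1))
    warning("train_cascade(): layer 1 left no obvious negatives; layer 2 uses criticals only")
  layers[[2]] <- train_dt_layer(mined1, folds = 10)
  mined2 <- mine_hard_negatives(layers[[2]], mined1)

  # layer 3: cost-sensitive RBF SVM, 2-fold CV, capped negatives
  if (nrow(mined2) > svm_neg_cap * nrow(pos)) {
    keep <- sample.int(nrow(mined2), svm_neg_cap * nrow(pos))
    mined2 <- mined2[keep, , drop = FALSE]
  }
  cost3 <- cost_matrix(nrow(pos), nrow(mined2), nrow(crit))
  negs3 <- with_crit(mined2)
  fit3 <- train_layer_cv(pos, negs3, cost3, folds = 2,
                         trainer = svm_trainer(), predictor = predict_svm)
  layers[[3]] <- list(type = "svm", model = fit3$model, cost = cost3,
                      counts = counts(mined2), cv_accuracy = fit3$accuracy,
                      fold_sizes = fit3$fold_sizes)
  mined3 <- mine_hard_negatives(layers[[3]], mined2)

  # layer 4: plain KNN (K = 3) on RGB only
  layers[[4]] <- list(type = "knn",
                      model = knn_layer(rgb_cols(pos), rgb_cols(crit),
                                        rgb_cols(mined3)),
                      cost = cost_matrix(nrow(pos), nrow(mined3), nrow(crit),
                                         knn = TRUE),
                      counts = counts(mined3))

  structure(list(layers = layers, sizes = sizes, seed = as.integer(seed),
                 feature_names = colnames(pos)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("cascade_model: DT -> DT -> SVM -> KNN(3)\n")
  for (i in 1:4) {
    ct <- x$layers[[i]]$counts
    cat(sprintf("  layer %d (%s): Npos=%d Ncrit=%d Nneg=%d\n", i,
                x$layers[[i]]$type, ct["Npos"], ct["Ncrit"], ct["Nneg"]))
  }
  invisible(x)
}

#' Apply the cascade to an image
#'
#' Only tissue pixels are evaluated; a pixel is a marker pixel iff all four
#' layers accept it. The KNN layer sees only the raw RGB triple; the other
#' layers see the full feature vector, computed with the neighbourhood sizes
#' stored in the model.
#'
#' @param model a `cascade_model`.
#' @param img H x W x 3 array.
#' @param tissue `tissue_region` or logical mask; pixels outside are
#'   negative by definition.
#' @param planes optional pre-computed feature planes (must match the
#'   model's sizes).
#' @return raw (uncleaned) marker mask, logical matrix.
#' @export
apply_cascade <- function(model, img, tissue, planes = NULL) {
  stopifnot(inherits(model, "cascade_model"))
  mask <- if (inherits(tissue, "tissue_region")) tissue$mask else tissue
  stopifnot(identical(dim(mask), dim(img)[1:2]))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!any(mask)) return(out)
  if (is.null(planes)) planes <- compute_feature_planes(img, model$sizes)
  if (!identical(attr(planes, "sizes"), model$sizes))
    stop("apply_cascade(): feature configuration mismatch")
  coords <- which(mask, arr.ind = TRUE)
  X <- extract_vectors(planes, coords)
  alive <- rep(TRUE, nrow(coords))
  for (i in 1:4) {
    if (!any(alive)) break
    Xi <- if (model$layers[[i]]$type == "knn")
      rgb_cols(X[alive, , drop = FALSE]) else X[alive, , drop = FALSE]
    pred <- predict_layer(model$layers[[i]], Xi)
    alive[alive] <- pred == "1"
  }
  out[coords[alive, , drop = FALSE]] <- TRUE
  out
}

#' Save / load a trained cascade model
#'
#' @param model a `cascade_model`; `path` file path.
#' @param path file path.
#' @export
save_cascade <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cascade_model"))
  m
}
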