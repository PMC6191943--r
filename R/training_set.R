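#' Pixel annotations for classifier training
#'
#' Annotations live in a CSV with columns `image, class, row, col, row2,
#' col2`. Three classes are understood:
#' * `marker` - positive pixels (the stain to segment); `row`/`col` only.
#' * `critical` - not-marker pixels whose colour mimics the stain (ink,
#'   blood, folds); `row`/`col` only.
#' * `negative_rect` - rectangles containing only obvious not-marker pixels;
#'   bounds `[row, row2) x [col, col2)`, expanded to pixels on load.
#'
#' All coordinates are 0-based; rectangle bounds are inclusive-exclusive.
#'
#' @name annotations
NULL

#' @describeIn annotations Read and validate an annotation CSV.
#' @param path CSV path.
#' @param image_dims optional named list `image id -> c(rows, cols)` for
#'   bounds checking.
#' @return `annotation_set` object: list with `marker`, `critical` (each a
#'   data.frame image/row/col, 1-based internally) and `rects` (image, row0,
#'   col0, row1, col1, 1-based inclusive-exclusive).
#' @export
read_annotations <- function(path, image_dims = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_set(df, image_dims)
}

#' @describeIn annotations Build an `annotation_set` from a data.frame in the
#'   same format (as produced by [synthetic_annotations()]).
#' @param df annotation data.frame.
#' @export
annotation_set <- function(df, image_dims = NULL) {
  need <- c("image", "class", "row", "col")
  if (!all(need %in% names(df)))
    stop("annotations: missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  if (!"row2" %in% names(df)) df$row2 <- NA_integer_
  if (!"col2" %in% names(df)) df$col2 <- NA_integer_
  bad <- !df$class %in% c("marker", "critical", "negative_rect")
  if (any(bad)) stop("annotations: unknown class ", unique(df$class[bad])[1])
  pix <- df[df$class != "negative_rect", ]
  rects <- df[df$class == "negative_rect", ]
  if (nrow(rects) && any(is.na(rects$row2) | is.na(rects$col2) |
                         rects$row2 <= rects$row | rects$col2 <= rects$col))
    stop("annotations: degenerate rectangle")
  # 0-based file coordinates -> 1-based internal
  mk <- pix[pix$class == "marker", c("image", "row", "col")]
  cr <- pix[pix$class == "critical", c("image", "row", "col")]
  mk$row <- mk$row + 1L; mk$col <- mk$col + 1L
  cr$row <- cr$row + 1L; cr$col <- cr$col + 1L
  key <- function(d) paste(d$image, d$row, d$col)
  dup <- intersect(key(mk), key(cr))
  if (length(dup))
    stop("annotations: pixel annotated both marker and critical: ", dup[1])
  rects2 <- data.frame(image = rects$image,
                       row0 = rects$row + 1L, col0 = rects$col + 1L,
                       row1 = rects$row2 + 1L, col1 = rects$col2 + 1L)
  if (!is.null(image_dims)) {
    chk <- function(img, r, c, what) {
      d <- image_dims[[img]]
      if (is.null(d)) return(invisible())
      if (any(r < 1 | r > d[1] | c < 1 | c > d[2]))
        stop("annotations: ", what, " coordinate outside image ", img)
    }
    for (im in unique(mk$image)) chk(im, mk$row[mk$image == im], mk$col[mk$image == im], "marker")
    for (im in unique(cr$image)) chk(im, cr$row[cr$image == im], cr$col[cr$image == im], "critical")
    for (i in seq_len(nrow(rects2)))
      chk(rects2$image[i], c(rects2$row0[i], rects2$row1[i] - 1L),
          c(rects2$col0[i], rects2$col1[i] - 1L), "rectangle")
  }
  structure(list(marker = mk, critical = cr, rects = rects2),
            class = "annotation_set")
}

#' @describeIn annotations Write an `annotation_set` (or compatible
#'   data.frame) back to CSV (0-based coordinates).
#' @param ann `annotation_set`.
#' @export
write_annotations <- function(ann, path) {
  rows <- list()
  mk_df <- function(d, cls) data.frame(image = d$image, class = cls,
                                       row = d$row - 1L, col = d$col - 1L,
                                       row2 = NA_integer_, col2 = NA_integer_)
  if (nrow(ann$marker)) rows$m <- mk_df(ann$marker, "marker")
  if (nrow(ann$critical)) rows$c <- mk_df(ann$critical, "critical")
  if (nrow(ann$rects))
    rows$r <- data.frame(image = ann$rects$image, class = "negative_rect",
                         row = ann$rects$row0 - 1L, col = ann$rects$col0 - 1L,
                         row2 = ann$rects$row1 - 1L, col2 = ann$rects$col1 - 1L)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @describeIn annotations Expand a rectangle row to its contained pixels
#'   (1-based, inclusive-exclusive bounds).
#' @param rect one row of the `rects` data.frame.
#' @export
expand_rect <- function(rect) {
  as.matrix(expand.grid(row = rect$row0:(rect$row1 - 1L),
                        col = rect$col0:(rect$col1 - 1L)))
}

#' Assemble a labelled training set from annotations and feature planes
#'
#' Rectangles are expanded to obvious-negative pixels; pixels that coincide
#' with annotated positives or criticals are excluded from the negatives
#' (class disjointness wins). Reports the imbalance ratio
#' Npos / (Nneg + Ncrit).
#'
#' @param ann an `annotation_set`.
#' @param planes_by_image named list: image id -> feature planes from
#'   [compute_feature_planes()].
#' @return object of class `training_set`: list with feature matrices
#'   `positives`, `critical_negatives`, `obvious_negatives`, the RGB-only
#'   versions `positives_rgb` etc. (first three columns), counts `Npos`,
#'   `Ncrit`, `Nneg` and `imbalance_ratio`.
#' @export
assemble_training_set <- function(ann, planes_by_image) {
  get_feats <- function(df) {
    parts <- lapply(unique(df$image), function(im) {
      pl <- planes_by_image[[im]]
      if (is.null(pl)) stop("assemble_training_set(): no features for image ", im)
      sub <- df[df$image == im, ]
      extract_vectors(pl, cbind(sub$row, sub$col))
    })
    do.call(rbind, parts)
  }
  pos <- get_feats(ann$marker)
  crit <- if (nrow(ann$critical)) get_feats(ann$critical) else
    matrix(numeric(0), 0, ncol(pos))
  neg_list <- list()
  occupied <- paste(c(ann$marker$image, ann$critical$image),
                    c(ann$marker$row, ann$critical$row),
                    c(ann$marker$col, ann$critical$col))
  if (nrow(ann$rects)) {
    for (i in seq_len(nrow(ann$rects))) {
      px <- expand_rect(ann$rects[i, ])
      keep <- !(paste(ann$rects$image[i], px[, 1], px[, 2]) %in% occupied)
      neg_list[[i]] <- data.frame(image = ann$rects$image[i],
                                  row = px[keep, 1], col = px[keep, 2])
    }
  }
  neg_df <- do.call(rbind, neg_list)
  neg <- if (!is.null(neg_df) && nrow(neg_df)) get_feats(neg_df) else
    matrix(numeric(0), 0, ncol(pos))
  Npos <- nrow(pos); Ncrit <- nrow(crit); Nneg <- nrow(neg)
  if (Npos == 0) stop("assemble_training_set(): no positive samples")
  if (Nneg + Ncrit == 0) stop("assemble_training_set(): no negative samples")
  if (Ncrit == 0) warning("assemble_training_set(): no critical negatives")
  structure(list(positives = pos, critical_negatives = crit,
                 obvious_negatives = neg,
                 Npos = Npos, Ncrit = Ncrit, Nneg = Nneg,
                 imbalance_ratio = Npos / (Nneg + Ncrit)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: Npos=%d, Ncrit=%d, Nneg=%d (ratio %.4f)\n",
              x$Npos, x$Ncrit, x$Nneg, x$imbalance_ratio))
  invisible(x)
}

#' Misclassification cost matrix from class cardinalities
#'
#' Rows are the true class, columns the predicted class, in label order
#' (0 = not-marker, 1 = marker). The diagonal is zero and
#' Cost(predict 1 | true 0) = 1 - (Nneg + Ncrit) / N,
#' Cost(predict 0 | true 1) = 1 - Npos / N with N the total count, so the
#' minority class always carries the larger misclassification cost and the
#' two off-diagonals sum to 1. The KNN layer is not cost-sensitive: request
#' it with `knn = TRUE` to get unit off-diagonals.
#'
#' @param Npos,Nneg,Ncrit class cardinalities (>= 0, positive total).
#' @param knn if TRUE return the cost-neutral 0/1 matrix.
#' @return 2 x 2 numeric matrix with dimnames `true` x `predicted`.
#' @export
cost_matrix <- function(Npos, Nneg, Ncrit = 0, knn = FALSE) {
  N <- Npos + Nneg + Ncrit
  if (N <= 0) stop("cost_matrix(): empty training set")
  if (knn) {
    m <- matrix(c(0, 1, 1, 0), 2, 2)
  } else {
    m <- matrix(c(0, 1 - Npos / N,             # column "0": predicted negative
                  1 - (Nneg + Ncrit) / N, 0),  # column "1": predicted positive
                2, 2)
  }
  dimnames(m) <- list(true = c("0", "1"), predicted = c("0", "1"))
  m
}
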