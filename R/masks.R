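#' Binary mask utilities
#'
#' Masks are plain logical matrices (rows x columns). `mask_area()` counts
#' foreground pixels; `label_components()` labels connected components with
#' either 4- or 8-connectivity; `component_perimeter()` measures the contour
#' length of each component as the number of pixel edges shared between
#' foreground and background (4-neighbourhood), the discrete analogue of the
#' boundary length.
#'
#' @param mask logical matrix.
#' @name mask-utils
NULL

#' @rdname mask-utils
#' @return `mask_area()`: integer count of `TRUE` pixels.
#' @export
mask_area <- function(mask) {
  stopifnot(is.matrix(mask))
  sum(mask)
}

as_logical_mask <- function(x) {
  if (is.logical(x)) return(x)
  m <- x > 0
  storage.mode(m) <- "logical"
  m
}

#' @rdname mask-utils
#' @param connectivity 4 or 8.
#' @return `label_components()`: integer matrix, 0 for background, components
#'   numbered 1..n in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- as_logical_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(t(mask))            # 4-connected labelling
  lab <- t(matrix(as.integer(lab), nrow(t(mask)), ncol(t(mask))))
  if (connectivity == 8) {
    lab <- merge_diagonal_labels(lab)
  }
  relabel_sequential(lab)
}

# union-find merge of 4-connected labels that touch diagonally
merge_diagonal_labels <- function(lab) {
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

relabel_sequential <- function(lab) {
  ids <- unique(as.vector(lab[lab > 0]))
  if (!length(ids)) return(lab)
  # renumber in raster order of first occurrence (column-major of the matrix)
  lut <- integer(max(ids))
  lut[ids] <- match(ids, ids)
  out <- lab
  out[lab > 0] <- lut[lab[lab > 0]]
  out
}

#' @rdname mask-utils
#' @param labels integer label matrix from `label_components()`.
#' @return `component_perimeter()`: named numeric vector of edge counts per label.
#' @export
component_perimeter <- function(labels) {
  stopifnot(is.matrix(labels))
  n <- max(labels)
  if (n == 0) return(numeric(0))
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- labels
  per <- numeric(n)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad[(2:(H + 1)) + sh[1], (2:(W + 1)) + sh[2]]
    diff <- labels > 0 & nb != labels
    if (any(diff)) {
      tab <- tabulate(labels[diff], nbins = n)
      per <- per + tab
    }
  }
  stats::setNames(per, seq_len(n))
}

#' Exact Euclidean distance to the nearest foreground pixel
#'
#' Every pixel receives the Euclidean distance to the closest `TRUE` pixel of
#' `mask`; foreground pixels receive 0.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return numeric matrix of distances, same shape as `mask`.
#' @export
distance_to_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- as_logical_mask(mask)
  if (!any(mask)) stop("distance_to_mask(): mask is empty")
  # distmap() returns, for each non-zero pixel, the distance to the nearest
  # zero pixel; invert so targets are the zeros
  d <- EBImage::distmap(EBImage::Image(t(!mask) * 1), metric = "euclidean")
  t(matrix(as.numeric(d), ncol(mask), nrow(mask)))
}

#' Remove connected components smaller than a minimum area
#'
#' @param mask logical matrix.
#' @param min_area components with fewer pixels are dropped.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
remove_small_components <- function(mask, min_area, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(as_logical_mask(mask) & FALSE)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Fill holes of a binary mask up to a maximum hole area
#'
#' A hole is a background component not connected to the matrix border
#' (4-connectivity for the background, matching 8-connectivity foreground).
#'
#' @param mask logical matrix.
#' @param max_hole_area holes at most this large are filled; `Inf` fills all.
#' @return logical matrix.
#' @export
fill_small_holes <- function(mask, max_hole_area = Inf) {
  mask <- as_logical_mask(mask)
  fh <- EBImage::imageData(EBImage::fillHull(EBImage::Image(t(mask) * 1)))
  filled <- t(matrix(as.numeric(fh), nrow(fh), ncol(fh))) > 0
  holes <- filled & !mask
  if (!any(holes) || is.infinite(max_hole_area)) return(filled)
  lab <- label_components(holes, connectivity = 4)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  small <- which(areas <= max_hole_area)
  mask | matrix(lab %in% small, nrow(mask), ncol(mask))
}
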