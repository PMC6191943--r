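#' Per-pixel colour/neighbourhood features
#'
#' Every pixel is described by its RGB colour plus, for each configured odd
#' neighbourhood size n, the per-channel mean, population standard deviation
#' and local range (max - min) over the n x n window centred on the pixel.
#' Borders use replicate padding. The default sizes c(3, 7) give a
#' 3 + 9 * 2 = 21-dimensional vector; `sizes = 7` gives the minimal
#' 12-dimensional set.
#'
#' Plane order (fixed): R, G, B, then for each size n in order:
#' mu_nR, mu_nG, mu_nB, sigma_nR, sigma_nG, sigma_nB,
#' range_nR, range_nG, range_nB.
#'
#' @name pixel-features
NULL

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# exact box sum over an n x n window via integral image on the padded matrix
box_sum <- function(m, n) {
  r <- (n - 1L) %/% 2L
  p <- pad_replicate(m, r)
  ii <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  ii[-1, -1] <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  H <- nrow(m); W <- ncol(m)
  ii[(n + 1):(n + H), (n + 1):(n + W)] - ii[1:H, (n + 1):(n + W)] -
    ii[(n + 1):(n + H), 1:W] + ii[1:H, 1:W]
}

# separable running min/max over an n x n window (replicate padding)
box_extreme <- function(m, n, fun) {
  r <- (n - 1L) %/% 2L
  p <- pad_replicate(m, r)
  H <- nrow(m); W <- ncol(m)
  # rows pass
  acc <- p[1:H, , drop = FALSE]
  for (k in seq_len(2 * r)) acc <- fun(acc, p[(1:H) + k, , drop = FALSE])
  # cols pass
  out <- acc[, 1:W, drop = FALSE]
  for (k in seq_len(2 * r)) out <- fun(out, acc[, (1:W) + k, drop = FALSE])
  out
}

#' @describeIn pixel-features Compute all feature planes for an image.
#' @param img H x W x 3 array in \[0, 255\].
#' @param sizes odd neighbourhood sizes (default c(3, 7)).
#' @return `compute_feature_planes()`: H x W x D array with
#'   `dimnames[[3]]` naming each plane; attribute `sizes` records the config.
#' @export
compute_feature_planes <- function(img, sizes = c(3, 7)) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  if (any(sizes %% 2 == 0) || any(sizes < 3))
    stop("compute_feature_planes(): neighbourhood sizes must be odd and >= 3")
  H <- dim(img)[1]; W <- dim(img)[2]
  chan <- c("R", "G", "B")
  planes <- list(R = img[, , 1], G = img[, , 2], B = img[, , 3])
  for (n in sizes) {
    N <- n * n
    for (k in 1:3) {
      m <- img[, , k]
      s <- box_sum(m, n)
      s2 <- box_sum(m * m, n)
      mu <- s / N
      sig <- sqrt(pmax(s2 / N - mu^2, 0))
      planes[[paste0("mu_", n, chan[k])]] <- mu
      planes[[paste0("sigma_", n, chan[k])]] <- sig
      planes[[paste0("range_", n, chan[k])]] <-
        box_extreme(m, n, pmax) - box_extreme(m, n, pmin)
    }
    # reorder channel-major within size: mu R G B, sigma R G B, range R G B
  }
  ord <- c(chan, unlist(lapply(sizes, function(n)
    c(paste0("mu_", n, chan), paste0("sigma_", n, chan),
      paste0("range_", n, chan)))))
  arr <- array(unlist(planes[ord], use.names = FALSE), c(H, W, length(ord)),
               dimnames = list(NULL, NULL, ord))
  attr(arr, "sizes") <- sizes
  arr
}

#' @describeIn pixel-features Extract feature vectors at pixel coordinates.
#' @param planes output of `compute_feature_planes()`.
#' @param pixels n x 2 matrix of 1-based (row, col) coordinates.
#' @return `extract_vectors()`: n x D numeric matrix (one row per pixel, in
#'   input order; duplicates allowed).
#' @export
extract_vectors <- function(planes, pixels) {
  stopifnot(length(dim(planes)) == 3)
  pixels <- matrix(as.integer(pixels), ncol = 2)
  D <- dim(planes)[3]
  if (!nrow(pixels))
    return(matrix(numeric(0), 0, D, dimnames = list(NULL, dimnames(planes)[[3]])))
  if (any(pixels[, 1] < 1 | pixels[, 1] > dim(planes)[1] |
          pixels[, 2] < 1 | pixels[, 2] > dim(planes)[2]))
    stop("extract_vectors(): coordinate outside image")
  out <- vapply(seq_len(D), function(k) planes[, , k][pixels],
                numeric(nrow(pixels)))
  out <- matrix(out, nrow = nrow(pixels), ncol = D,
                dimnames = list(NULL, dimnames(planes)[[3]]))
  out
}
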