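#' Similarity transforms on image coordinates
#'
#' A similarity transform is parameterised by a translation `(tx, ty)` in
#' pixels (x = column offset, y = row offset), a rotation `theta` in degrees
#' (counter-clockwise in x/y coordinates) and an isotropic `scale`. The
#' rotation and scaling act about a fixed `center` (by convention the image
#' centre), so parameters of transforms of the same image are directly
#' comparable:
#'
#'   T(p) = scale * R(theta) (p - center) + center + (tx, ty)
#'
#' @param tx,ty translation in pixels.
#' @param theta rotation in degrees.
#' @param scale positive scale factor.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(tx = 0, ty = 0, theta = 0, scale = 1) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(theta), scale > 0)
  structure(list(tx = tx, ty = ty, theta = theta, scale = scale),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform(tx=%.3f, ty=%.3f, theta=%.3f deg, scale=%.4f)\n",
              x$tx, x$ty, x$theta, x$scale))
  invisible(x)
}

rotmat <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Invert a similarity transform
#' @param tf a `similarity_transform`.
#' @return the inverse transform (about the same center).
#' @export
invert_transform <- function(tf) {
  Rinv <- rotmat(-tf$theta) / tf$scale
  t_inv <- -Rinv %*% c(tf$tx, tf$ty)
  similarity_transform(t_inv[1], t_inv[2], -tf$theta, 1 / tf$scale)
}

#' Compose two similarity transforms (apply `first`, then `second`)
#' @param first,second `similarity_transform` objects sharing a center.
#' @return their composition.
#' @export
compose_transforms <- function(first, second) {
  R2 <- rotmat(second$theta) * second$scale
  tt <- R2 %*% c(first$tx, first$ty) + c(second$tx, second$ty)
  similarity_transform(tt[1], tt[2], first$theta + second$theta,
                       first$scale * second$scale)
}

#' Apply a similarity transform to points
#' @param tf transform; `xy` n x 2 matrix of (x, y) coordinates.
#' @param xy points; `center` the fixed point, (x, y).
#' @param center rotation/scaling center.
#' @return transformed n x 2 matrix.
#' @export
transform_points <- function(tf, xy, center) {
  R <- rotmat(tf$theta) * tf$scale
  sweep(t(R %*% t(sweep(xy, 2, center))), 2,
        center + c(tf$tx, tf$ty), `+`)
}

#' Warp a mask (or matrix) by a similarity transform
#'
#' Output pixel (r, c) samples the input at the inverse-transformed location
#' using nearest-neighbour interpolation, preserving binarity of masks.
#' Locations falling outside the input are background (0 / FALSE).
#'
#' @param mask logical or numeric matrix.
#' @param tf `similarity_transform` mapping input coordinates to output
#'   coordinates.
#' @param dims output dimensions (rows, cols); default same as input.
#' @return warped matrix of the same storage mode.
#' @export
warp_mask <- function(mask, tf, dims = dim(mask)) {
  H <- dims[1]; W <- dims[2]
  center <- c((ncol(mask) + 1) / 2, (nrow(mask) + 1) / 2)   # (x, y)
  inv <- invert_transform(tf)
  xy <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  src <- transform_points(inv, xy, center)
  cs <- round(src[, 1]); rs <- round(src[, 2])
  ok <- cs >= 1 & cs <= ncol(mask) & rs >= 1 & rs <= nrow(mask)
  out <- matrix(if (is.logical(mask)) FALSE else 0, H, W)
  out[ok] <- mask[cbind(rs[ok], cs[ok])]    # xy rows follow column-major order
  out
}

# bilinear warp of a numeric/logical matrix; fractional edge values make
# overlap objectives smooth in sub-pixel shifts (used by the registration
# search; final masks always use the nearest-neighbour warp_mask)
warp_bilinear <- function(mask, tf, dims = dim(mask)) {
  m <- mask * 1
  H <- dims[1]; W <- dims[2]
  center <- c((ncol(m) + 1) / 2, (nrow(m) + 1) / 2)
  inv <- invert_transform(tf)
  xy <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  src <- transform_points(inv, xy, center)
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * get(y0, x0) + fx * (1 - fy) * get(y0, x0 + 1) +
    (1 - fx) * fy * get(y0 + 1, x0) + fx * fy * get(y0 + 1, x0 + 1)
  matrix(v, H, W)
}
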