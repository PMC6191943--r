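#' Read an RGB image
#'
#' Reads PNG, TIFF or JPEG into an H x W x 3 integer-valued array with
#' intensities in \[0, 255\]. Grayscale inputs are replicated to three
#' channels; an alpha channel is discarded; 16-bit inputs are rescaled to
#' 8-bit by division by the maximum representable value.
#'
#' @param path path to an image file.
#' @return numeric H x W x 3 array, values in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image(): file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("read_image(): cannot decode ", path, ": ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)           # x (cols) first, values in [0,1]
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] > 3) stop("read_image(): more than 4 channels in ", path)
  if (dim(a)[3] == 2) stop("read_image(): unsupported 2-channel image ", path)
  out <- aperm(a, c(2, 1, 3))
  round(out * 255)
}

#' Write an RGB image or a binary mask as PNG/TIFF/JPEG
#'
#' Masks are written as single-channel images with values 0/255.
#'
#' @param img H x W x 3 array in \[0, 255\], or a logical matrix for masks.
#' @param path output path; the extension selects the format.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) {
    a <- t(as_logical_mask(img)) * 1
  } else {
    stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
    a <- aperm(img, c(2, 1, 3)) / 255
  }
  EBImage::writeImage(EBImage::Image(a, colormode = if (is.matrix(img)) "Grayscale" else "Color"),
                      path)
  invisible(path)
}

#' Read a binary mask from a single-channel image
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path image path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  img[, , 1] > 127
}

#' Slice an image into vertical strips
#'
#' Large slides are processed strip-by-strip: strips span full image height
#' and are cut along columns so that each strip holds at most `max_pixels`
#' pixels (per channel), plus an `overlap_px` margin on interior cut edges so
#' neighbourhood features computed per strip agree with whole-image features.
#'
#' @param img H x W x 3 array.
#' @param max_pixels maximum core pixels (H x width) per tile.
#' @param overlap_px non-negative overlap added on interior edges.
#' @return object of class `tile_set`: list with `tiles` (each a list with
#'   `pixels`, `col0` 1-based start of the core region, `core_cols`),
#'   `overlap_px` and the source dimensions.
#' @export
slice_tiles <- function(img, max_pixels = 25e6, overlap_px = 3L) {
  stopifnot(length(dim(img)) == 3)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (max_pixels < H) stop("slice_tiles(): max_pixels smaller than one image column")
  core_w <- max(1L, min(W, as.integer(floor(max_pixels / H))))
  starts <- seq(1L, W, by = core_w)
  tiles <- lapply(starts, function(c0) {
    c1 <- min(W, c0 + core_w - 1L)
    lo <- max(1L, c0 - overlap_px)
    hi <- min(W, c1 + overlap_px)
    list(pixels = img[, lo:hi, , drop = FALSE],
         col0 = c0, core_cols = c1 - c0 + 1L, pad_left = c0 - lo)
  })
  structure(list(tiles = tiles, overlap_px = as.integer(overlap_px),
                 height = H, width = W),
            class = "tile_set")
}

#' Reassemble a tile set into the original image
#'
#' Inverse of [slice_tiles()]: overlap margins are dropped and core strips are
#' concatenated, reproducing the source image exactly.
#'
#' @param ts a `tile_set`.
#' @return H x W x 3 array.
#' @export
merge_tiles <- function(ts) {
  stopifnot(inherits(ts, "tile_set"))
  out <- array(0, c(ts$height, ts$width, 3))
  for (tl in ts$tiles) {
    cols <- tl$pad_left + seq_len(tl$core_cols)
    out[, tl$col0 + seq_len(tl$core_cols) - 1L, ] <- tl$pixels[, cols, , drop = FALSE]
  }
  out
}

#' Render a multi-marker colour overlay
#'
#' Each mask is painted in its colour; where masks overlap the colours add
#' (clipped at 255), so red + green markers appear yellow and all three
#' primary-coloured markers together appear white.
#'
#' @param masks list of logical matrices, all the same size.
#' @param colors list of RGB triples in \[0, 255\]; defaults to pure red,
#'   green, blue for up to three masks.
#' @param background `"black"` (default) or `"white"` for pixels in no mask.
#' @return H x W x 3 array.
#' @export
render_overlay <- function(masks, colors = NULL,
                           background = c("black", "white")) {
  background <- match.arg(background)
  stopifnot(length(masks) >= 1)
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), dims)) stop("render_overlay(): mask size mismatch")
  }
  if (is.null(colors)) {
    if (length(masks) > 3) stop("render_overlay(): provide colors for >3 masks")
    colors <- list(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255))[seq_along(masks)]
  }
  stopifnot(length(colors) == length(masks))
  out <- array(0, c(dims, 3))
  for (i in seq_along(masks)) {
    m <- as_logical_mask(masks[[i]])
    for (k in 1:3) {
      pl <- out[, , k]
      pl[m] <- pl[m] + colors[[i]][k]
      out[, , k] <- pl
    }
  }
  out <- pmin(out, 255)
  if (background == "white") {
    any_mask <- Reduce(`|`, lapply(masks, as_logical_mask))
    for (k in 1:3) {
      pl <- out[, , k]
      pl[!any_mask] <- 255
      out[, , k] <- pl
    }
  }
  out
}
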