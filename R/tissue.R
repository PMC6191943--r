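#' Tissue-region segmentation
#'
#' The tissue slice is the darker foreground on the bright slide background.
#' It is found by (1) downsampling the image so its largest dimension is at
#' most `downsample_limit` pixels, converting to gray level and smoothing
#' heavily (25 x 25 median filter, then Gaussian sigma 0.5) so noise and
#' texture vanish and only the bright-background / dark-tissue contrast
#' remains; (2) Otsu thresholding, tissue = the darker class; (3) removing
#' mask pixels whose full-resolution gray level is brighter than
#' mean_back + 0.5 * std_back, where the statistics are computed over the
#' background (pixels outside the mask); (4) filling small holes, removing
#' components that are too small or too elongated, and cropping to the tight
#' bounding box of the result.
#'
#' @name tissue-segmentation
NULL

luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' @describeIn tissue-segmentation Downsample, gray-convert and smooth.
#' @param img H x W x 3 array in \[0, 255\].
#' @param downsample_limit maximum output dimension (px).
#' @param median_size median filter window side (odd, px).
#' @param gaussian_sigma Gaussian smoothing sigma (px).
#' @return `smooth_gray()`: list with `gray` (smoothed, possibly downsampled,
#'   \[0, 255\]), `scale` (output px per input px, <= 1) and `orig_dim`.
#' @export
smooth_gray <- function(img, downsample_limit = 5000,
                        median_size = 25, gaussian_sigma = 0.5) {
  stopifnot(length(dim(img)) == 3, median_size %% 2 == 1)
  H <- dim(img)[1]; W <- dim(img)[2]
  scale <- min(1, downsample_limit / max(H, W))
  g <- luminance(img) / 255
  eg <- EBImage::Image(t(g))
  if (scale < 1) eg <- EBImage::resize(eg, w = round(W * scale))
  if (median_size > 1 && min(dim(eg)) > median_size)
    eg <- EBImage::medianFilter(eg, (median_size - 1) / 2)
  if (gaussian_sigma > 0 && min(dim(eg)) >= 9)
    eg <- EBImage::gblur(eg, sigma = gaussian_sigma)
  dat <- EBImage::imageData(eg)
  gray <- t(matrix(as.numeric(dat), nrow(dat), ncol(dat))) * 255
  list(gray = gray, scale = scale, orig_dim = c(H, W))
}

#' @describeIn tissue-segmentation Otsu threshold of the smoothed image;
#'   tissue is the class below the threshold. The mask is rescaled back to
#'   the original size by nearest-neighbour when the image was downsampled.
#' @param smoothed output of `smooth_gray()`.
#' @return `otsu_tissue_mask()`: logical matrix at the original size.
#' @export
otsu_tissue_mask <- function(smoothed) {
  gray <- smoothed$gray
  if (diff(range(gray)) == 0)
    stop("otsu_tissue_mask(): constant image, no tissue/background contrast")
  thr <- EBImage::otsu(EBImage::Image(t(gray) / 255), range = c(0, 1)) * 255
  mask <- gray < thr
  if (!any(mask)) stop("otsu_tissue_mask(): no tissue found")
  if (smoothed$scale < 1) {
    H <- smoothed$orig_dim[1]; W <- smoothed$orig_dim[2]
    ri <- pmin(nrow(mask), pmax(1L, round(seq_len(H) * nrow(mask) / H)))
    ci <- pmin(ncol(mask), pmax(1L, round(seq_len(W) * ncol(mask) / W)))
    mask <- mask[ri, ci, drop = FALSE]
  }
  mask
}

#' @describeIn tissue-segmentation Background-brightness statistics of the
#'   pixels outside the mask.
#' @param mask tissue mask (logical matrix).
#' @param gray full-resolution gray image in \[0, 255\].
#' @return `background_stats()`: list with `mean_back` and `std_back`.
#' @export
background_stats <- function(mask, gray) {
  stopifnot(identical(dim(mask), dim(gray)))
  bg <- gray[!mask]
  if (!length(bg)) stop("background_stats(): empty background")
  list(mean_back = mean(bg),
       std_back = if (length(bg) > 1) stats::sd(bg) else 0)
}

#' @describeIn tissue-segmentation Drop mask pixels brighter than
#'   mean_back + 0.5 * std_back. Anti-extensive and idempotent for fixed
#'   statistics; pass `stats` to freeze them across calls.
#' @param stats optional pre-computed `background_stats()` result.
#' @return `refine_border()`: logical matrix, subset of `mask`.
#' @export
refine_border <- function(mask, gray, stats = NULL) {
  stopifnot(identical(dim(mask), dim(gray)))
  if (is.null(stats)) stats <- background_stats(mask, gray)
  thr <- stats$mean_back + 0.5 * stats$std_back
  mask & gray <= thr
}

#' @describeIn tissue-segmentation Fill small holes, remove components that
#'   are too small (area < `min_area_frac` x image area) or too elongated
#'   (compactness 4 pi A / P^2 below `min_compactness`, with P the
#'   foreground/background edge count), and crop.
#' @param min_area_frac minimum component area as a fraction of image area.
#' @param min_compactness minimum 4 pi A / P^2.
#' @param hole_fill_frac holes up to this fraction of the tissue area are
#'   filled.
#' @return `clean_mask()`: object of class `tissue_region`: list with `mask`
#'   (full size), `TA` (tissue area, px), `crop_box` (row0, col0, row1, col1,
#'   1-based inclusive) and `cropped` (mask restricted to the box).
#' @export
clean_mask <- function(mask, min_area_frac = 0.0005, min_compactness = 0.05,
                       hole_fill_frac = 0.01) {
  stopifnot(is.matrix(mask))
  mask <- as_logical_mask(mask)
  if (!any(mask)) stop("clean_mask(): empty mask")
  mask <- fill_small_holes(mask, max_hole_area = hole_fill_frac * sum(mask))
  lab <- label_components(mask, connectivity = 8)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  per <- component_perimeter(lab)
  compact <- 4 * pi * areas / pmax(per, 1)^2
  keep <- which(areas >= min_area_frac * length(mask) & compact >= min_compactness)
  if (!length(keep)) stop("clean_mask(): no tissue component survives cleaning")
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  tissue_region(out)
}

#' Construct a tissue region from a final mask
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return `tissue_region` object (see [clean_mask()]).
#' @export
tissue_region <- function(mask) {
  stopifnot(any(mask))
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  structure(list(mask = mask, TA = sum(mask),
                 crop_box = c(rows[1], cols[1], rows[2], cols[2]),
                 cropped = mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]),
            class = "tissue_region")
}

#' @export
print.tissue_region <- function(x, ...) {
  cat(sprintf("tissue_region: %d px tissue in %d x %d image, crop [%d:%d, %d:%d]\n",
              x$TA, nrow(x$mask), ncol(x$mask),
              x$crop_box[1], x$crop_box[3], x$crop_box[2], x$crop_box[4]))
  invisible(x)
}

#' Segment the tissue region of a slide image
#'
#' Runs the full chain: [smooth_gray()], [otsu_tissue_mask()],
#' [refine_border()], [clean_mask()].
#'
#' @inheritParams smooth_gray
#' @inheritParams clean_mask
#' @return a `tissue_region`.
#' @export
segment_tissue <- function(img, downsample_limit = 5000, median_size = 25,
                           gaussian_sigma = 0.5, min_area_frac = 0.0005,
                           min_compactness = 0.05, hole_fill_frac = 0.01) {
  sm <- smooth_gray(img, downsample_limit, median_size, gaussian_sigma)
  mask <- otsu_tissue_mask(sm)
  mask <- refine_border(mask, luminance(img))
  clean_mask(mask, min_area_frac, min_compactness, hole_fill_frac)
}
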