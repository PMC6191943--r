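#' Marker-mask cleaning and density
#'
#' @name marker-quant
NULL

#' @describeIn marker-quant Remove 8-connected components with fewer than 3
#'   pixels (noise and artefacts) from a raw marker mask.
#' @param raw logical matrix (raw classifier output).
#' @param min_component minimum surviving component size (px).
#' @return `clean_marker_mask()`: object of class `marker_segmentation`:
#'   list with `M` (cleaned mask) and `A_M` (marker area, px).
#' @export
clean_marker_mask <- function(raw, min_component = 3) {
  stopifnot(is.matrix(raw))
  M <- remove_small_components(raw, min_component, connectivity = 8)
  structure(list(M = M, A_M = sum(M)), class = "marker_segmentation")
}

#' @export
print.marker_segmentation <- function(x, ...) {
  cat(sprintf("marker_segmentation: A_M = %d px\n", x$A_M))
  invisible(x)
}

#' @describeIn marker-quant Marker density: the fraction of the tissue (or
#'   ROI) area covered by marker pixels, DM_T = A_M / TA. With an ROI, the
#'   markers are clipped to it and the ROI area is the denominator.
#' @param seg a `marker_segmentation`.
#' @param region a `tissue_region`, or a logical ROI mask.
#' @return `marker_density()`: list with `DM_T` (fraction), `percent`,
#'   `A_M`, `denominator`.
#' @export
marker_density <- function(seg, region) {
  mask <- if (inherits(region, "tissue_region")) region$mask else region
  denom <- sum(mask)
  if (denom == 0) stop("marker_density(): zero-area region")
  a <- sum(seg$M & mask)
  list(DM_T = a / denom, percent = 100 * a / denom,
       A_M = a, denominator = denom)
}

#' Normalized minimum-distance histogram of markers from a border
#'
#' For every marker pixel the Euclidean distance to the nearest border pixel
#' is computed; pixels farther than `band_limit_px` are excluded (the "gray
#' band"); the remaining distances are binned with width `bin_width_px`
#' (bins \[k w, (k+1) w)) and normalized to sum to 1.
#'
#' @param seg `marker_segmentation` (or logical mask).
#' @param border logical mask of the structure-of-interest border, same size.
#' @param band_limit_px only markers within this distance are counted
#'   (default Inf).
#' @param bin_width_px histogram bin width (default 1 px).
#' @return object of class `distance_histogram`: list with `breaks`, `mids`,
#'   `frequencies` (sum 1), `n` pixels counted, `bin_width_px`,
#'   `band_limit_px`.
#' @export
min_distance_histogram <- function(seg, border, band_limit_px = Inf,
                                   bin_width_px = 1) {
  M <- if (inherits(seg, "marker_segmentation")) seg$M else seg
  stopifnot(identical(dim(M), dim(border)), bin_width_px > 0)
  if (!any(border)) stop("min_distance_histogram(): empty border mask")
  d <- distance_to_mask(border)[M]
  d <- d[d <= band_limit_px]
  if (!length(d)) stop("min_distance_histogram(): no marker pixel within the band")
  nb <- floor(max(d) / bin_width_px) + 1L
  bins <- findInterval(d, seq(0, by = bin_width_px, length.out = nb + 1L),
                       rightmost.closed = FALSE)
  counts <- tabulate(bins, nbins = nb)
  structure(list(breaks = seq(0, by = bin_width_px, length.out = nb + 1L),
                 mids = (seq_len(nb) - 0.5) * bin_width_px,
                 frequencies = counts / sum(counts),
                 n = length(d), bin_width_px = bin_width_px,
                 band_limit_px = band_limit_px),
            class = "distance_histogram")
}

same_bins <- function(h1, h2) {
  h1$bin_width_px == h2$bin_width_px
}

# pad two histograms to a common number of bins
align_bins <- function(hists) {
  nb <- max(vapply(hists, function(h) length(h$frequencies), integer(1)))
  lapply(hists, function(h) {
    f <- c(h$frequencies, rep(0, nb - length(h$frequencies)))
    h$frequencies <- f
    h$mids <- (seq_len(nb) - 0.5) * h$bin_width_px
    h$breaks <- seq(0, by = h$bin_width_px, length.out = nb + 1L)
    h
  })
}

#' Mean of normalized distance histograms
#'
#' Each image contributes one normalized histogram; the mean weights images
#' equally (per-bin arithmetic mean), rather than pooling pixels.
#'
#' @param hists list of `distance_histogram`s with equal bin width.
#' @return a `distance_histogram` (frequencies sum to 1 by construction).
#' @export
mean_histogram <- function(hists) {
  stopifnot(length(hists) >= 1)
  w <- vapply(hists, function(h) h$bin_width_px, numeric(1))
  if (length(unique(w)) != 1) stop("mean_histogram(): mixed bin widths")
  hists <- align_bins(hists)
  out <- hists[[1]]
  out$frequencies <- Reduce(`+`, lapply(hists, `[[`, "frequencies")) /
    length(hists)
  out$n <- sum(vapply(hists, `[[`, numeric(1), "n"))
  out
}

#' Histogram intersection of two normalized histograms
#'
#' intersection(a -> b) = sum_i min(a_i, b_i) / sum_i b_i; the returned value
#' is the mean of the two directions, which for normalized inputs equals
#' sum_i min(a_i, b_i). Lies in \[0, 1\]; 1 iff the histograms are equal.
#'
#' @param h1,h2 `distance_histogram`s with equal bin width.
#' @return numeric scalar in \[0, 1\].
#' @export
histogram_intersection <- function(h1, h2) {
  if (!same_bins(h1, h2)) stop("histogram_intersection(): mixed bin widths")
  ab <- align_bins(list(h1, h2))
  a <- ab[[1]]$frequencies; b <- ab[[2]]$frequencies
  if (sum(a) == 0 || sum(b) == 0) stop("histogram_intersection(): zero-mass histogram")
  s <- sum(pmin(a, b))
  (s / sum(b) + s / sum(a)) / 2
}
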