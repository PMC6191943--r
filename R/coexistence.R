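#' Distance map from tissue pixels to the nearest marker pixel
#'
#' @param tissue `tissue_region` or logical mask.
#' @param seg `marker_segmentation` or logical mask with at least one pixel.
#' @return numeric matrix; Euclidean distance to the nearest marker pixel
#'   (0 on marker pixels), `NA` outside the tissue.
#' @export
distance_map <- function(tissue, seg) {
  tmask <- if (inherits(tissue, "tissue_region")) tissue$mask else as_logical_mask(tissue)
  M <- if (inherits(seg, "marker_segmentation")) seg$M else as_logical_mask(seg)
  stopifnot(identical(dim(tmask), dim(M)))
  if (!any(M)) stop("distance_map(): empty marker mask")
  d <- distance_to_mask(M)
  d[!tmask] <- NA_real_
  d
}

#' Estimate the concentration radius R(M) of a section
#'
#' The histogram of minimum marker distances over all tissue pixels (1-px
#' bins \[r, r+1)) peaks at the most common distance; R_MAX is the centre of
#' the first maximal bin. To guard against sections with no real
#' concentration (where the peak lies far out), R_LIMIT is the largest
#' integer r such that fewer than `cap_factor * A_M` tissue pixels lie at
#' distance < r from a marker. R = min(R_LIMIT, R_MAX), floored at 1 px.
#'
#' @param dmap distance map from [distance_map()].
#' @param A_M marker area (pixel count).
#' @param cap_factor multiplier of A_M bounding the covered-pixel count
#'   (default 50).
#' @return object of class `radius_estimate`: list with `R`, `R_MAX`,
#'   `R_LIMIT`, `histogram` (counts per integer bin).
#' @export
estimate_R <- function(dmap, A_M, cap_factor = 50) {
  d <- dmap[!is.na(dmap)]
  stopifnot(length(d) > 0, A_M > 0)
  bins <- floor(d)                       # [r, r+1) -> r
  counts <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  R_MAX <- which.max(counts) - 1L + 0.5  # centre of the first maximal bin
  cum <- cumsum(counts)                  # cum[r] = #{pixels with distance < r}
  below <- which(cum < cap_factor * A_M)
  R_LIMIT <- if (length(below)) max(below) else 1
  R <- max(1, min(R_LIMIT, R_MAX))
  if (all(d == 0)) {
    warning("estimate_R(): all tissue pixels are marker pixels; R = 1")
    R <- 1
  }
  structure(list(R = R, R_MAX = R_MAX, R_LIMIT = R_LIMIT, histogram = counts),
            class = "radius_estimate")
}

#' Extract the concentration regions of a section
#'
#' Concentration regions are areas of the tissue where the marker is locally
#' dense. They are built in four steps: (1) the core mask keeps tissue
#' pixels at distance < R/2 from any marker pixel; (2) core components with
#' area < 10 (R/2)^2 are deleted; (3) surviving cores are expanded to the
#' connected components of the tissue pixels at distance < R that contain
#' them; (4) expanded components with area < 20 R^2 are discarded.
#'
#' @param tissue `tissue_region` or mask.
#' @param seg `marker_segmentation` or mask.
#' @param R a `radius_estimate` or numeric radius; default estimated from
#'   the data.
#' @param cap_factor passed to [estimate_R()] when R is estimated.
#' @return object of class `concentration_regions`: list with `labels`
#'   (integer matrix, 0 outside), `mask`, `CA` (total area), `CA_i`
#'   (per-region areas), `R` (the estimate used), `core` (the filtered core
#'   mask). Empty sets (no region survives) are valid.
#' @export
concentration_regions <- function(tissue, seg, R = NULL, cap_factor = 50) {
  tmask <- if (inherits(tissue, "tissue_region")) tissue$mask else as_logical_mask(tissue)
  M <- if (inherits(seg, "marker_segmentation")) seg$M else as_logical_mask(seg)
  empty <- function(Rv) structure(
    list(labels = matrix(0L, nrow(tmask), ncol(tmask)),
         mask = matrix(FALSE, nrow(tmask), ncol(tmask)),
         CA = 0L, CA_i = integer(0), R = Rv, core = matrix(FALSE, nrow(tmask), ncol(tmask))),
    class = "concentration_regions")
  if (!any(M)) return(empty(NULL))
  dmap <- distance_map(tmask, M)
  if (is.null(R)) R <- estimate_R(dmap, sum(M), cap_factor)
  Rv <- if (inherits(R, "radius_estimate")) R$R else R
  stopifnot(Rv > 0)

  core <- !is.na(dmap) & dmap < Rv / 2
  core <- remove_small_components(core, min_area = 10 * (Rv / 2)^2,
                                  connectivity = 8)
  if (!any(core)) return(empty(R))
  expand <- !is.na(dmap) & dmap < Rv
  lab <- label_components(expand, connectivity = 8)
  keep <- sort(unique(lab[core & lab > 0]))
  if (!length(keep)) return(empty(R))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- keep[areas[keep] >= 20 * Rv^2]
  if (!length(keep)) return(empty(R))
  out_lab <- matrix(0L, nrow(tmask), ncol(tmask))
  for (j in seq_along(keep)) out_lab[lab == keep[j]] <- j
  structure(list(labels = out_lab, mask = out_lab > 0,
                 CA = sum(out_lab > 0),
                 CA_i = tabulate(out_lab[out_lab > 0], nbins = length(keep)),
                 R = R, core = core),
            class = "concentration_regions")
}

#' @export
print.concentration_regions <- function(x, ...) {
  cat(sprintf("concentration_regions: %d region(s), CA = %d px\n",
              length(x$CA_i), x$CA))
  invisible(x)
}

pair_measures <- function(A_Mi, A_Mj, CA_i, CA_j, A_Mi_in_Cj, A_Mj_in_Ci) {
  und <- function(num, den) if (den > 0) num / den else NA_real_
  DM_Ci <- und(A_Mi, CA_i); DM_Cj <- und(A_Mj, CA_j)
  DM_iInCj <- und(A_Mi_in_Cj, CA_j); DM_jInCi <- und(A_Mj_in_Ci, CA_i)
  PM_iInCj <- und(A_Mi_in_Cj, A_Mi); PM_jInCi <- und(A_Mj_in_Ci, A_Mj)
  w <- if (!is.na(DM_Ci) && !is.na(DM_Cj) && max(DM_Ci, DM_Cj) > 0)
    min(DM_Ci, DM_Cj) / max(DM_Ci, DM_Cj) else NA_real_
  list(DM_Ci = DM_Ci, DM_Cj = DM_Cj,
       DM_iInCj = DM_iInCj, DM_jInCi = DM_jInCi,
       PM_iInCj = PM_iInCj, PM_jInCi = PM_jInCi,
       w = w,
       wMean_Dens = w * (DM_iInCj + DM_jInCi) / 2,
       wMean_AVG = w * (PM_iInCj + PM_jInCi) / 2)
}

#' Marker co-existence measures over a registered serial set
#'
#' For each marker the density in the tissue (DM_T) and in its own
#' concentration regions (DM_C = A_M / CA) is computed; for each marker pair
#' (i, j): the density DM_iInCj = A(M_i inside Conc_j) / CA_j, the
#' percentage PM_iInCj = A(M_i inside Conc_j) / A_Mi, the balance weight
#' w = min(DM_Ci, DM_Cj) / max(DM_Ci, DM_Cj), and the weighted means
#' wMean_Dens = w (DM_iInCj + DM_jInCi)/2 and
#' wMean_AVG = w (PM_iInCj + PM_jInCi)/2 (both symmetric in the pair). With
#' an ROI, all masks and regions are clipped to it and the ROI area replaces
#' the tissue area as denominator of DM_T. Measures whose denominator is
#' zero are reported as `NA`, never as 0.
#'
#' @param rs a `registered_set` whose sections carry marker masks, or a
#'   plain list with `tissue_masks` and `marker_masks` in a common frame.
#' @param regions list of `concentration_regions`, one per section (default:
#'   computed from the registered masks).
#' @param roi optional logical mask (or c(row0, col0, row1, col1) rectangle,
#'   1-based inclusive) restricting the analysis.
#' @param names optional marker names.
#' @return object of class `coexistence_report`: list with `per_marker`
#'   data.frame (name, A_M, TA, DM_T, CA, DM_C), `pairs` data.frame (one row
#'   per unordered pair with all measures; densities as fractions,
#'   `wMean_AVG_percent` additionally in percent) and `GTRO`.
#' @export
coexistence_report <- function(rs, regions = NULL, roi = NULL, names = NULL) {
  tmasks <- rs$tissue_masks
  mmasks <- rs$marker_masks
  n <- length(tmasks)
  stopifnot(n >= 2, length(mmasks) == n)
  if (is.null(names)) names <- paste0("M", seq_len(n))
  if (is.null(regions))
    regions <- lapply(seq_len(n), function(i)
      concentration_regions(tmasks[[i]], mmasks[[i]]))
  g <- gtro(tmasks)

  if (!is.null(roi)) {
    if (!is.matrix(roi)) {
      rmask <- matrix(FALSE, nrow(tmasks[[1]]), ncol(tmasks[[1]]))
      rmask[roi[1]:roi[3], roi[2]:roi[4]] <- TRUE
      roi <- rmask
    }
    tmasks <- lapply(tmasks, function(m) m & roi)
    mmasks <- lapply(mmasks, function(m) m & roi)
    regions <- lapply(regions, function(rg) {
      rg$mask <- rg$mask & roi
      rg$labels[!roi] <- 0L
      rg$CA <- sum(rg$mask)
      rg$CA_i <- if (max(rg$labels) > 0)
        tabulate(rg$labels[rg$labels > 0], nbins = max(rg$labels)) else integer(0)
      rg
    })
    denom <- rep(sum(roi), n)
  } else {
    denom <- vapply(tmasks, sum, numeric(1))
  }

  A_M <- vapply(mmasks, sum, numeric(1))
  CA <- vapply(regions, `[[`, numeric(1), "CA")
  per_marker <- data.frame(
    name = names, A_M = A_M, TA = denom,
    DM_T = ifelse(denom > 0, A_M / denom, NA_real_),
    CA = CA,
    DM_C = ifelse(CA > 0, A_M / CA, NA_real_))

  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    Aij <- sum(mmasks[[i]] & regions[[j]]$mask)
    Aji <- sum(mmasks[[j]] & regions[[i]]$mask)
    pm <- pair_measures(A_M[i], A_M[j], CA[i], CA[j], Aij, Aji)
    pairs[[length(pairs) + 1L]] <- data.frame(
      marker_i = names[i], marker_j = names[j],
      A_Mi_in_Cj = Aij, A_Mj_in_Ci = Aji,
      as.data.frame(pm),
      wMean_AVG_percent = 100 * pm$wMean_AVG)
  }
  structure(list(per_marker = per_marker,
                 pairs = do.call(rbind, pairs),
                 GTRO = g, roi_used = !is.null(roi)),
            class = "coexistence_report")
}

#' @export
print.coexistence_report <- function(x, ...) {
  cat(sprintf("coexistence_report (GTRO %.1f%%)\n", x$GTRO))
  print(x$per_marker, row.names = FALSE)
  cat("\npairwise:\n")
  print(x$pairs[, c("marker_i", "marker_j", "w", "wMean_Dens",
                    "wMean_AVG_percent")], row.names = FALSE)
  invisible(x)
}
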