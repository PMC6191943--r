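#' Global tissue-region overlap (GTRO)
#'
#' Intersection-over-union of all tissue masks of a registered serial set,
#' as a percentage: 100 * A(intersection) / A(union).
#'
#' @param masks list of >= 2 logical matrices of identical size.
#' @return numeric percent in \[0, 100\].
#' @export
gtro <- function(masks) {
  stopifnot(length(masks) >= 2)
  dims <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), dims)) stop("gtro(): size mismatch")
  masks <- lapply(masks, as_logical_mask)
  inter <- Reduce(`&`, masks)
  uni <- Reduce(`|`, masks)
  u <- sum(uni)
  if (u == 0) stop("gtro(): empty union")
  100 * sum(inter) / u
}

mask_dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}

mask_centroid <- function(mask) {        # (x, y) = (col, row)
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 2]), mean(idx[, 1]))
}

principal_angle <- function(mask) {      # degrees, orientation of major axis
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - mean(idx[, 2]); y <- idx[, 1] - mean(idx[, 1])
  0.5 * atan2(2 * mean(x * y), mean(x * x) - mean(y * y)) * 180 / pi
}

downscale_mask <- function(mask, f) {
  if (f == 1) return(mask)
  ri <- seq(1, nrow(mask), by = f); ci <- seq(1, ncol(mask), by = f)
  mask[ri, ci, drop = FALSE]
}

#' Shape-based registration of one tissue mask onto another
#'
#' Multiscale similarity registration of binary tissue masks: the masks are
#' downscaled by factors of 2 until the largest dimension is at most
#' `min_dim`; the transform is initialised from the centroid offset, the
#' principal-axis angle difference (both polarities tried) and the square
#' root of the area ratio, then refined by coordinate-descent hill climbing
#' on the Dice overlap with step sizes halved at each pyramid level. The
#' result is accepted only if it does not reduce the full-resolution overlap
#' below the identity transform; otherwise the identity is returned.
#'
#' @param fixed,moving `tissue_region`s or logical masks of identical size.
#' @param min_dim coarsest pyramid resolution (px).
#' @param max_iter hill-climbing sweeps per pyramid level.
#' @return a [similarity_transform()] mapping `moving` onto `fixed`, with
#'   attributes `dice_before` and `dice_after`.
#' @export
register_pair <- function(fixed, moving, min_dim = 256, max_iter = 40) {
  fm <- if (inherits(fixed, "tissue_region")) fixed$mask else as_logical_mask(fixed)
  mm <- if (inherits(moving, "tissue_region")) moving$mask else as_logical_mask(moving)
  stopifnot(identical(dim(fm), dim(mm)))
  if (sum(fm) < 2 || sum(mm) < 2) stop("register_pair(): degenerate mask")

  dice_id <- mask_dice(fm, mm)
  # pyramid factors, coarse to fine
  f <- 1L
  while (max(dim(fm)) / (2 * f) >= min_dim) f <- f * 2L

  # initialisation at full resolution coordinates
  cf <- mask_centroid(fm); cm <- mask_centroid(mm)
  s0 <- sqrt(sum(fm) / sum(mm))
  angles <- principal_angle(fm) - principal_angle(mm)
  inits <- lapply(c(angles, angles + 180, 0), function(th) {
    th <- ((th + 180) %% 360) - 180
    similarity_transform(cf[1] - cm[1], cf[2] - cm[2], th, s0)
  })

  score <- function(tf, fmask, mmask, fac) {
    tf_s <- similarity_transform(tf$tx / fac, tf$ty / fac, tf$theta, tf$scale)
    w <- warp_bilinear(mmask, tf_s, dims = dim(fmask))
    2 * sum(w[fmask]) / (sum(fmask) + sum(w))      # soft Dice, sub-pixel smooth
  }

  best <- NULL
  for (tf0 in inits) {
    sc <- score(tf0, downscale_mask(fm, f), downscale_mask(mm, f), f)
    if (is.null(best) || sc > best$sc) best <- list(tf = tf0, sc = sc)
  }
  tf <- best$tf

  fac <- f
  while (fac >= 1) {
    fmask <- downscale_mask(fm, fac); mmask <- downscale_mask(mm, fac)
    steps <- c(t = 4 * fac, theta = 2, scale = 0.02)
    cur <- score(tf, fmask, mmask, fac)
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      for (par in c("tx", "ty", "theta", "scale")) {
        st <- if (par %in% c("tx", "ty")) steps["t"]
              else if (par == "theta") steps["theta"] else steps["scale"]
        for (dir in c(-1, 1)) {
          cand <- tf
          cand[[par]] <- cand[[par]] + dir * st
          if (par == "scale" && cand$scale <= 0.1) next
          sc <- score(cand, fmask, mmask, fac)
          if (sc > cur + 1e-9) { tf <- cand; cur <- sc; improved <- TRUE }
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (steps["t"] < 0.1 * fac && steps["theta"] < 0.02 &&
            steps["scale"] < 2e-4) break
      }
    }
    fac <- fac %/% 2L
    if (fac == 0) break
  }

  dice_after <- mask_dice(fm, warp_mask(mm, tf, dims = dim(fm)))
  if (dice_after < dice_id) {
    tf <- similarity_transform()
    dice_after <- dice_id
  }
  attr(tf, "dice_before") <- dice_id
  attr(tf, "dice_after") <- dice_after
  tf
}

#' Register a serial-section set to a reference section
#'
#' Every section is registered to the reference (default: the first) with
#' [register_pair()]; the recovered transform is applied to the section's
#' tissue and marker masks with nearest-neighbour resampling. GTRO is
#' reported before and after; if registration would lower the set GTRO the
#' offending section falls back to the identity transform, so GTRO never
#' worsens.
#'
#' @param sections list; each element a list with `tissue` (a
#'   `tissue_region` or mask) and optionally `marker` (a
#'   `marker_segmentation` or mask).
#' @param reference index of the reference section (default 1).
#' @param ... passed to [register_pair()].
#' @return object of class `registered_set`: list with `reference`,
#'   `transforms`, `tissue_masks`, `marker_masks` (registered frames),
#'   `GTRO_before`, `GTRO_after`.
#' @export
register_set <- function(sections, reference = 1L, ...) {
  stopifnot(length(sections) >= 2)
  get_tissue <- function(s)
    if (inherits(s$tissue, "tissue_region")) s$tissue$mask else as_logical_mask(s$tissue)
  get_marker <- function(s) {
    if (is.null(s$marker)) return(NULL)
    if (inherits(s$marker, "marker_segmentation")) s$marker$M else as_logical_mask(s$marker)
  }
  tmasks <- lapply(sections, get_tissue)
  before <- gtro(tmasks)
  ref <- tmasks[[reference]]
  transforms <- vector("list", length(sections))
  reg_t <- tmasks
  reg_m <- lapply(sections, get_marker)
  for (i in seq_along(sections)) {
    if (i == reference) {
      transforms[[i]] <- similarity_transform()
      next
    }
    tf <- tryCatch(register_pair(ref, tmasks[[i]], ...),
                   error = function(e) stop("register_set(): section ", i, ": ",
                                            conditionMessage(e)))
    transforms[[i]] <- tf
    reg_t[[i]] <- warp_mask(tmasks[[i]], tf, dims = dim(ref))
    if (!is.null(reg_m[[i]])) reg_m[[i]] <- warp_mask(reg_m[[i]], tf, dims = dim(ref))
  }
  after <- gtro(reg_t)
  if (after < before) {   # never worsen the set overlap
    for (i in seq_along(sections)) {
      transforms[[i]] <- similarity_transform()
      reg_t[[i]] <- tmasks[[i]]
      reg_m[[i]] <- get_marker(sections[[i]])
    }
    after <- before
  }
  structure(list(reference = reference, transforms = transforms,
                 tissue_masks = reg_t, marker_masks = reg_m,
                 GTRO_before = before, GTRO_after = after),
            class = "registered_set")
}

#' @export
print.registered_set <- function(x, ...) {
  cat(sprintf("registered_set: %d sections, GTRO %.1f%% -> %.1f%%\n",
              length(x$tissue_masks), x$GTRO_before, x$GTRO_after))
  invisible(x)
}
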