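#' Specification of a synthetic histology-like section
#'
#' The generator emulates the appearance that the pipeline is built for: a
#' darker tissue slice on a bright slide background, stain-coloured marker
#' dots (single dots or planted clusters), and distractor colourings whose
#' colour is deliberately close to the marker stain (mimicking china ink at
#' resection margins or blood cells). Ground-truth masks are exact by
#' construction.
#'
#' Default colour models: markers N((180, 60, 50), 12) per channel, a reddish
#' IHC stain; distractor "ink" N((120, 60, 50), 12) - same green/blue, darker
#' red, i.e. separable only through colour, as for real critical negatives;
#' tissue tint (205, 175, 185); background (245, 245, 245) with i.i.d.
#' Gaussian noise (sd 4) on every channel and optional salt-and-pepper noise.
#'
#' @param canvas c(rows, cols) of the image, default c(256, 256).
#' @param tissue list: `center` (row, col; default canvas centre), `radius`
#'   (default 0.36 * min(canvas)), `wobble` amplitude of the radial
#'   perturbation as a fraction of the radius (default 0.06, harmonics 2..4),
#'   `aspect` elongation of the slice (major/minor axis ratio, default 1.25,
#'   random orientation), `tint` mean RGB.
#' @param marker list: `mean` RGB, `sd` per-channel standard deviation,
#'   `dot_radius` (pixels), `layout` either
#'   `list(type = "uniform", n = <dots>)` or
#'   `list(type = "clusters", centers = <k x 2 (row, col)>, sds = <k>,
#'   ns = <k>, background_n = <sparse dots>, background_sep = <spacing>)`;
#'   cluster layouts may add sparse background dots over the rest of the
#'   tissue (their spacing drives the concentration-radius estimate).
#' @param distractor list: `mean`, `sd`, `n_blobs`, `blob_radius`; blobs are
#'   placed just inside the tissue border. Use `n_blobs = 0` to disable.
#' @param noise list: `sd` Gaussian sigma (default 4), `salt_pepper` rate
#'   (default 1e-4).
#' @param seed integer; the same seed reproduces the section bit-exactly.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(canvas = c(256, 256),
                           tissue = list(),
                           marker = list(),
                           distractor = list(),
                           noise = list(),
                           seed = 1L) {
  tissue <- utils::modifyList(list(center = (canvas + 1) / 2,
                                   radius = 0.36 * min(canvas),
                                   wobble = 0.06, aspect = 1.25,
                                   tint = c(205, 175, 185)), tissue)
  marker <- utils::modifyList(list(mean = c(180, 60, 50), sd = 12,
                                   dot_radius = 1,
                                   layout = list(type = "uniform", n = 120)),
                              marker)
  distractor <- utils::modifyList(list(mean = c(120, 60, 50), sd = 12,
                                       n_blobs = 2, blob_radius = 4), distractor)
  noise <- utils::modifyList(list(sd = 4, salt_pepper = 1e-4), noise)
  stopifnot(all(marker$mean >= 0 & marker$mean <= 255),
            all(distractor$mean >= 0 & distractor$mean <= 255),
            tissue$radius > 0, length(canvas) == 2)
  structure(list(canvas = canvas, tissue = tissue, marker = marker,
                 distractor = distractor, noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# star-shaped tissue blob: an ellipse of the given aspect ratio (random
# orientation) with the radius modulated by low-order harmonics; tissue
# slices are elongated, not circular, which also keeps their orientation
# identifiable for registration
blob_mask <- function(canvas, center, radius, wobble, rng_amp,
                      aspect = 1.25, orientation = 0) {
  H <- canvas[1]; W <- canvas[2]
  rr <- matrix(seq_len(H), H, W) - center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  phi <- atan2(rr, cc)
  A <- radius * sqrt(aspect); B <- radius / sqrt(aspect)
  rad_e <- A * B / sqrt((B * cos(phi - orientation))^2 +
                        (A * sin(phi - orientation))^2)
  rad <- rad_e * (1 + wobble * (rng_amp[1] * cos(2 * phi + rng_amp[4]) +
                                rng_amp[2] * cos(3 * phi + rng_amp[5]) +
                                rng_amp[3] * cos(4 * phi + rng_amp[6])))
  sqrt(rr^2 + cc^2) <= rad
}

place_dots <- function(allowed, n, min_sep, around = NULL, sd = NULL) {
  # rejection-sample dot centres inside `allowed`, pairwise distance >= min_sep
  ok_idx <- which(allowed)
  if (!length(ok_idx)) stop("synthetic_spec: no room to place marker dots")
  H <- nrow(allowed)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    if (tries > 300L * n) stop("synthetic_spec: could not place ", n, " dots")
    tries <- tries + 1L
    if (is.null(around)) {
      i <- ok_idx[sample.int(length(ok_idx), 1L)]
      cand <- c((i - 1L) %% H + 1L, (i - 1L) %/% H + 1L)
    } else {
      cand <- round(around + stats::rnorm(2, 0, sd))
      if (cand[1] < 1 || cand[2] < 1 || cand[1] > H || cand[2] > ncol(allowed) ||
          !allowed[cand[1], cand[2]]) next
    }
    if (nrow(pts) &&
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) < min_sep^2) next
    pts <- rbind(pts, cand)
  }
  pts
}

disc_union <- function(canvas, centers, radius) {
  m <- matrix(FALSE, canvas[1], canvas[2])
  if (!nrow(centers)) return(m)
  off <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                     dc = -ceiling(radius):ceiling(radius))
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  for (i in seq_len(nrow(centers))) {
    rs <- centers[i, 1] + off$dr; cs <- centers[i, 2] + off$dc
    keep <- rs >= 1 & cs >= 1 & rs <= canvas[1] & cs <= canvas[2]
    m[cbind(rs[keep], cs[keep])] <- TRUE
  }
  m
}

render_pixels <- function(img, mask, mean_rgb, sd) {
  n <- sum(mask)
  if (!n) return(img)
  for (k in 1:3) {
    pl <- img[, , k]
    pl[mask] <- stats::rnorm(n, mean_rgb[k], sd)
    img[, , k] <- pl
  }
  img
}

#' Generate one synthetic section with exact ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param tissue_mask optional pre-computed tissue mask (used internally for
#'   serial sets); by default the blob described by the spec.
#' @return list with `image` (H x W x 3, \[0, 255\]), `tissue` and `marker`
#'   ground-truth masks, `dot_centers` (n x 2) with `dot_cluster` (cluster id
#'   per dot, 0 = background), and `classes`: per-class pixel coordinate
#'   matrices (`marker`, `distractor`, `tissue`, `background`).
#' @export
generate_section <- function(spec, tissue_mask = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  canvas <- spec$canvas
  if (is.null(tissue_mask)) {
    amp <- c(stats::runif(3, 0.4, 1), stats::runif(3, 0, 2 * pi))
    ori <- stats::runif(1, 0, pi)
    tissue_mask <- blob_mask(canvas, spec$tissue$center, spec$tissue$radius,
                             spec$tissue$wobble, amp,
                             aspect = spec$tissue$aspect, orientation = ori)
  }
  H <- canvas[1]; W <- canvas[2]

  img <- array(stats::rnorm(H * W * 3, 245, spec$noise$sd), c(H, W, 3))
  img <- render_pixels(img, tissue_mask, spec$tissue$tint, spec$noise$sd)

  # distractor blobs hugging the tissue border (ink-like)
  distractor_mask <- matrix(FALSE, H, W)
  if (spec$distractor$n_blobs > 0 && any(tissue_mask)) {
    dist_in <- distance_to_mask(!tissue_mask)       # depth inside tissue
    band <- tissue_mask & dist_in <= 2 * spec$distractor$blob_radius &
      dist_in > spec$distractor$blob_radius / 2
    if (any(band)) {
      ctr <- place_dots(band, spec$distractor$n_blobs,
                        min_sep = 6 * spec$distractor$blob_radius)
      distractor_mask <- disc_union(canvas, ctr, spec$distractor$blob_radius) &
        tissue_mask
      img <- render_pixels(img, distractor_mask, spec$distractor$mean,
                           spec$distractor$sd)
    }
  }

  # marker dots inside the tissue, clear of the border and of distractors
  margin <- spec$marker$dot_radius + 3
  interior <- tissue_mask & distance_to_mask(!tissue_mask) > margin &
    !distractor_mask
  lay <- spec$marker$layout
  min_sep <- 2 * spec$marker$dot_radius + 2
  centers <- matrix(numeric(0), 0, 2)
  dot_cluster <- integer(0)        # cluster id per dot; 0 = background/uniform
  if (identical(lay$type, "uniform")) {
    if (lay$n > 0) centers <- place_dots(interior, lay$n, min_sep)
    dot_cluster <- rep(0L, nrow(centers))
  } else if (identical(lay$type, "clusters")) {
    for (i in seq_along(lay$ns)) {
      ctr <- lay$centers[i, ]
      if (!tissue_mask[round(ctr[1]), round(ctr[2])])
        stop("synthetic_spec: cluster center outside the tissue blob")
      pts <- place_dots(interior, lay$ns[i], min_sep, around = ctr,
                        sd = lay$sds[i])
      # keep clusters disjoint: newly placed dots must also avoid earlier ones
      if (nrow(centers)) {
        d2 <- outer(pts[, 1], centers[, 1], `-`)^2 +
              outer(pts[, 2], centers[, 2], `-`)^2
        if (any(d2 < min_sep^2))
          pts <- place_dots(interior & !disc_union(canvas, centers,
                                                   2 * spec$marker$dot_radius + 2),
                            lay$ns[i], min_sep, around = ctr, sd = lay$sds[i])
      }
      centers <- rbind(centers, pts)
      dot_cluster <- c(dot_cluster, rep(i, nrow(pts)))
    }
    # sparse background dots scattered over the rest of the tissue; their
    # spacing sets the mode of the tissue-to-marker distance histogram
    if (!is.null(lay$background_n) && lay$background_n > 0) {
      away <- interior
      if (nrow(centers))
        away <- away & distance_to_mask(disc_union(canvas, centers, 1)) >
          (lay$background_margin %||% lay$background_sep %||% 16)
      pts <- place_dots(away, lay$background_n,
                        min_sep = lay$background_sep %||% 16)
      centers <- rbind(centers, pts)
      dot_cluster <- c(dot_cluster, rep(0L, nrow(pts)))
    }
  } else stop("synthetic_spec: unknown marker layout type ", lay$type)
  marker_mask <- disc_union(canvas, centers, spec$marker$dot_radius)
  img <- render_pixels(img, marker_mask, spec$marker$mean, spec$marker$sd)

  # salt-and-pepper speckle
  if (spec$noise$salt_pepper > 0) {
    n_sp <- stats::rbinom(1, H * W, spec$noise$salt_pepper)
    if (n_sp > 0) {
      idx <- sample.int(H * W, n_sp)
      val <- sample(c(0, 255), n_sp, replace = TRUE)
      for (k in 1:3) {
        pl <- img[, , k]
        pl[idx] <- val
        img[, , k] <- pl
      }
    }
  }
  img <- pmin(pmax(img, 0), 255)

  to_coords <- function(m) which(m, arr.ind = TRUE)
  list(image = img,
       tissue = tissue_mask,
       marker = marker_mask,
       dot_centers = centers,
       dot_cluster = dot_cluster,
       classes = list(marker = to_coords(marker_mask),
                      distractor = to_coords(distractor_mask),
                      tissue = to_coords(tissue_mask & !marker_mask & !distractor_mask),
                      background = to_coords(!tissue_mask)))
}

#' Generate a serial-section set with known inter-section transforms
#'
#' Section i shows the base tissue blob warped by `transforms[[i]]`, rendered
#' with its own marker layout; the transforms are returned as ground truth so
#' registration recovery can be tested.
#'
#' @param spec a [synthetic_spec()]; its marker layout is the default for
#'   every section.
#' @param n_sections number of sections (>= 2).
#' @param transforms list of [similarity_transform()]s, one per section
#'   (default: identity for all).
#' @param marker_layouts optional list of per-section marker layouts.
#' @return list with `sections` (each as [generate_section()]) and
#'   `transforms`.
#' @export
generate_serial_set <- function(spec, n_sections,
                                transforms = NULL, marker_layouts = NULL) {
  stopifnot(n_sections >= 2)
  if (is.null(transforms))
    transforms <- replicate(n_sections, similarity_transform(), simplify = FALSE)
  stopifnot(length(transforms) == n_sections)
  set.seed(spec$seed)
  amp <- c(stats::runif(3, 0.4, 1), stats::runif(3, 0, 2 * pi))
  ori <- stats::runif(1, 0, pi)
  base <- blob_mask(spec$canvas, spec$tissue$center, spec$tissue$radius,
                    spec$tissue$wobble, amp,
                    aspect = spec$tissue$aspect, orientation = ori)
  sections <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    warped <- warp_mask(base, transforms[[i]])
    if (sum(warped) < 0.9 * sum(base) * transforms[[i]]$scale^2)
      stop("generate_serial_set(): transform ", i, " moves tissue off-canvas")
    spec_i <- spec
    spec_i$seed <- spec$seed + 1000L * i
    if (!is.null(marker_layouts)) spec_i$marker$layout <- marker_layouts[[i]]
    sections[[i]] <- generate_section(spec_i, tissue_mask = warped)
  }
  list(sections = sections, transforms = transforms)
}

#' Draw a training annotation set from a synthetic section
#'
#' Samples marker pixels as positives, distractor pixels as critical
#' negatives, and rectangles free of markers/distractors as obvious-negative
#' areas, reproducing the three sample classes an annotator would mark.
#'
#' @param section output of [generate_section()].
#' @param image_id identifier recorded in the annotation rows.
#' @param npos,ncrit numbers of positive / critical pixels to sample.
#' @param n_rects,rect_size obvious-negative rectangles (side length px).
#' @param seed RNG seed.
#' @return data.frame in the annotation format of [read_annotations()].
#' @export
synthetic_annotations <- function(section, image_id = "img1",
                                  npos = 150, ncrit = 150,
                                  n_rects = 6, rect_size = 24, seed = 1L) {
  set.seed(seed)
  cls <- section$classes
  stopifnot(nrow(cls$marker) >= npos)
  pick <- function(coords, n) coords[sample.int(nrow(coords), n), , drop = FALSE]
  pos <- pick(cls$marker, npos)
  crit <- if (nrow(cls$distractor) >= ncrit && ncrit > 0)
    pick(cls$distractor, ncrit) else cls$distractor
  H <- nrow(section$tissue); W <- ncol(section$tissue)
  occupied <- section$marker | disc_union(c(H, W),
    if (nrow(cls$distractor)) cls$distractor else matrix(numeric(0), 0, 2), 0.5)
  rects <- matrix(numeric(0), 0, 4)
  tries <- 0L
  while (nrow(rects) < n_rects && tries < 500L) {
    tries <- tries + 1L
    r0 <- sample.int(H - rect_size, 1L); c0 <- sample.int(W - rect_size, 1L)
    sub <- occupied[r0:(r0 + rect_size - 1L), c0:(c0 + rect_size - 1L)]
    if (any(sub)) next
    rects <- rbind(rects, c(r0, c0, r0 + rect_size, c0 + rect_size))
  }
  # annotation files use 0-based coordinates
  df_pix <- function(coords, class) {
    if (!nrow(coords)) return(NULL)
    data.frame(image = image_id, class = class,
               row = coords[, 1] - 1L, col = coords[, 2] - 1L,
               row2 = NA_integer_, col2 = NA_integer_)
  }
  rbind(df_pix(pos, "marker"),
        df_pix(crit, "critical"),
        if (nrow(rects)) data.frame(image = image_id, class = "negative_rect",
                                    row = rects[, 1] - 1L, col = rects[, 2] - 1L,
                                    row2 = rects[, 3] - 1L, col2 = rects[, 4] - 1L))
}
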