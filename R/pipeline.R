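#' End-to-end pipeline runs from a single configuration
#'
#' `run_pipeline()` executes the requested stages in dependency order:
#' `simulate` (synthetic serial set with ground truth), `tissue` (tissue
#' masks + areas), `train` (cascade model from annotations), `segment`
#' (marker masks), `quantify` (densities), `register` (serial-set
#' alignment + GTRO), `coexist` (co-existence report). All intermediate
#' artifacts are plain files (PNG / CSV / JSON) under `out_dir`, so any
#' stage can be replaced by hand-made inputs, and a manifest records every
#' output with its MD5 hash, the stage parameters and the seed: reruns with
#' the same configuration and seed are bit-identical.
#'
#' @param config list or path to a YAML file. Recognised fields: `seed`,
#'   `out_dir`, `stages` (character vector), `images` (paths, when not
#'   simulating), `annotations` (CSV path; default: sampled from the first
#'   synthetic section), `simulate` (list: `n_sections`, `spec` arguments for
#'   [synthetic_spec()], `transforms` as list of tx/ty/theta/scale lists),
#'   `features` (`sizes`), `tissue`, `quantify` (`bin_width_px`,
#'   `band_limit_px`), `register` (`reference`), `roi` (row0, col0, row1,
#'   col1; 1-based).
#' @return the run manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = ".", stages = c("simulate", "tissue", "train",
                                         "segment", "quantify", "register",
                                         "coexist"),
    features = list(sizes = c(3, 7)),
    tissue = list(), quantify = list(bin_width_px = 1, band_limit_px = Inf),
    register = list(reference = 1L),
    simulate = list(n_sections = 3),
    annotations = NULL, images = NULL, roi = NULL), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  manifest <- list(seed = cfg$seed, stages = stages, outputs = list())
  record <- function(stage, path, params = NULL) {
    manifest$outputs[[length(manifest$outputs) + 1L]] <<-
      list(stage = stage, path = basename(path),
           md5 = unname(tools::md5sum(path)), params = params)
  }
  p <- function(...) file.path(cfg$out_dir, ...)

  # validate up-front: segment requires a model source
  if ("segment" %in% stages && !"train" %in% stages &&
      is.null(cfg$model))
    stop("run_pipeline(): 'segment' requested without a model or 'train' stage")

  sections <- NULL
  image_paths <- cfg$images

  if ("simulate" %in% stages) {
    sim <- cfg$simulate
    spec_args <- utils::modifyList(list(seed = cfg$seed), sim$spec %||% list())
    spec <- do.call(synthetic_spec, spec_args)
    tfs <- NULL
    if (!is.null(sim$transforms))
      tfs <- lapply(sim$transforms, function(t) do.call(similarity_transform, t))
    set <- generate_serial_set(spec, sim$n_sections, transforms = tfs)
    sections <- set$sections
    image_paths <- character(sim$n_sections)
    for (i in seq_along(sections)) {
      image_paths[i] <- p(sprintf("section%02d.png", i))
      write_image(sections[[i]]$image, image_paths[i])
      record("simulate", image_paths[i])
      gt <- p(sprintf("section%02d_gt_marker.png", i))
      write_image(sections[[i]]$marker, gt); record("simulate", gt)
    }
    if (is.null(cfg$annotations)) {
      ann_df <- synthetic_annotations(sections[[1]],
                                      image_id = basename(image_paths[1]),
                                      seed = cfg$seed)
      cfg$annotations <- p("annotations.csv")
      utils::write.csv(ann_df, cfg$annotations, row.names = FALSE, na = "")
      record("simulate", cfg$annotations)
    }
  }
  if (is.null(image_paths)) stop("run_pipeline(): no images configured")
  imgs <- lapply(image_paths, read_image)
  ids <- basename(image_paths)

  tissues <- NULL
  if ("tissue" %in% stages) {
    tissues <- lapply(imgs, function(im)
      do.call(segment_tissue, c(list(im), cfg$tissue)))
    for (i in seq_along(tissues)) {
      f <- p(sprintf("tissue%02d.png", i))
      write_image(tissues[[i]]$mask, f)
      record("tissue", f, params = cfg$tissue)
    }
    sidecar <- p("tissue.json")
    jsonlite::write_json(lapply(tissues, function(t)
      list(TA = t$TA, crop_box = t$crop_box)), sidecar, auto_unbox = TRUE)
    record("tissue", sidecar)
  }

  model <- NULL
  planes_cache <- list()
  planes_for <- function(i) {
    key <- as.character(i)
    if (is.null(planes_cache[[key]]))
      planes_cache[[key]] <<- compute_feature_planes(imgs[[i]],
                                                     cfg$features$sizes)
    planes_cache[[key]]
  }
  if ("train" %in% stages) {
    ann <- read_annotations(cfg$annotations)
    used <- unique(c(ann$marker$image, ann$critical$image, ann$rects$image))
    planes_by_image <- stats::setNames(
      lapply(match(used, ids), planes_for), used)
    ts <- assemble_training_set(ann, planes_by_image)
    model <- train_cascade(ts, sizes = cfg$features$sizes, seed = cfg$seed)
    f <- p("model.rds")
    save_cascade(model, f)
    record("train", f, params = list(sizes = cfg$features$sizes, seed = cfg$seed))
  } else if (!is.null(cfg$model)) {
    model <- load_cascade(cfg$model)
  }

  segs <- NULL
  if ("segment" %in% stages) {
    if (is.null(model)) stop("run_pipeline(): no model for 'segment'")
    if (is.null(tissues)) stop("run_pipeline(): 'segment' needs the 'tissue' stage")
    segs <- lapply(seq_along(imgs), function(i) {
      raw <- apply_cascade(model, imgs[[i]], tissues[[i]],
                           planes = planes_for(i))
      clean_marker_mask(raw)
    })
    for (i in seq_along(segs)) {
      f <- p(sprintf("markers%02d.png", i))
      write_image(segs[[i]]$M, f)
      record("segment", f)
    }
  }

  if ("quantify" %in% stages) {
    if (is.null(segs) || is.null(tissues))
      stop("run_pipeline(): 'quantify' needs 'tissue' and 'segment'")
    dens <- data.frame(image = ids,
                       A_M = vapply(segs, function(s) s$A_M, numeric(1)),
                       TA = vapply(tissues, function(t) t$TA, numeric(1)))
    dens$DM_T_percent <- 100 * dens$A_M / dens$TA
    f <- p("density.csv")
    utils::write.csv(dens, f, row.names = FALSE)
    record("quantify", f, params = cfg$quantify)
  }

  rs <- NULL
  if ("register" %in% stages) {
    if (is.null(tissues)) stop("run_pipeline(): 'register' needs 'tissue'")
    secs <- lapply(seq_along(tissues), function(i)
      list(tissue = tissues[[i]],
           marker = if (!is.null(segs)) segs[[i]] else NULL))
    rs <- register_set(secs, reference = cfg$register$reference)
    f <- p("registration.json")
    jsonlite::write_json(list(
      reference = rs$reference,
      GTRO_before = rs$GTRO_before, GTRO_after = rs$GTRO_after,
      transforms = lapply(rs$transforms, function(t)
        list(tx = t$tx, ty = t$ty, theta = t$theta, scale = t$scale))),
      f, auto_unbox = TRUE, digits = NA)
    record("register", f, params = cfg$register)
  }

  if ("coexist" %in% stages) {
    if (is.null(rs)) stop("run_pipeline(): 'coexist' needs 'register'")
    rep <- coexistence_report(rs, roi = cfg$roi, names = ids)
    f <- p("coexistence_pairs.csv")
    utils::write.csv(rep$pairs, f, row.names = FALSE)
    record("coexist", f)
    f2 <- p("coexistence.json")
    jsonlite::write_json(list(GTRO = rep$GTRO,
                              per_marker = rep$per_marker,
                              pairs = rep$pairs),
                         f2, auto_unbox = TRUE, digits = NA, na = "null")
    record("coexist", f2)
  }

  mf <- p("manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
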