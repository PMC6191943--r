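# Shared fixtures, built once per test run and cached. Training images use
# the two-Gaussian colour model: marker stain N((180, 60, 50), 12) against an
# ink-like distractor N((120, 60, 50), 12) inside the tissue.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_section <- function(seed = 11) {
  cached(paste0("section", seed), generate_section(synthetic_spec(seed = seed)))
}

# trained cascade + its training section, used by classifier and pipeline tests
fixture_trained_cascade <- function() {
  cached("cascade", {
    sec <- fixture_section(11)
    ann <- synthetic_annotations(sec, image_id = "img1",
                                 npos = 150, ncrit = 90, seed = 2)
    pl <- compute_feature_planes(sec$image)
    ts <- assemble_training_set(annotation_set(ann), list(img1 = pl))
    list(model = train_cascade(ts, seed = 3), training_set = ts,
         section = sec, planes = pl)
  })
}

# cluster fixture whose geometry the concentration-region machinery should
# recover: two dense planted clusters plus sparse background dots
fixture_cluster_spec <- function(seed = 31) {
  synthetic_spec(seed = seed, canvas = c(320, 320),
    tissue = list(radius = 118),
    marker = list(layout = list(type = "clusters",
      centers = rbind(c(115, 115), c(205, 200)), sds = c(14, 14),
      ns = c(100, 100),
      background_n = 120, background_sep = 12, background_margin = 18)),
    distractor = list(n_blobs = 0))
}

fixture_cluster_section <- function() {
  cached("cluster_section", generate_section(fixture_cluster_spec()))
}
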