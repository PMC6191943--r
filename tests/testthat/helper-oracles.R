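# Independent brute-force oracles used across the suite. They deliberately
# use the slowest possible formulation (explicit loops / all-pairs scans) so
# they share no code path with the implementation.

brute_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || lab[r, c] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[2] < 1 || p[1] > H || p[2] > W) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] > 0) next
      lab[p[1], p[2]] <- nxt
      for (dr in -1:1) for (dc in -1:1)
        if (dr || dc) stack[[length(stack) + 1L]] <- c(p[1] + dr, p[2] + dc)
    }
  }
  lab
}

brute_min_dist <- function(from_coords, to_mask) {
  tc <- which(to_mask, arr.ind = TRUE)
  apply(from_coords, 1, function(p)
    sqrt(min((tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2)))
}

brute_gtro <- function(masks) {
  inter <- masks[[1]]; uni <- masks[[1]]
  for (m in masks[-1]) { inter <- inter & m; uni <- uni | m }
  100 * sum(inter) / sum(uni)
}

brute_window_stat <- function(img, r, c, n, k) {
  half <- (n - 1) / 2
  rr <- pmin(pmax(r + (-half):half, 1), dim(img)[1])
  cc <- pmin(pmax(c + (-half):half, 1), dim(img)[2])
  w <- img[rr, cc, k]
  c(mu = mean(w), sigma = sqrt(mean(w^2) - mean(w)^2), range = max(w) - min(w))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_mask <- function(H, W, p = 0.3) matrix(stats::runif(H * W) < p, H, W)

# residual of a recovered transform against the ground truth that generated
# the moving mask: compose them and measure how far the composition is from
# the identity (displacement of the canvas centre, angle, scale)
transform_residual <- function(recovered, truth) {
  comp <- compose_transforms(truth, recovered)
  list(t = sqrt(comp$tx^2 + comp$ty^2),
       theta = abs(comp$theta),
       scale = abs(comp$scale - 1))
}
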