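# Shared fixtures and brute-force oracles used across test files.

# Disk painted on a blank raster.
disk_image <- function(n = 64, cy = n / 2, cx = n / 2, r = 8, value = 1000,
                       bg = 0) {
  img <- matrix(bg, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- value
  img
}

# Brute-force nearest-label expansion (the oracle for expand_labels).
brute_expand <- function(lab, distance) {
  out <- lab
  pts <- which(lab > 0, arr.ind = TRUE)
  pl <- lab[lab > 0]
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    if (lab[i, j] > 0) next
    d <- sqrt((pts[, 1] - i)^2 + (pts[, 2] - j)^2)
    dm <- min(d)
    if (dm <= distance) out[i, j] <- min(pl[d == dm])
  }
  out
}

# Brute-force background set for the SBR exclusion gap.
brute_sbr_background <- function(image, threshold, gap) {
  fg <- image > threshold
  fgp <- which(fg, arr.ind = TRUE)
  bg <- matrix(FALSE, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (fg[i, j]) next
    if (min(sqrt((fgp[, 1] - i)^2 + (fgp[, 2] - j)^2)) > gap) bg[i, j] <- TRUE
  }
  bg
}

# Brute-force exact kNN by all-pairs distances, ties to lower index.
brute_knn <- function(x, k) {
  n <- nrow(x)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
}

# Normalized cross-correlation of two rasters.
ncc <- function(a, b) stats::cor(as.vector(a), as.vector(b))

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(tab)
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small aligned multi-round stack fixture built from simulated images.
small_sim <- function(seed = 1, ...) {
  simulate_image_experiment(sim_image_config(
    shape = c(128L, 128L), n_cells = 18L, nucleus_radius_px = c(4, 7),
    rounds = 3L, channels = "c2", af_diffuse_mean = 100, af_n_fibers = 1L,
    seed = seed, ...))
}
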