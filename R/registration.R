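# Evaluate expr with a private RNG stream so package internals are
# deterministic without disturbing the caller's random-number state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a planar affine transform
#'
#' Maps moving-image coordinates `(x, y)` (x = column, y = row, pixels) into
#' the reference frame: `x' = a x + b y + tx`, `y' = c x + d y + ty`.
#'
#' @param a,b,c,d Linear part (must be non-singular).
#' @param tx,ty Translation in pixels.
#' @param residual_rms Root-mean-square residual of the inlier matches used
#'   to fit the transform, in pixels.
#' @param n_inliers Number of inlier correspondences.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0,
                             residual_rms = 0, n_inliers = 0L) {
  det <- a * d - b * c
  if (!is.finite(det) || abs(det) < 1e-12)
    stop("singular affine transform (zero determinant)", call. = FALSE)
  if (residual_rms < 0) stop("residual_rms must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, tx = tx, ty = ty,
                 residual_rms = residual_rms,
                 n_inliers = as.integer(n_inliers)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> [%+.4f %+.4f; %+.4f %+.4f] t=(%.2f, %.2f) rms=%.3f px, %d inliers\n",
              x$a, x$b, x$c, x$d, x$tx, x$ty, x$residual_rms, x$n_inliers))
  invisible(x)
}

#' Apply an affine transform to coordinates
#'
#' @param t An [affine_transform()].
#' @param xy n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_affine <- function(t, xy) {
  xy <- rbind(xy)
  cbind(t$a * xy[, 1] + t$b * xy[, 2] + t$tx,
        t$c * xy[, 1] + t$d * xy[, 2] + t$ty)
}

#' Invert an affine transform
#'
#' @param t An [affine_transform()].
#' @return The inverse `affine_transform` (diagnostic fields copied over).
#' @export
invert_affine <- function(t) {
  det <- t$a * t$d - t$b * t$c
  ia <- t$d / det; ib <- -t$b / det; ic <- -t$c / det; id <- t$a / det
  affine_transform(ia, ib, ic, id,
                   tx = -(ia * t$tx + ib * t$ty),
                   ty = -(ic * t$tx + id * t$ty),
                   residual_rms = t$residual_rms, n_inliers = t$n_inliers)
}

# Blob keypoints: smooth, Otsu-threshold, label, intensity-weighted centroids.
# Nuclei are the natural landmarks of DAPI rasters; weighted centroids give
# sub-pixel localization.
detect_keypoints <- function(img, sigma = 2, min_area = 4) {
  img <- as.matrix(img)
  rng <- range(img)
  if (rng[2] <= rng[1]) return(matrix(numeric(0), 0, 2))
  x <- (img - rng[1]) / (rng[2] - rng[1])
  xs <- imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  lab <- imageData(EBImage::bwlabel(EBImage::Image(xs > thr)))
  n <- max(lab)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  idx <- which(lab > 0)
  l <- lab[idx]
  w <- xs[idx]
  ri <- (idx - 1) %% nrow(img) + 1   # row (y)
  ci <- (idx - 1) %/% nrow(img) + 1  # col (x)
  sw <- rowsum(w, l)
  keep <- rowsum(rep(1, length(l)), l)[, 1] >= min_area & sw[, 1] > 0
  cx <- rowsum(w * ci, l)[, 1] / sw[, 1]
  cy <- rowsum(w * ri, l)[, 1] / sw[, 1]
  cbind(x = cx, y = cy)[keep, , drop = FALSE]
}

# Rotation/translation-invariant descriptor: sorted distances to the m
# nearest other keypoints. Robust to the small (<2%) scale changes seen
# between imaging rounds.
.keypoint_descriptors <- function(pts, m = 12L) {
  n <- nrow(pts)
  m <- min(m, n - 1L)
  d <- as.matrix(stats::dist(pts))
  t(apply(d, 1, function(row) sort(row)[2:(m + 1L)]))
}

.fit_affine_ls <- function(src, dst) {
  # dst ~ linear model in src coordinates, solved per output axis
  A <- cbind(src[, 1], src[, 2], 1)
  px <- qr.solve(A, dst[, 1])
  py <- qr.solve(A, dst[, 2])
  list(a = px[1], b = px[2], tx = px[3], c = py[1], d = py[2], ty = py[3])
}

#' Estimate an affine transform between two rasters
#'
#' Detects blob keypoints (smoothed-threshold nuclei centroids) in both
#' images, matches them by rotation-invariant neighborhood-distance
#' descriptors with a ratio test, and fits the affine transform by robust
#' consensus sampling (3-point RANSAC, inlier tolerance `inlier_tol` px)
#' followed by a least-squares refit on the inliers.
#'
#' @param reference,moving 2-D rasters (matrices), same bit depth.
#' @param min_matches Minimum number of consistent inlier correspondences
#'   required (default 10); fewer raises a registration-failure error that
#'   reports the match count.
#' @param inlier_tol RANSAC inlier tolerance in pixels (default 2).
#' @param residual_max Maximum acceptable inlier RMS residual in pixels
#'   (default 5); above it registration is considered failed.
#' @param ransac_iter Number of consensus-sampling iterations.
#' @param seed Seed for the (internal, restored) consensus sampling stream.
#' @return An [affine_transform()] mapping moving coordinates into the
#'   reference frame, with `n_inliers` and `residual_rms` filled in.
#' @export
estimate_affine <- function(reference, moving, min_matches = 10L,
                            inlier_tol = 2, residual_max = 5,
                            ransac_iter = 500L, seed = 1L) {
  kr <- detect_keypoints(reference)
  km <- detect_keypoints(moving)
  if (nrow(kr) < 3 || nrow(km) < 3)
    stop(sprintf("registration failure: found %d reference / %d moving keypoints (need >= 3)",
                 nrow(kr), nrow(km)), call. = FALSE)
  m <- min(12L, nrow(kr) - 1L, nrow(km) - 1L)
  dr <- .keypoint_descriptors(kr, m)
  dm <- .keypoint_descriptors(km, m)
  # match each moving keypoint to its best reference descriptor (ratio test)
  cross <- outer(rowSums(dm^2), rowSums(dr^2), "+") - 2 * dm %*% t(dr)
  cross[cross < 0] <- 0
  matches <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(dm))) {
    o <- order(cross[i, ])
    best <- o[1]
    ratio_ok <- length(o) < 2 ||
      sqrt(cross[i, best]) < 0.8 * sqrt(cross[i, o[2]]) ||
      cross[i, best] < 1e-9
    if (ratio_ok) matches <- rbind(matches, c(i, best))
  }
  if (nrow(matches) < max(3L, min_matches))
    stop(sprintf("registration failure: only %d descriptor matches (min_matches = %d)",
                 nrow(matches), min_matches), call. = FALSE)
  src <- km[matches[, 1], , drop = FALSE]
  dst <- kr[matches[, 2], , drop = FALSE]
  n <- nrow(src)
  best_inl <- logical(n); best_count <- -1L
  with_local_seed(seed, {
    for (it in seq_len(ransac_iter)) {
      tri <- sample.int(n, 3L)
      s <- src[tri, , drop = FALSE]
      if (abs((s[2, 1] - s[1, 1]) * (s[3, 2] - s[1, 2]) -
              (s[3, 1] - s[1, 1]) * (s[2, 2] - s[1, 2])) < 1e-6) next
      p <- tryCatch(.fit_affine_ls(s, dst[tri, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(p)) next
      pred <- cbind(p$a * src[, 1] + p$b * src[, 2] + p$tx,
                    p$c * src[, 1] + p$d * src[, 2] + p$ty)
      res <- sqrt(rowSums((pred - dst)^2))
      inl <- res <= inlier_tol
      if (sum(inl) > best_count) { best_count <- sum(inl); best_inl <- inl }
    }
  })
  if (best_count < max(3L, min_matches))
    stop(sprintf("registration failure: only %d consistent correspondences (min_matches = %d)",
                 max(best_count, 0L), min_matches), call. = FALSE)
  p <- .fit_affine_ls(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE])
  pred <- cbind(p$a * src[best_inl, 1] + p$b * src[best_inl, 2] + p$tx,
                p$c * src[best_inl, 1] + p$d * src[best_inl, 2] + p$ty)
  rms <- sqrt(mean(rowSums((pred - dst[best_inl, , drop = FALSE])^2)))
  if (rms > residual_max)
    stop(sprintf("registration failure: inlier RMS residual %.2f px exceeds %.2f px",
                 rms, residual_max), call. = FALSE)
  affine_transform(p$a, p$b, p$c, p$d, p$tx, p$ty,
                   residual_rms = rms, n_inliers = best_count)
}

#' Warp a raster into the reference frame
#'
#' Resamples `image` (the moving raster) onto the reference grid under
#' transform `t` using bilinear interpolation; pixels mapping outside the
#' moving image are filled with 0. Integer input yields rounded integer
#' output (dtype preserved).
#'
#' @param image Moving raster (matrix).
#' @param t An [affine_transform()] mapping moving into reference
#'   coordinates.
#' @param out_shape `c(rows, cols)` of the output; default `dim(image)`.
#' @return Warped raster of shape `out_shape`.
#' @export
warp <- function(image, t, out_shape = dim(image)) {
  ti <- invert_affine(t)   # also validates non-singularity
  nr <- out_shape[1]; nc <- out_shape[2]
  xo <- rep(seq_len(nc), each = nr)   # x = column
  yo <- rep(seq_len(nr), times = nc)  # y = row
  xs <- ti$a * xo + ti$b * yo + ti$tx
  ys <- ti$c * xo + ti$d * yo + ti$ty
  mr <- nrow(image); mc <- ncol(image)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- numeric(nr * nc)
  ok <- x0 >= 1 & x0 + 1 <= mc & y0 >= 1 & y0 + 1 <= mr
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * mr + y0[ok]
    v00 <- image[i00]; v10 <- image[i00 + mr]
    v01 <- image[i00 + 1]; v11 <- image[i00 + mr + 1]
    val[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * v00 + fx[ok] * (1 - fy[ok]) * v10 +
      (1 - fx[ok]) * fy[ok] * v01 + fx[ok] * fy[ok] * v11
  }
  # edge pixels exactly on the last row/column sample without interpolation
  edge <- !ok & xs >= 1 & xs <= mc & ys >= 1 & ys <= mr
  if (any(edge)) {
    xe <- pmin(pmax(round(xs[edge]), 1), mc)
    ye <- pmin(pmax(round(ys[edge]), 1), mr)
    val[edge] <- image[(xe - 1) * mr + ye]
  }
  out <- matrix(val, nr, nc)
  if (is.integer(image)) { out <- round(out); storage.mode(out) <- "integer" }
  out
}

#' Register every round of a stack onto the reference round's DAPI
#'
#' Estimates one affine transform per round from that round's DAPI image to
#' the reference round's DAPI, then applies the identical transform to all
#' channels of the round. The reference round (default: the lowest round
#' index present) is returned unchanged.
#'
#' @param stack A `round_stack` from [assemble_stack()].
#' @param ref_round Reference round index; default `min(stack$rounds)`.
#' @param ... Passed to [estimate_affine()].
#' @return The registered `round_stack`; per-round transforms are stored in
#'   `$transforms` (named by round).
#' @export
register_stack <- function(stack, ref_round = min(stack$rounds), ...) {
  ref_dapi <- stack_image(stack, ref_round, "DAPI")
  out_shape <- dim(ref_dapi)
  transforms <- list()
  out <- stack
  for (r in stack$rounds) {
    if (r == ref_round) {
      transforms[[as.character(r)]] <- affine_transform()
      next
    }
    mov_dapi <- stack$images[[.stack_key(r, "DAPI")]]
    t <- tryCatch(estimate_affine(ref_dapi, mov_dapi, ...),
                  error = function(e)
                    stop(sprintf("round %d: %s", r, conditionMessage(e)),
                         call. = FALSE))
    transforms[[as.character(r)]] <- t
    for (ch in stack$channels) {
      key <- .stack_key(r, ch)
      if (!is.null(out$images[[key]]))
        out$images[[key]] <- warp(stack$images[[key]], t, out_shape)
    }
  }
  out$transforms <- transforms
  out$registered <- TRUE
  out
}

#' Serialize round transforms to CSV
#'
#' One row per round: the six affine parameters plus the fit diagnostics.
#'
#' @param transforms Named list of [affine_transform()] (as stored by
#'   [register_stack()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_transforms <- function(transforms, path) {
  df <- do.call(rbind, lapply(names(transforms), function(r) {
    t <- transforms[[r]]
    data.frame(round_index = as.integer(r), a = t$a, b = t$b, c = t$c,
               d = t$d, tx = t$tx, ty = t$ty,
               residual_rms = t$residual_rms, n_inliers = t$n_inliers)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
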