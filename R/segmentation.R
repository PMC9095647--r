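#' Construct a label mask
#'
#' An integer raster in which 0 is background and each positive integer
#' labels one object; nucleus, cell and cytoplasm masks of one scene share a
#' single label space (`nucleus(k)` is contained in `cell(k)`, and
#' `cytoplasm(k) = cell(k)` minus `nucleus(k)`).
#'
#' @param labels Integer matrix, values >= 0.
#' @param compartment `"nucleus"`, `"cell"` or `"cytoplasm"`.
#' @param pixel_size_um Pixel size in micrometers.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, compartment = c("nucleus", "cell", "cytoplasm"),
                       pixel_size_um = 0.325) {
  compartment <- match.arg(compartment)
  labels <- as.matrix(labels)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, compartment = compartment,
                 pixel_size_um = pixel_size_um), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s, %dx%d px, %d objects\n", x$compartment,
              nrow(x$labels), ncol(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

.mask_labels <- function(mask) {
  if (inherits(mask, "label_mask")) mask$labels else {
    m <- as.matrix(mask); storage.mode(m) <- "integer"; m
  }
}

# 1-D Otsu threshold (maximum between-class variance) on a numeric vector.
.otsu_vec <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[2] <= r[1]) return(r[1])
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, all.inside = TRUE),
                           nbins = levels))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

#' Z-project the DAPI channel of a stack
#'
#' Pixelwise maximum of the registered DAPI images across all rounds, so
#' nuclei that detach in later rounds still contribute to segmentation.
#'
#' @param stack A registered `round_stack`.
#' @return Raster matrix (the projection).
#' @export
project_dapi <- function(stack) {
  keys <- names(stack$images)[vapply(stack$meta, function(m)
    m$channel == "DAPI", TRUE)]
  if (length(keys) == 0) stop("stack contains no DAPI images", call. = FALSE)
  proj <- Reduce(pmax, stack$images[keys])
  proj
}

# Euclidean distance of every pixel to the nearest pixel of `set` (logical
# matrix). Exact distance transform via EBImage.
.dist_to_set <- function(set) {
  if (!any(set)) return(matrix(Inf, nrow(set), ncol(set)))
  imageData(distmap(Image(1 - set)))
}

# Prewitt gradient magnitude, the nuclear-contour relief for the watershed.
.prewitt_gradient <- function(img) {
  kx <- matrix(c(1, 0, -1, 1, 0, -1, 1, 0, -1), 3, 3)
  ky <- t(kx)
  gx <- imageData(filter2(Image(img), kx))
  gy <- imageData(filter2(Image(img), ky))
  sqrt(gx^2 + gy^2)
}

# Keep at most max_px pixels of each listed label, dropping the pixels
# farthest from the label's centroid, then retain the connected component
# containing the centroid so labels stay single components.
.clip_label_size <- function(labels, ids, max_px) {
  for (k in ids) {
    idx <- which(labels == k)
    if (length(idx) <= max_px) next
    ri <- (idx - 1) %% nrow(labels) + 1
    ci <- (idx - 1) %/% nrow(labels) + 1
    cy <- mean(ri); cx <- mean(ci)
    d2 <- (ri - cy)^2 + (ci - cx)^2
    drop <- idx[order(d2, decreasing = TRUE)][seq_len(length(idx) - max_px)]
    labels[drop] <- 0L
    # re-connect: keep only the component nearest the centroid
    sub <- labels == k
    comp <- imageData(bwlabel(Image(sub)))
    if (max(comp) > 1) {
      idx2 <- which(sub)
      ri2 <- (idx2 - 1) %% nrow(labels) + 1
      ci2 <- (idx2 - 1) %/% nrow(labels) + 1
      keep_comp <- comp[idx2[which.min((ri2 - cy)^2 + (ci2 - cx)^2)]]
      labels[sub & comp != keep_comp] <- 0L
    }
  }
  labels
}

#' Segment nuclei from a DAPI projection
#'
#' The watershed procedure: (i) white top-hat of the projection isolates
#' nuclear candidates from background, (ii) seeds are local maxima of the
#' top-hat image (above its Otsu threshold, separated by at least
#' `seed_min_distance_px`), (iii) the Prewitt gradient magnitude of the
#' projection provides the nuclear-contour relief, (iv) a seeded watershed
#' grows the seeds over the relief inside the tissue mask, and (v) each
#' nucleus is clipped to a maximum size that depends on whether its seed is
#' cytokeratin-positive (epithelial nuclei are allowed to be larger).
#'
#' @param dapi_proj DAPI projection raster (see [project_dapi()]).
#' @param tophat_radius_px Radius of the disc structuring element
#'   (default 15 px, about one nuclear radius).
#' @param seed_min_distance_px Minimum seed separation (default 5 px).
#' @param size_cap_ck_pos_px2,size_cap_ck_neg_px2 Maximum nuclear area in
#'   px^2 for cytokeratin-positive (default 1200) and -negative (default
#'   600) seeds.
#' @param ck_positive Optional logical vector, one flag per seed label; when
#'   `NULL` all seeds use the positive (larger) cap. See
#'   [seed_marker_positive()].
#' @param pixel_size_um Pixel size recorded in the mask.
#' @return A nucleus [label_mask()].
#' @export
segment_nuclei <- function(dapi_proj, tophat_radius_px = 15,
                           seed_min_distance_px = 5,
                           size_cap_ck_pos_px2 = 1200,
                           size_cap_ck_neg_px2 = 600,
                           ck_positive = NULL, pixel_size_um = 0.325) {
  stopifnot(tophat_radius_px > 0, seed_min_distance_px > 0,
            size_cap_ck_pos_px2 >= size_cap_ck_neg_px2)
  img <- as.matrix(dapi_proj)
  rng <- range(img)
  if (rng[2] <= rng[1]) stop("no seeds found (constant image)", call. = FALSE)
  x <- (img - rng[1]) / (rng[2] - rng[1])
  brush_sz <- 2L * as.integer(tophat_radius_px) + 1L
  th <- imageData(whiteTopHat(Image(x), makeBrush(brush_sz, "disc")))
  thr <- .otsu_vec(as.vector(th))
  fg <- th > thr
  if (!any(fg)) stop("no seeds found", call. = FALSE)
  # local maxima of the (lightly smoothed) top-hat at the minimum distance
  ths <- imageData(gblur(Image(th), sigma = 2))
  mx_sz <- 2L * as.integer(seed_min_distance_px) + 1L
  mx <- imageData(dilate(Image(ths), makeBrush(mx_sz, "disc")))
  peaks <- fg & (ths >= mx - 1e-12)
  if (!any(peaks)) stop("no seeds found", call. = FALSE)
  seeds <- imageData(bwlabel(Image(peaks)))
  storage.mode(seeds) <- "integer"
  # tissue mask to bound the watershed: candidate foreground plus seeds
  xs <- imageData(gblur(Image(x), sigma = 2))
  tissue <- xs > .otsu_vec(as.vector(xs)) | fg
  relief <- .prewitt_gradient(xs)
  relief <- relief / max(relief, 1e-12)
  lab <- imageData(propagate(Image(relief), Image(seeds), mask = Image(tissue)))
  storage.mode(lab) <- "integer"
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (is.null(ck_positive)) {
    pos_ids <- ids
    neg_ids <- integer(0)
  } else {
    if (length(ck_positive) < max(ids))
      stop("ck_positive must supply one flag per seed label", call. = FALSE)
    pos_ids <- ids[ck_positive[ids]]
    neg_ids <- setdiff(ids, pos_ids)
  }
  lab <- .clip_label_size(lab, pos_ids, size_cap_ck_pos_px2)
  lab <- .clip_label_size(lab, neg_ids, size_cap_ck_neg_px2)
  label_mask(lab, "nucleus", pixel_size_um)
}

#' Seed-level marker positivity
#'
#' Classifies each label of a mask as positive for a marker by the mean
#' marker intensity inside a disc of `radius_px` around the label centroid,
#' compared against a threshold (Otsu over the per-label means by default).
#' Used to pick the nuclear size cap before cells exist.
#'
#' @param marker_img Marker raster.
#' @param mask Nucleus/seed [label_mask()] or integer matrix.
#' @param radius_px Disc radius around each centroid (default 10 px).
#' @param threshold Manual threshold on the disc means; `NULL` = Otsu.
#' @return Logical vector indexed by label id.
#' @export
seed_marker_positive <- function(marker_img, mask, radius_px = 10,
                                 threshold = NULL) {
  lab <- .mask_labels(mask)
  .check_same_shape(marker_img, lab)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) return(logical(0))
  nr <- nrow(lab)
  means <- rep(NA_real_, max(ids))
  for (k in ids) {
    idx <- which(lab == k)
    ri <- (idx - 1) %% nr + 1; ci <- (idx - 1) %/% nr + 1
    cy <- mean(ri); cx <- mean(ci)
    rr <- pmax(1, round(cy - radius_px)):pmin(nrow(lab), round(cy + radius_px))
    cc <- pmax(1, round(cx - radius_px)):pmin(ncol(lab), round(cx + radius_px))
    sub <- marker_img[rr, cc, drop = FALSE]
    dd <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2)
    means[k] <- mean(sub[dd <= radius_px^2])
  }
  if (is.null(threshold)) threshold <- .otsu_vec(means[ids])
  out <- means > threshold
  out[is.na(out)] <- FALSE
  out
}

#' Expand labels into surrounding background
#'
#' Each label grows into background pixels within Euclidean distance
#' `distance_px` of the object; a contested pixel goes to the nearest label,
#' with ties broken deterministically in favor of the smaller label id.
#' `distance_px = 0` is the identity. This is the five-pixel (1.6 um)
#' cytoplasm approximation applied to membrane-negative nuclei.
#'
#' @param nuclei A [label_mask()] or integer label matrix.
#' @param distance_px Expansion distance in pixels, >= 0.
#' @param compartment Compartment tag of the returned mask (default
#'   `"cell"`).
#' @return Expanded [label_mask()] with the same label ids.
#' @export
expand_labels <- function(nuclei, distance_px = 5, compartment = "cell") {
  stopifnot(distance_px >= 0)
  lab <- .mask_labels(nuclei)
  ps <- if (inherits(nuclei, "label_mask")) nuclei$pixel_size_um else 0.325
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids) || distance_px == 0)
    return(label_mask(lab, compartment, ps))
  best_d <- matrix(Inf, nrow(lab), ncol(lab))
  best_l <- matrix(0L, nrow(lab), ncol(lab))
  for (k in ids) {             # ascending ids: strict '<' keeps smaller id on ties
    dk <- .dist_to_set(lab == k)
    upd <- dk < best_d
    best_d[upd] <- dk[upd]
    best_l[upd] <- k
  }
  out <- best_l
  out[best_d > distance_px] <- 0L
  label_mask(out, compartment, ps)
}

#' Segment cells from a membrane image and nucleus seeds
#'
#' Membrane-positive nuclei are grown by a seeded watershed on the membrane
#' (E-cadherin) image: all nuclei compete as seeds, together with a
#' background seed placed on low-membrane pixels far from any nucleus, so
#' epithelial cells stop at membrane ridges. Membrane-negative nuclei are
#' instead inflated by [expand_labels()] (`expand_px`, default 5 px).
#' Label ids are preserved from the nucleus mask and every cell contains its
#' nucleus.
#'
#' @param membrane_img Membrane marker raster (e.g. E-cadherin).
#' @param nuclei Nucleus [label_mask()].
#' @param membrane_negative Logical vector indexed by label id; `NULL` =
#'   classify by the mean membrane intensity in the `expand_px` ring (Otsu
#'   cut on ring means).
#' @param expand_px Expansion distance for membrane-negative cells.
#' @param bg_seed_distance_px Background seed distance: low-membrane pixels
#'   farther than this from any nucleus seed the background (default 30 px).
#' @param lambda Regularization of the seeded propagation (see
#'   [EBImage::propagate()]).
#' @return Cell [label_mask()].
#' @export
segment_cells <- function(membrane_img, nuclei, membrane_negative = NULL,
                          expand_px = 5, bg_seed_distance_px = 30,
                          lambda = 1e-4) {
  lab <- .mask_labels(nuclei)
  .check_same_shape(membrane_img, lab)
  ps <- if (inherits(nuclei, "label_mask")) nuclei$pixel_size_um else 0.325
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) return(label_mask(lab, "cell", ps))
  expanded <- expand_labels(nuclei, expand_px)$labels
  if (is.null(membrane_negative)) {
    ring_mean <- vapply(ids, function(k)
      mean(membrane_img[expanded == k & lab != k]), 0)
    thr <- .otsu_vec(ring_mean)
    membrane_negative <- rep(TRUE, max(ids))
    membrane_negative[ids] <- !(ring_mean > thr)
  }
  if (length(membrane_negative) < max(ids))
    stop("membrane_negative must cover all labels", call. = FALSE)
  neg_ids <- ids[membrane_negative[ids]]
  pos_ids <- setdiff(ids, neg_ids)
  if (!length(pos_ids))
    return(label_mask(expanded, "cell", ps))
  # seeded propagation over the membrane landscape with a background seed
  rng <- range(membrane_img)
  relief <- if (rng[2] > rng[1]) (membrane_img - rng[1]) / (rng[2] - rng[1])
            else matrix(0, nrow(lab), ncol(lab))
  bg_id <- max(ids) + 1L
  seeds <- lab
  dn <- .dist_to_set(lab > 0)
  memb_lo <- relief < .otsu_vec(as.vector(relief))
  seeds[lab == 0L & dn > bg_seed_distance_px & memb_lo] <- bg_id
  ws <- imageData(propagate(Image(relief), Image(seeds), lambda = lambda))
  storage.mode(ws) <- "integer"
  ws[ws == bg_id] <- 0L
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in neg_ids) out[expanded == k] <- k
  for (k in pos_ids) out[ws == k & out == 0L] <- k
  # every cell must contain its nucleus
  for (k in pos_ids) out[lab == k] <- k
  label_mask(out, "cell", ps)
}

#' Derive cytoplasm masks
#'
#' `cytoplasm(k) = cell(k)` minus `nucleus(k)`; a label's cytoplasm may be
#' empty (cell identical to nucleus). Every nucleus must lie inside its
#' cell.
#'
#' @param cell Cell [label_mask()].
#' @param nuclei Nucleus [label_mask()] sharing the label space.
#' @return Cytoplasm [label_mask()].
#' @export
derive_cytoplasm <- function(cell, nuclei) {
  cl <- .mask_labels(cell)
  nl <- .mask_labels(nuclei)
  .check_same_shape(cl, nl)
  nid <- setdiff(unique(as.vector(nl)), 0L)
  cid <- setdiff(unique(as.vector(cl)), 0L)
  extra <- setdiff(nid, cid)
  if (length(extra))
    stop("label sets mismatch: nuclei without cells: ",
         paste(sort(extra), collapse = ", "), call. = FALSE)
  bad <- sort(unique(nl[nl > 0L & cl != nl]))
  if (length(bad))
    stop("containment violation: nucleus outside cell for labels ",
         paste(bad, collapse = ", "), call. = FALSE)
  cyt <- cl
  cyt[nl > 0L] <- 0L
  ps <- if (inherits(cell, "label_mask")) cell$pixel_size_um else 0.325
  label_mask(cyt, "cytoplasm", ps)
}
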