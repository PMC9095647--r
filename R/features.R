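#' Mean intensity per label
#'
#' Arithmetic mean of the raster values under each label of a mask. Labels
#' with an empty compartment (possible for cytoplasm) get `NA`, never 0, so
#' downstream thresholding and normalization are not biased.
#'
#' @param image Raster matrix.
#' @param mask [label_mask()] or integer label matrix.
#' @param ids Label ids to report; default: all labels present in `mask`.
#' @return Named numeric vector, one entry per label id.
#' @export
mean_intensity <- function(image, mask, ids = NULL) {
  lab <- .mask_labels(mask)
  .check_same_shape(image, lab)
  present <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (is.null(ids)) ids <- present
  out <- setNames(rep(NA_real_, length(ids)), ids)
  sel <- lab > 0L
  if (any(sel)) {
    s <- rowsum(as.numeric(image[sel]), lab[sel])
    n <- rowsum(rep(1, sum(sel)), lab[sel])
    m <- setNames(s[, 1] / n[, 1], rownames(s))
    hit <- intersect(names(m), names(out))
    out[hit] <- m[hit]
  }
  out
}

#' Morphological features per label
#'
#' Area (pixel count), centroid (mean pixel coordinates, `x` = column,
#' `y` = row) and eccentricity of the ellipse with matching second central
#' moments (`sqrt(1 - minor/major)` on the eigenvalues; 0 for a disk,
#' approaching 1 for a line).
#'
#' @param mask [label_mask()] or integer label matrix.
#' @return Data frame with columns `label`, `area_px2`, `centroid_x`,
#'   `centroid_y`, `eccentricity`.
#' @export
morphology <- function(mask) {
  lab <- .mask_labels(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids))
    return(data.frame(label = integer(0), area_px2 = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      eccentricity = numeric(0)))
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  y <- (idx - 1) %% nr + 1
  x <- (idx - 1) %/% nr + 1
  area <- rowsum(rep(1L, length(l)), l)[, 1]
  cx <- rowsum(as.numeric(x), l)[, 1] / area
  cy <- rowsum(as.numeric(y), l)[, 1] / area
  keys <- as.integer(rownames(rowsum(rep(1L, length(l)), l)))
  pos <- match(l, keys)
  dx <- x - cx[pos]; dy <- y - cy[pos]
  mxx <- rowsum(dx * dx, l)[, 1] / area
  myy <- rowsum(dy * dy, l)[, 1] / area
  mxy <- rowsum(dx * dy, l)[, 1] / area
  tr <- mxx + myy
  det <- mxx * myy - mxy^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(1 - l2 / pmax(l1, 1e-300), 0)))
  ecc <- pmin(ecc, 1 - 1e-12)
  data.frame(label = keys, area_px2 = as.integer(area), centroid_x = cx,
             centroid_y = cy, eccentricity = ecc)[match(ids, keys), ]
}

#' Build the per-cell feature table
#'
#' One row per cell: identifiers, morphology of the nucleus, and the mean
#' intensity of every marker in every compartment
#' (columns `mean_{marker}_{nucleus|cytoplasm|cell}`), plus one
#' `{marker}` column holding the intensity of the marker's
#' biologically-relevant compartment (e.g. cytoplasm for CK19, nucleus for
#' Ki67) as given by `marker_compartments`.
#'
#' @param stack Registered (and usually AF-corrected) `round_stack`; every
#'   non-blank, non-DAPI image contributes one marker.
#' @param masks Named list with elements `nucleus`, `cell`, `cytoplasm`
#'   ([label_mask()] objects sharing one label space).
#' @param marker_compartments Named character vector mapping markers to
#'   `"nucleus"`, `"cytoplasm"` or `"cell"`. Unmapped markers default to
#'   `"cell"` with a warning.
#' @param slide_id,scene_id,core_id,batch_id Identifier strings stored in
#'   every row.
#' @return Data frame (the cell table); column order is stable:
#'   identifiers, morphology, per-compartment means, selected intensities.
#' @export
build_cell_table <- function(stack, masks, marker_compartments = character(0),
                             slide_id = "S1", scene_id = "scene01",
                             core_id = "core01", batch_id = "B1") {
  stopifnot(all(c("nucleus", "cell", "cytoplasm") %in% names(masks)))
  nl <- .mask_labels(masks$nucleus)
  cl <- .mask_labels(masks$cell)
  ids_n <- setdiff(sort(unique(as.vector(nl))), 0L)
  ids_c <- setdiff(sort(unique(as.vector(cl))), 0L)
  if (!setequal(ids_n, ids_c))
    stop("label-space mismatch between nucleus and cell masks", call. = FALSE)
  ids <- ids_n
  morph_n <- morphology(masks$nucleus)
  morph_c <- morphology(masks$cell)
  tab <- data.frame(cell_id = ids,
                    slide_id = slide_id, scene_id = scene_id,
                    core_id = core_id, batch_id = batch_id,
                    centroid_x = morph_n$centroid_x[match(ids, morph_n$label)],
                    centroid_y = morph_n$centroid_y[match(ids, morph_n$label)],
                    nucleus_area_px2 = morph_n$area_px2[match(ids, morph_n$label)],
                    cell_area_px2 = morph_c$area_px2[match(ids, morph_c$label)],
                    eccentricity = morph_n$eccentricity[match(ids, morph_n$label)],
                    stringsAsFactors = FALSE)
  is_marker <- vapply(stack$meta, function(m)
    m$channel != "DAPI" && !identical(m$marker, "blank"), TRUE)
  keys <- names(stack$images)[is_marker]
  markers <- vapply(stack$meta[keys], `[[`, "", "marker")
  if (anyDuplicated(markers)) {
    warning("duplicate marker acquisitions; keeping the first of each",
            call. = FALSE)
    keys <- keys[!duplicated(markers)]
    markers <- markers[!duplicated(markers)]
  }
  comp_names <- c("nucleus", "cytoplasm", "cell")
  for (i in seq_along(keys)) {
    img <- stack$images[[keys[i]]]
    for (cp in comp_names) {
      v <- mean_intensity(img, masks[[cp]], ids = ids)
      tab[[sprintf("mean_%s_%s", markers[i], cp)]] <- unname(v)
    }
  }
  unmapped <- setdiff(markers, names(marker_compartments))
  if (length(unmapped)) {
    warning("markers without a compartment mapping default to 'cell': ",
            paste(unmapped, collapse = ", "), call. = FALSE)
    marker_compartments[unmapped] <- "cell"
  }
  for (m in markers) {
    cp <- match.arg(marker_compartments[[m]], comp_names)
    tab[[m]] <- tab[[sprintf("mean_%s_%s", m, cp)]]
    attr(tab, "selected_compartment") <-
      c(attr(tab, "selected_compartment"), setNames(cp, m))
  }
  tab
}

#' Marker columns of a cell table
#'
#' @param table Cell table from [build_cell_table()] or
#'   [simulate_cell_table()].
#' @return Character vector of selected-intensity (marker) column names.
#' @export
marker_columns <- function(table) {
  sel <- attr(table, "selected_compartment")
  if (!is.null(sel)) return(names(sel))
  core <- c(.CELLTABLE_ID_COLS, "centroid_x", "centroid_y",
            "nucleus_area_px2", "cell_area_px2", "eccentricity")
  cand <- setdiff(names(table), core)
  cand[!grepl("^mean_", cand) & vapply(table[cand], is.numeric, TRUE)]
}

#' Quartile assignment
#'
#' Assigns each value its quartile (1 = lowest) by inclusive quantile cut on
#' the analyzed population, as used for nuclear-area and eccentricity
#' stratification of tissue retention.
#'
#' @param x Numeric vector.
#' @return Integer vector of quartile indices in `1:4`.
#' @export
quartile_bins <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  findInterval(x, q, left.open = TRUE) + 1L
}
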