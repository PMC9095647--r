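#' Construct a threshold record
#'
#' A per-marker intensity threshold with its provenance: set by eye
#' (`manual`), by the Li minimum-cross-entropy algorithm (`li`), from
#' exclusive-marker-pair background estimation (`restore`), or as the third
#' quartile of the reverse subcellular compartment (`reverse_quantile`).
#'
#' @param marker Marker name.
#' @param value Threshold intensity, >= 0. "Positive" always means strictly
#'   greater than the threshold (ties on integer data count as negative).
#' @param provenance One of `"manual"`, `"li"`, `"restore"`,
#'   `"reverse_quantile"`.
#' @param scope `"pixel"` or `"cell_mean"`.
#' @return A `threshold_record`.
#' @export
threshold_record <- function(marker, value,
                             provenance = c("manual", "li", "restore",
                                            "reverse_quantile"),
                             scope = c("pixel", "cell_mean")) {
  if (value < 0) stop("threshold must be >= 0", call. = FALSE)
  structure(list(marker = marker, value = value,
                 provenance = match.arg(provenance),
                 scope = match.arg(scope)),
            class = "threshold_record")
}

.threshold_value <- function(t) if (inherits(t, "threshold_record")) t$value else t

#' Signal-to-background ratio from a pixel threshold
#'
#' Foreground is every pixel strictly above the threshold. Background is
#' every pixel at or below the threshold that lies more than `gap_px`
#' (Euclidean; default 30 px = 10 um at 0.325 um/px) from any foreground
#' pixel, excluding lateral bleed-through around positive staining, and
#' outside the optional artifact exclusion mask.
#' `SBR = (mean FG - mean BG) / mean BG`. A marker with no positive pixels
#' is flagged `negative_in_tissue` and not scored.
#'
#' @param image Raster matrix.
#' @param t [threshold_record()] or numeric threshold.
#' @param gap_px Exclusion gap around foreground, in pixels (>= 0).
#' @param exclusion_mask Optional logical matrix; `TRUE` pixels (manually
#'   erased artifacts) are excluded from both sets.
#' @return An `sbr_result`: `marker`, `fg_mean`, `bg_mean`, `sbr`,
#'   `n_fg_px`, `n_bg_px`, `negative_in_tissue`.
#' @export
sbr_from_threshold <- function(image, t, gap_px = 30, exclusion_mask = NULL) {
  stopifnot(gap_px >= 0)
  tv <- .threshold_value(t)
  marker <- if (inherits(t, "threshold_record")) t$marker else NA_character_
  keep <- if (is.null(exclusion_mask)) {
    matrix(TRUE, nrow(image), ncol(image))
  } else {
    .check_same_shape(image, exclusion_mask)
    !exclusion_mask
  }
  fg <- image > tv & keep
  if (!any(fg)) {
    return(structure(list(marker = marker, fg_mean = NA_real_,
                          bg_mean = NA_real_, sbr = NA_real_,
                          n_fg_px = 0L, n_bg_px = 0L,
                          negative_in_tissue = TRUE), class = "sbr_result"))
  }
  d <- .dist_to_set(fg)
  bg <- image <= tv & d > gap_px & keep
  if (!any(bg)) stop("no background pixels (gap too large?)", call. = FALSE)
  fg_mean <- mean(image[fg]); bg_mean <- mean(image[bg])
  structure(list(marker = marker, fg_mean = fg_mean, bg_mean = bg_mean,
                 sbr = (fg_mean - bg_mean) / bg_mean,
                 n_fg_px = sum(fg), n_bg_px = sum(bg),
                 negative_in_tissue = FALSE), class = "sbr_result")
}

#' @export
print.sbr_result <- function(x, ...) {
  if (x$negative_in_tissue) cat("<sbr_result> negative in tissue\n")
  else cat(sprintf("<sbr_result> sbr=%.3f (fg=%.1f n=%d, bg=%.1f n=%d)\n",
                   x$sbr, x$fg_mean, x$n_fg_px, x$bg_mean, x$n_bg_px))
  invisible(x)
}

#' Quantile-based dynamic range and SBR estimate
#'
#' When no manual threshold is set, the dynamic range is estimated from the
#' 4th and 99.5th percentile of intensity, and SBR as
#' `(q99.5 - q4) / q4`. The 99.5th (not a higher) percentile reflects both
#' common and rare markers.
#'
#' @param values Per-cell (or per-pixel) intensities.
#' @param q_low,q_high Quantile probabilities (defaults 0.04 and 0.995).
#' @return List with `dynamic_range` (the two quantile values), `sbr_est`
#'   (`NA` and `undefined = TRUE` when the low quantile is 0).
#' @export
sbr_from_quantiles <- function(values, q_low = 0.04, q_high = 0.995) {
  values <- values[is.finite(values)]
  if (length(values) < 100)
    warning("fewer than 100 values; quantile SBR estimate is unstable",
            call. = FALSE)
  q <- quantile(values, c(q_low, q_high), names = FALSE)
  if (q[1] == 0)
    return(list(dynamic_range = q, sbr_est = NA_real_, undefined = TRUE))
  list(dynamic_range = q, sbr_est = (q[2] - q[1]) / q[1], undefined = FALSE)
}

#' Fraction of positive cells
#'
#' @param cell_values Per-cell intensities.
#' @param t [threshold_record()] or numeric threshold; positive = strictly
#'   above.
#' @return Fraction in `[0, 1]`.
#' @export
percent_positive <- function(cell_values, t) {
  if (!length(cell_values)) stop("no cells", call. = FALSE)
  mean(cell_values > .threshold_value(t))
}

#' Ratio of two replicate metrics
#'
#' Relative SBR / relative percent-positive between two conditions or
#' replicates (near 1 for reproducible staining).
#'
#' @param metric_a,metric_b Scalars; `metric_b > 0`.
#' @return `metric_a / metric_b`.
#' @export
relative_ratio <- function(metric_a, metric_b) {
  if (!is.finite(metric_b) || metric_b <= 0)
    stop("denominator metric must be positive", call. = FALSE)
  metric_a / metric_b
}

#' Li minimum-cross-entropy threshold
#'
#' Iterative scheme: from the current threshold, compute the means of the
#' values below and above it, and update
#' `t <- (mu_above - mu_below) / (log(mu_above) - log(mu_below))` until
#' convergence. Initial guess is the mean. Values are shifted to be
#' positive if needed (threshold shifted back).
#'
#' @param values Numeric vector.
#' @param tol Convergence tolerance on the threshold (default 0.5).
#' @param max_iter Iteration cap.
#' @return Threshold value.
#' @export
li_threshold <- function(values, tol = 0.5, max_iter = 100L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no values", call. = FALSE)
  shift <- 0
  if (min(values) <= 0) { shift <- 1 - min(values); values <- values + shift }
  t_cur <- mean(values)
  for (i in seq_len(max_iter)) {
    lo <- values[values <= t_cur]; hi <- values[values > t_cur]
    if (!length(lo) || !length(hi)) break
    m_lo <- mean(lo); m_hi <- mean(hi)
    if (m_lo <= 0 || m_hi <= 0 || m_lo == m_hi) break
    t_new <- (m_hi - m_lo) / (log(m_hi) - log(m_lo))
    if (abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur - shift
}

#' Tissue retention over rounds
#'
#' Cells are considered retained in a round if their mean DAPI intensity
#' exceeds that round's Li threshold. The reference population is the cells
#' retained in the first round, so `retention(first round) = 1`; later
#' rounds report the fraction of those reference cells still above the
#' (per-round) Li threshold.
#'
#' @param dapi_by_round Matrix (cells x rounds) or data frame of per-cell
#'   mean DAPI, columns ordered by round, or a named list of equal-length
#'   vectors. The same cell index must run across rounds.
#' @param denominator `"round1_positive"` (default) or `"all_cells"`.
#' @param log_space Compute the Li threshold on `log2(x + 1)` intensities
#'   (default). Fluorescence intensities are approximately lognormal and
#'   span decades; on the raw scale the minimum-cross-entropy iteration can
#'   lodge inside the bright nuclear mode when few cells have detached.
#' @return Named numeric vector: retained fraction per round.
#' @export
tissue_retention <- function(dapi_by_round,
                             denominator = c("round1_positive", "all_cells"),
                             log_space = TRUE) {
  denominator <- match.arg(denominator)
  m <- if (is.list(dapi_by_round) && !is.data.frame(dapi_by_round))
    do.call(cbind, dapi_by_round) else as.matrix(dapi_by_round)
  if (ncol(m) < 1 || nrow(m) < 1) stop("empty round data", call. = FALSE)
  rn <- colnames(m)
  if (is.null(rn)) rn <- as.character(seq_len(ncol(m)))
  thr <- if (log_space) {
    m <- log2(m + 1)
    apply(m, 2, li_threshold, tol = 0.01)
  } else {
    apply(m, 2, li_threshold)
  }
  ref <- if (denominator == "round1_positive") m[, 1] > thr[1]
         else rep(TRUE, nrow(m))
  if (!any(ref)) stop("no reference cells above the round-1 threshold",
                      call. = FALSE)
  ret <- vapply(seq_len(ncol(m)), function(j) mean(m[ref, j] > thr[j]), 0)
  if (denominator == "round1_positive") ret[1] <- 1
  setNames(pmin(ret, 1), rn)
}

#' Precision, recall and F1 from per-cell annotation
#'
#' Cells are annotated `TP`, `FP`, `FN` or `TN` (e.g. against manual review
#' of an autofluorescence threshold); the standard confusion-matrix metrics
#' are returned.
#'
#' @param annotations Character/factor vector over `{"TP","FP","FN","TN"}`
#'   covering all cells.
#' @return List with `precision`, `recall`, `f1` and the four counts.
#' @export
f1_vs_annotation <- function(annotations) {
  annotations <- as.character(annotations)
  bad <- setdiff(unique(annotations), c("TP", "FP", "FN", "TN"))
  if (length(bad))
    stop("unknown annotation labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tp <- sum(annotations == "TP"); fp <- sum(annotations == "FP")
  fn <- sum(annotations == "FN"); tn <- sum(annotations == "TN")
  if (tp + fn == 0) stop("no positives in annotation", call. = FALSE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
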