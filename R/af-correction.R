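# Channels receiving autofluorescence subtraction by default: the AF488,
# AF555 and AF647 dyes (c2..c4). DAPI passes through, and AF750 (c5) shows
# minimal tissue autofluorescence, so neither is corrected unless asked.
.DEFAULT_AF_CHANNELS <- c("c2", "c3", "c4")

#' Default autofluorescence-corrected channels
#'
#' @return Character vector of channel names corrected by default
#'   (`c2`, `c3`, `c4`, i.e. AF488/AF555/AF647).
#' @export
af_corrected_channels <- function() .DEFAULT_AF_CHANNELS

#' Scale a blank image to a target exposure
#'
#' Fluorescence intensity is approximately linear in camera integration
#' time, so a blank (unstained-tissue) acquisition taken at one exposure is
#' rescaled to the marker image's exposure by the exposure ratio.
#'
#' @param blank Blank raster (matrix).
#' @param blank_exposure_ms,target_exposure_ms Exposures in ms, > 0.
#' @return Real-valued raster `blank * target_exposure_ms / blank_exposure_ms`
#'   (no clipping or integer cast).
#' @export
scale_background <- function(blank, blank_exposure_ms, target_exposure_ms) {
  if (!is.numeric(blank_exposure_ms) || blank_exposure_ms <= 0 ||
      !is.numeric(target_exposure_ms) || target_exposure_ms <= 0)
    stop("exposures must be positive", call. = FALSE)
  blank * (target_exposure_ms / blank_exposure_ms)
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
}

.finish_subtraction <- function(diff, clamp, integer_out) {
  if (!clamp) return(diff)
  out <- pmax(diff, 0)
  if (integer_out) {
    out <- round(pmin(out, 65535))
    storage.mode(out) <- "integer"
  }
  out
}

#' Baseline autofluorescence subtraction
#'
#' Subtracts a single exposure-scaled blank acquisition (ideally collected
#' after three or four rounds of quenching, where tissue autofluorescence is
#' near its minimum) from a marker image. Negative differences are clamped
#' to zero so the unsigned output never wraps around; over-subtraction is
#' thereby bounded.
#'
#' @param marker_img Marker raster.
#' @param baseline_blank Blank raster registered to the marker image.
#' @param marker_exposure_ms,blank_exposure_ms Exposures in ms.
#' @param clamp If `FALSE`, return the signed floating-point difference for
#'   diagnostics instead of the clamped 16-bit image.
#' @return Corrected raster (integer, >= 0) or signed matrix if
#'   `clamp = FALSE`.
#' @export
subtract_baseline <- function(marker_img, baseline_blank, marker_exposure_ms,
                              blank_exposure_ms, clamp = TRUE) {
  .check_same_shape(marker_img, baseline_blank)
  sb <- scale_background(baseline_blank, blank_exposure_ms, marker_exposure_ms)
  .finish_subtraction(marker_img - sb, clamp, is.integer(marker_img))
}

#' Background set for interpolated subtraction
#'
#' Pairs an early and a late blank acquisition of one channel so the
#' autofluorescence at an intermediate round can be interpolated.
#'
#' @param early_blank,late_blank Blank rasters registered to the stack.
#' @param early_round,late_round Rounds at which they were acquired
#'   (`late_round > early_round`).
#' @param early_exposure_ms,late_exposure_ms Exposures in ms.
#' @return A `background_set` object.
#' @export
background_set <- function(early_blank, early_round, early_exposure_ms,
                           late_blank = NULL, late_round = NULL,
                           late_exposure_ms = NULL) {
  if (!is.null(late_blank)) {
    .check_same_shape(early_blank, late_blank)
    if (is.null(late_round) || late_round <= early_round)
      stop("late blank round must be greater than early blank round",
           call. = FALSE)
    if (is.null(late_exposure_ms) || late_exposure_ms <= 0)
      stop("late blank exposure must be positive", call. = FALSE)
  }
  if (early_exposure_ms <= 0) stop("early blank exposure must be positive",
                                   call. = FALSE)
  if (early_round == 0)
    warning("early blank is the round-0 (pre-quench) acquisition; ",
            "autofluorescence drops ~25% during the first quench, so a ",
            "post-quench blank (round 3-4) is recommended", call. = FALSE)
  structure(list(early_blank = early_blank, early_round = early_round,
                 early_exposure_ms = early_exposure_ms,
                 late_blank = late_blank, late_round = late_round,
                 late_exposure_ms = late_exposure_ms),
            class = "background_set")
}

#' Round-interpolated ("scaled") autofluorescence subtraction
#'
#' Estimates the autofluorescence at round `r` by linear interpolation
#' between exposure-scaled blank images collected at the beginning and end
#' of staining, then subtracts the estimate:
#' `AF(r) = (1 - w) B_early + w B_late`, `w = (r - r_e) / (r_l - r_e)`.
#' For rounds outside `[r_e, r_l]` the weight is clamped to `[0, 1]`
#' (no extrapolation, which risks over-subtraction).
#'
#' @param marker_img Marker raster acquired at round `r`.
#' @param r Round index of the marker image.
#' @param bg A [background_set()] with both blanks present.
#' @param marker_exposure_ms Exposure of the marker image (ms).
#' @param clamp As in [subtract_baseline()].
#' @return Corrected raster.
#' @export
subtract_interpolated <- function(marker_img, r, bg, marker_exposure_ms,
                                  clamp = TRUE) {
  stopifnot(inherits(bg, "background_set"))
  if (is.null(bg$late_blank))
    stop("background_set has no late blank: use the baseline algorithm ",
         "(subtract_baseline) instead", call. = FALSE)
  .check_same_shape(marker_img, bg$early_blank)
  w <- (r - bg$early_round) / (bg$late_round - bg$early_round)
  w <- min(max(w, 0), 1)
  be <- scale_background(bg$early_blank, bg$early_exposure_ms, marker_exposure_ms)
  bl <- scale_background(bg$late_blank, bg$late_exposure_ms, marker_exposure_ms)
  af <- (1 - w) * be + w * bl
  .finish_subtraction(marker_img - af, clamp, is.integer(marker_img))
}

#' Autofluorescence-correct a registered stack
#'
#' Applies [subtract_baseline()] or [subtract_interpolated()] to every
#' marker image of the selected channels; DAPI and unselected channels pass
#' through unchanged. Blank acquisitions (`marker == "blank"`) are left in
#' the stack untouched.
#'
#' @param stack Registered `round_stack`.
#' @param backgrounds Named list of [background_set()], one per corrected
#'   channel.
#' @param algorithm `"baseline"` (early blank only) or `"scaled"`
#'   (round-interpolated between the two blanks).
#' @param channels Channels to correct; default [af_corrected_channels()].
#' @return The corrected `round_stack`.
#' @export
correct_stack <- function(stack, backgrounds,
                          algorithm = c("baseline", "scaled"),
                          channels = af_corrected_channels()) {
  algorithm <- match.arg(algorithm)
  out <- stack
  for (key in names(stack$images)) {
    meta <- stack$meta[[key]]
    if (!(meta$channel %in% channels) || identical(meta$marker, "blank")) next
    bg <- backgrounds[[meta$channel]]
    if (is.null(bg))
      stop("no background_set supplied for channel ", meta$channel,
           call. = FALSE)
    out$images[[key]] <- if (algorithm == "baseline") {
      subtract_baseline(stack$images[[key]], bg$early_blank,
                        meta$exposure_ms, bg$early_exposure_ms)
    } else {
      subtract_interpolated(stack$images[[key]], meta$round_index, bg,
                            meta$exposure_ms)
    }
  }
  out$af_corrected <- algorithm
  out
}
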