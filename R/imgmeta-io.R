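# Channels of the five-filter CyCIF acquisition; c2..c5 carry the quenchable
# Alexa Fluor dyes, DAPI is the nuclear counterstain used for registration.
.CHANNELS <- c("DAPI", "c2", "c3", "c4", "c5")

.DEFAULT_FLUORS <- c(DAPI = "DAPI", c2 = "AF488", c3 = "AF555",
                     c4 = "AF647", c5 = "AF750")

#' Channel-to-fluorophore map
#'
#' Default assignment of acquisition channels to Alexa Fluor dyes used
#' throughout the package (`c2` = AF488, `c3` = AF555, `c4` = AF647,
#' `c5` = AF750).
#'
#' @return Named character vector mapping channel names to fluor labels.
#' @export
channel_fluors <- function() .DEFAULT_FLUORS

#' Construct image metadata
#'
#' One record per acquired raster: slide, scene, staining round, channel,
#' marker and camera exposure. Round 0 denotes a pre-staining blank
#' acquisition; `marker = "blank"` marks unstained autofluorescence images
#' in any round.
#'
#' @param slide_id,scene_id Identifier strings.
#' @param round_index Integer staining round, >= 0.
#' @param marker Marker name, or `"blank"` for unstained acquisitions.
#' @param channel One of `"DAPI"`, `"c2"`, `"c3"`, `"c4"`, `"c5"`.
#' @param exposure_ms Camera exposure time in milliseconds, > 0.
#' @param pixel_size_um Pixel size in micrometers (default 0.325, a 20x scan).
#' @return An object of class `image_meta`.
#' @export
image_meta <- function(slide_id, scene_id, round_index, marker, channel,
                       exposure_ms, pixel_size_um = 0.325) {
  round_index <- as.integer(round_index)
  if (is.na(round_index) || round_index < 0)
    stop("round_index must be a non-negative integer", call. = FALSE)
  channel <- match.arg(channel, .CHANNELS)
  exposure_ms <- as.numeric(exposure_ms)
  if (is.na(exposure_ms) || exposure_ms <= 0)
    stop("exposure_ms must be positive", call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive", call. = FALSE)
  structure(list(slide_id = as.character(slide_id),
                 scene_id = as.character(scene_id),
                 round_index = round_index,
                 marker = as.character(marker),
                 channel = channel,
                 fluor = unname(.DEFAULT_FLUORS[channel]),
                 exposure_ms = exposure_ms,
                 pixel_size_um = pixel_size_um),
            class = "image_meta")
}

#' @export
print.image_meta <- function(x, ...) {
  cat(sprintf("<image_meta> %s/%s round %d %s (%s, %s) %gms\n",
              x$slide_id, x$scene_id, x$round_index, x$marker, x$channel,
              x$fluor, x$exposure_ms))
  invisible(x)
}

#' Parse an image filename into metadata
#'
#' The package's naming convention is
#' `{slide}_{scene}_R{round}_{marker}_{channel}_{exposure}ms.tif`,
#' e.g. `S1_scene01_R2_CK19_c5_100ms.tif`. The convention is this package's
#' own (acquisition software exports vary); an alternative layout can be
#' supplied as a template naming the same six fields.
#'
#' @param name File name (directories and the `.tif`/`.tiff` extension are
#'   ignored).
#' @param template Field order, default
#'   `"{slide}_{scene}_R{round}_{marker}_{channel}_{exposure}ms"`. Only the
#'   order of the six placeholders is honored; fields are split on `_`.
#' @param pixel_size_um Pixel size recorded in the returned metadata.
#' @return An [image_meta()] object.
#' @export
parse_filename <- function(name,
                           template = "{slide}_{scene}_R{round}_{marker}_{channel}_{exposure}ms",
                           pixel_size_um = 0.325) {
  base <- sub("\\.tiff?$", "", basename(name), ignore.case = TRUE)
  fields <- regmatches(template, gregexpr("\\{([a-z]+)\\}", template))[[1]]
  fields <- gsub("[{}]", "", fields)
  needed <- c("slide", "scene", "round", "marker", "channel", "exposure")
  if (!setequal(fields, needed))
    stop("template must contain exactly the fields ",
         paste(needed, collapse = ", "), call. = FALSE)
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) != length(fields))
    stop(sprintf("cannot parse '%s': expected %d '_'-separated fields (%s), got %d",
                 name, length(fields), paste(fields, collapse = ", "),
                 length(parts)), call. = FALSE)
  names(parts) <- fields
  rtok <- parts[["round"]]
  if (!grepl("^R[0-9]+$", rtok))
    stop(sprintf("cannot parse '%s': missing or malformed round token '%s' (expected R<integer>)",
                 name, rtok), call. = FALSE)
  etok <- parts[["exposure"]]
  if (!grepl("^[0-9]*\\.?[0-9]+(ms)?$", etok))
    stop(sprintf("cannot parse '%s': malformed exposure field '%s'", name, etok),
         call. = FALSE)
  if (!parts[["channel"]] %in% .CHANNELS)
    stop(sprintf("cannot parse '%s': unknown channel '%s'", name,
                 parts[["channel"]]), call. = FALSE)
  image_meta(slide_id = parts[["slide"]], scene_id = parts[["scene"]],
             round_index = as.integer(sub("^R", "", rtok)),
             marker = parts[["marker"]], channel = parts[["channel"]],
             exposure_ms = as.numeric(sub("ms$", "", etok)),
             pixel_size_um = pixel_size_um)
}

#' Format metadata back into a filename
#'
#' Inverse of [parse_filename()]: `parse_filename(format_filename(m))`
#' reproduces `m` field-for-field.
#'
#' @param meta An [image_meta()] object.
#' @param ext File extension, default `".tif"`.
#' @return File name string.
#' @export
format_filename <- function(meta, ext = ".tif") {
  stopifnot(inherits(meta, "image_meta"))
  sprintf("%s_%s_R%d_%s_%s_%gms%s", meta$slide_id, meta$scene_id,
          meta$round_index, meta$marker, meta$channel, meta$exposure_ms, ext)
}

.stack_key <- function(round_index, channel) sprintf("r%d_%s", round_index, channel)

#' Assemble a multi-round image stack
#'
#' Reads a set of image files (or accepts pre-read rasters) and organizes
#' them into a `round_stack` keyed by `(round, channel)`. Every round must
#' contain a DAPI image (required downstream for registration) and no
#' `(round, channel)` key may occur twice. Assembly is order-independent.
#'
#' @param files Character vector of TIFF paths, or a named list of matrices
#'   whose names parse under the filename convention.
#' @param template Filename template passed to [parse_filename()].
#' @param pixel_size_um Pixel size recorded in metadata.
#' @return A `round_stack`: list with `images` (named list of integer
#'   matrices), `meta` (named list of [image_meta()]), `rounds`, `channels`.
#' @export
assemble_stack <- function(files,
                           template = "{slide}_{scene}_R{round}_{marker}_{channel}_{exposure}ms",
                           pixel_size_um = 0.325) {
  if (length(files) == 0) stop("no input files", call. = FALSE)
  if (is.list(files)) {
    metas <- lapply(names(files), parse_filename, template = template,
                    pixel_size_um = pixel_size_um)
    imgs <- files
  } else {
    metas <- lapply(files, parse_filename, template = template,
                    pixel_size_um = pixel_size_um)
    imgs <- lapply(files, read_image)
  }
  scenes <- unique(vapply(metas, function(m) paste(m$slide_id, m$scene_id), ""))
  if (length(scenes) > 1)
    stop("files span multiple scenes: ", paste(scenes, collapse = ", "),
         call. = FALSE)
  keys <- vapply(metas, function(m) .stack_key(m$round_index, m$channel), "")
  dup <- keys[duplicated(keys)]
  if (length(dup))
    stop("duplicate (round, channel) keys: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  ord <- order(keys)
  imgs <- imgs[ord]; metas <- metas[ord]; keys <- keys[ord]
  names(imgs) <- keys; names(metas) <- keys
  rounds <- sort(unique(vapply(metas, `[[`, 0L, "round_index")))
  for (r in rounds) {
    if (!.stack_key(r, "DAPI") %in% keys)
      stop(sprintf("round %d has no DAPI image", r), call. = FALSE)
  }
  structure(list(images = imgs, meta = metas, rounds = rounds,
                 channels = sort(unique(vapply(metas, `[[`, "", "channel")))),
            class = "round_stack")
}

#' @export
print.round_stack <- function(x, ...) {
  cat(sprintf("<round_stack> %d images, rounds {%s}, channels {%s}\n",
              length(x$images), paste(x$rounds, collapse = ","),
              paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Fetch one raster (and its metadata) from a stack
#'
#' @param stack A `round_stack`.
#' @param round_index,channel Key of the image.
#' @return The raster matrix; its [image_meta()] is attached as attribute
#'   `"meta"`.
#' @export
stack_image <- function(stack, round_index, channel) {
  key <- .stack_key(round_index, channel)
  img <- stack$images[[key]]
  if (is.null(img)) stop("no image for key ", key, call. = FALSE)
  attr(img, "meta") <- stack$meta[[key]]
  img
}

#' Read a 16-bit grayscale TIFF as an integer matrix
#'
#' @param path TIFF file path.
#' @return Integer matrix of raw intensity values (0..65535).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  storage.mode(x) <- "integer"
  x
}

#' Write an integer matrix as an uncompressed 16-bit grayscale TIFF
#'
#' Values are clamped to the unsigned 16-bit range before writing. Label
#' masks are written the same way (integer labels as raw values).
#'
#' @param img Numeric or integer matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(round(img), 0), 65535)
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# Mandatory identifier columns of a cell table (feature columns vary by panel).
.CELLTABLE_ID_COLS <- c("cell_id", "slide_id", "scene_id", "core_id", "batch_id")

#' Write a cell feature table to CSV
#'
#' @param table Data frame with at least the identifier columns
#'   `cell_id, slide_id, scene_id, core_id, batch_id`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("cell table is empty", call. = FALSE)
  miss <- setdiff(.CELLTABLE_ID_COLS, names(table))
  if (length(miss))
    stop("cell table lacks mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell feature table from CSV
#'
#' Round-trips through [write_cell_table()] losslessly for identifiers and
#' numeric values (within double-precision I/O).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(.CELLTABLE_ID_COLS, names(tab))
  if (length(miss))
    stop("cell table lacks mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in c("slide_id", "scene_id", "core_id", "batch_id"))
    tab[[cc]] <- as.character(tab[[cc]])
  tab
}
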