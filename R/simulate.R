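#' Configuration for a synthetic multi-round imaging experiment
#'
#' Describes the simulated scene: ellipse nuclei placed without touching,
#' per-round marker signal, a tissue autofluorescence field (diffuse
#' component plus bright curvilinear fibers, 2-10x the signal scale) whose
#' intensity follows a per-round multiplier `af_profile` (default: linear
#' decline to a minimum at round 3, then rise -- the dynamics seen in
#' quenching experiments), per-round registration jitter, and a
#' non-increasing retention schedule emulating tissue loss.
#'
#' @param shape Image `c(rows, cols)` (default 512 x 512).
#' @param n_cells Number of nuclei.
#' @param nucleus_radius_px Semi-major-axis range, pixels.
#' @param nucleus_aspect Axis-ratio range (1 = circle).
#' @param rounds Number of staining rounds.
#' @param channels Marker channels acquired each round.
#' @param dapi_exposure_ms,marker_exposure_ms,blank_exposure_ms Exposures;
#'   `marker_exposure_ms` may be a vector recycled over rounds.
#' @param af_profile Per-round AF multiplier `v(r)` (length `rounds`);
#'   `NULL` = the default piecewise-linear dip at round 3.
#' @param af_diffuse_mean Mean of the diffuse AF component.
#' @param af_n_fibers Number of bright AF fibers.
#' @param jitter_shift_px,jitter_rot_deg Maximum per-round registration
#'   jitter (round 1 is never jittered).
#' @param retention_schedule Per-round retained fraction (non-increasing,
#'   starts at 1); `NULL` = no loss.
#' @param positive_fraction Fraction of cells positive per marker.
#' @param signal_mean Mean positive-cell marker amplitude.
#' @param dapi_mean Mean nuclear DAPI amplitude.
#' @param gaussian_sd Read-noise standard deviation.
#' @param poisson_noise Apply Poisson (shot) noise.
#' @param blank_rounds `c(early, late)` rounds at which blank
#'   autofluorescence acquisitions are simulated.
#' @param seed Seed; together with the config it fully determines the
#'   output.
#' @return A `sim_image_config` list.
#' @export
sim_image_config <- function(shape = c(512L, 512L), n_cells = 150L,
                             nucleus_radius_px = c(5, 9),
                             nucleus_aspect = c(1, 1.6),
                             rounds = 3L, channels = c("c2", "c3"),
                             dapi_exposure_ms = 20,
                             marker_exposure_ms = 100,
                             blank_exposure_ms = 50,
                             af_profile = NULL, af_diffuse_mean = 200,
                             af_n_fibers = 4L,
                             jitter_shift_px = 0, jitter_rot_deg = 0,
                             retention_schedule = NULL,
                             positive_fraction = 0.4, signal_mean = 800,
                             dapi_mean = 3000, gaussian_sd = 3,
                             poisson_noise = TRUE,
                             blank_rounds = NULL, seed = 1L) {
  rounds <- as.integer(rounds)
  if (is.null(af_profile)) {
    dip <- min(3L, rounds)
    af_profile <- c(seq(1, 0.5, length.out = dip),
                    if (rounds > dip) seq(0.5, 0.9, length.out = rounds - dip + 1)[-1])
  }
  stopifnot(length(af_profile) == rounds, all(af_profile > 0))
  if (is.null(retention_schedule)) retention_schedule <- rep(1, rounds)
  stopifnot(length(retention_schedule) == rounds,
            all(diff(retention_schedule) <= 1e-12),
            retention_schedule[1] == 1)
  if (is.null(blank_rounds)) blank_rounds <- c(min(3L, rounds), rounds)
  structure(list(shape = as.integer(shape), n_cells = as.integer(n_cells),
                 nucleus_radius_px = nucleus_radius_px,
                 nucleus_aspect = nucleus_aspect, rounds = rounds,
                 channels = channels, dapi_exposure_ms = dapi_exposure_ms,
                 marker_exposure_ms = rep(marker_exposure_ms,
                                          length.out = rounds),
                 blank_exposure_ms = blank_exposure_ms,
                 af_profile = af_profile,
                 af_diffuse_mean = af_diffuse_mean,
                 af_n_fibers = as.integer(af_n_fibers),
                 jitter_shift_px = jitter_shift_px,
                 jitter_rot_deg = jitter_rot_deg,
                 retention_schedule = retention_schedule,
                 positive_fraction = positive_fraction,
                 signal_mean = signal_mean, dapi_mean = dapi_mean,
                 gaussian_sd = gaussian_sd, poisson_noise = poisson_noise,
                 blank_rounds = as.integer(blank_rounds),
                 seed = as.integer(seed)),
            class = "sim_image_config")
}

# Paint value onto the ellipse of one nucleus; returns linear pixel indices.
.ellipse_pixels <- function(shape, cy, cx, a, b, theta) {
  rr <- max(1, floor(cy - a)):min(shape[1], ceiling(cy + a))
  cc <- max(1, floor(cx - a)):min(shape[2], ceiling(cx + a))
  dy <- outer(rr - cy, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sel <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  (cc[sel[, 2]] - 1) * shape[1] + rr[sel[, 1]]
}

# Bright curvilinear AF structures: smoothed random walks stamped as fibers.
.af_field <- function(shape, diffuse_mean, n_fibers, signal_mean) {
  diffuse <- matrix(runif(prod(shape)), shape[1], shape[2])
  diffuse <- imageData(gblur(Image(diffuse), sigma = min(shape) / 16))
  diffuse <- diffuse / mean(diffuse) * diffuse_mean
  fib <- matrix(0, shape[1], shape[2])
  for (f in seq_len(n_fibers)) {
    y <- runif(1, 1, shape[1]); x <- runif(1, 1, shape[2])
    ang <- runif(1, 0, 2 * pi)
    amp <- runif(1, 2, 10) * signal_mean
    for (s in seq_len(round(0.5 * min(shape)))) {
      ang <- ang + rnorm(1, 0, 0.15)
      y <- y + sin(ang); x <- x + cos(ang)
      if (y < 2 || y > shape[1] - 1 || x < 2 || x > shape[2] - 1) break
      ri <- round(y) + (-1:1); ci <- round(x) + (-1:1)
      fib[ri, ci] <- pmax(fib[ri, ci], amp)
    }
  }
  diffuse + imageData(gblur(Image(fib), sigma = 1))
}

.add_noise <- function(clean, gaussian_sd, poisson_noise) {
  v <- as.vector(clean)
  if (poisson_noise) v <- rpois(length(v), pmax(v, 0))
  if (gaussian_sd > 0) v <- v + rnorm(length(v), 0, gaussian_sd)
  out <- matrix(pmin(pmax(round(v), 0), 65535), nrow(clean), ncol(clean))
  storage.mode(out) <- "integer"
  out
}

#' Simulate a multi-round CyCIF imaging experiment
#'
#' Generates jittered, noisy multi-round images together with every piece
#' of ground truth needed to score the processing stages: the true nucleus
#' and cell label masks, the clean per-round marker signal, the AF field
#' and its per-round multiplier, the planted registration transforms
#' (moving to reference), the per-round retained-cell sets, and blank
#' acquisitions for AF subtraction.
#'
#' @param cfg A [sim_image_config()].
#' @return List with `stack` (unregistered `round_stack`), `truth` (list:
#'   `nuclei`, `cells` label masks; `signal` clean rasters per
#'   round/channel; `af`, `af_profile`; `transforms`; `retained` logical
#'   matrix cells x rounds; `retention`), and `blanks` (named list of
#'   [background_set()] per channel).
#' @export
simulate_image_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_image_config"))
  with_local_seed(cfg$seed, {
    sh <- cfg$shape
    rmax <- max(cfg$nucleus_radius_px)
    # non-touching placement: centers at least two max-radii plus margin apart
    min_sep <- 2 * rmax + 3
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < cfg$n_cells) {
      tries <- tries + 1L
      if (tries > 300L * cfg$n_cells)
        stop("too many cells to place without touching", call. = FALSE)
      p <- c(runif(1, rmax + 2, sh[1] - rmax - 1),
             runif(1, rmax + 2, sh[2] - rmax - 1))
      if (nrow(centers) == 0 ||
          min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= min_sep^2)
        centers <- rbind(centers, p)
    }
    a <- runif(cfg$n_cells, cfg$nucleus_radius_px[1], cfg$nucleus_radius_px[2])
    asp <- runif(cfg$n_cells, cfg$nucleus_aspect[1], cfg$nucleus_aspect[2])
    b <- a / asp
    th <- runif(cfg$n_cells, 0, pi)
    labels <- matrix(0L, sh[1], sh[2])
    pix <- vector("list", cfg$n_cells)
    for (i in seq_len(cfg$n_cells)) {
      pix[[i]] <- .ellipse_pixels(sh, centers[i, 1], centers[i, 2],
                                  a[i], b[i], th[i])
      labels[pix[[i]]] <- i
    }
    nuclei <- label_mask(labels, "nucleus")
    cells <- expand_labels(nuclei, 2, compartment = "cell")
    cellpix <- lapply(seq_len(cfg$n_cells), function(i) which(cells$labels == i))
    dapi_amp <- rlnorm(cfg$n_cells, log(cfg$dapi_mean), 0.25)
    # retention: a fixed random order of loss realizes the schedule exactly
    loss_order <- sample.int(cfg$n_cells)
    retained <- matrix(TRUE, cfg$n_cells, cfg$rounds)
    for (r in seq_len(cfg$rounds)) {
      n_keep <- round(cfg$retention_schedule[r] * cfg$n_cells)
      retained[loss_order[seq_len(cfg$n_cells - n_keep)], r] <- FALSE
    }
    af <- .af_field(sh, cfg$af_diffuse_mean, cfg$af_n_fibers, cfg$signal_mean)
    # per-(round, channel) marker signal: amplitude on the cell footprint
    signal <- list(); amp_gt <- list()
    for (r in seq_len(cfg$rounds)) for (ch in cfg$channels) {
      amp <- rlnorm(cfg$n_cells, log(cfg$signal_mean), 0.5) *
        (runif(cfg$n_cells) < cfg$positive_fraction)
      sig <- matrix(0, sh[1], sh[2])
      for (i in which(amp > 0)) sig[cellpix[[i]]] <- amp[i]
      sig <- imageData(gblur(Image(sig), sigma = 1))
      key <- .stack_key(r, ch)
      signal[[key]] <- sig
      amp_gt[[key]] <- amp
    }
    # ground-truth transforms: moving -> reference (round 1 = identity)
    transforms <- list()
    for (r in seq_len(cfg$rounds)) {
      if (r == 1 || (cfg$jitter_shift_px == 0 && cfg$jitter_rot_deg == 0)) {
        transforms[[as.character(r)]] <- affine_transform()
      } else {
        ang <- runif(1, -1, 1) * cfg$jitter_rot_deg * pi / 180
        dx <- runif(1, -1, 1) * cfg$jitter_shift_px
        dy <- runif(1, -1, 1) * cfg$jitter_shift_px
        cx <- (sh[2] + 1) / 2; cy <- (sh[1] + 1) / 2
        ca <- cos(ang); sa <- sin(ang)
        transforms[[as.character(r)]] <- affine_transform(
          a = ca, b = -sa, c = sa, d = ca,
          tx = cx - ca * cx + sa * cy + dx,
          ty = cy - sa * cx - ca * cy + dy)
      }
    }
    imgs <- list()
    slide <- "S1"; scene <- "scene01"
    for (r in seq_len(cfg$rounds)) {
      keep <- retained[, r]
      dapi_clean <- matrix(0, sh[1], sh[2])
      for (i in which(keep)) dapi_clean[pix[[i]]] <- dapi_amp[i]
      dapi_clean <- imageData(gblur(Image(dapi_clean), sigma = 1)) +
        0.15 * af * cfg$af_profile[r]
      t_r <- transforms[[as.character(r)]]
      mk_img <- function(clean, exposure) {
        sc <- clean * exposure / 100   # 100 ms is the reference exposure
        moved <- if (r == 1) sc else warp(sc, invert_affine(t_r))
        .add_noise(moved, cfg$gaussian_sd, cfg$poisson_noise)
      }
      nm <- sprintf("%s_%s_R%d_DAPI_DAPI_%gms.tif", slide, scene, r,
                    cfg$dapi_exposure_ms)
      imgs[[nm]] <- mk_img(dapi_clean * 100 / cfg$dapi_exposure_ms,
                           cfg$dapi_exposure_ms)
      for (ch in cfg$channels) {
        key <- .stack_key(r, ch)
        # clean signal of the cells still retained, plus the round's AF field
        clean <- matrix(0, sh[1], sh[2])
        amp <- amp_gt[[key]]
        for (i in which(keep & amp > 0)) clean[cellpix[[i]]] <- amp[i]
        clean <- imageData(gblur(Image(clean), sigma = 1)) +
          af * cfg$af_profile[r]
        exp_ms <- cfg$marker_exposure_ms[r]
        nm <- sprintf("%s_%s_R%d_M%d%s_%s_%gms.tif", slide, scene, r, r, ch,
                      ch, exp_ms)
        imgs[[nm]] <- mk_img(clean, exp_ms)
      }
    }
    stack <- assemble_stack(imgs)
    # blank acquisitions (registered, unstained tissue) at the blank rounds
    blanks <- list()
    for (ch in cfg$channels) {
      be <- cfg$blank_rounds[1]; bl <- cfg$blank_rounds[2]
      mk_blank <- function(rb) .add_noise(
        af * cfg$af_profile[rb] * cfg$blank_exposure_ms / 100,
        cfg$gaussian_sd, cfg$poisson_noise)
      blanks[[ch]] <- background_set(
        early_blank = mk_blank(be), early_round = be,
        early_exposure_ms = cfg$blank_exposure_ms,
        late_blank = if (bl > be) mk_blank(bl) else NULL,
        late_round = if (bl > be) bl else NULL,
        late_exposure_ms = if (bl > be) cfg$blank_exposure_ms else NULL)
    }
    list(stack = stack,
         truth = list(nuclei = nuclei, cells = cells, signal = signal,
                      amplitudes = amp_gt, af = af,
                      af_profile = cfg$af_profile, transforms = transforms,
                      retained = retained,
                      retention = colMeans(retained),
                      dapi_amplitude = dapi_amp, centers = centers),
         blanks = blanks, config = cfg)
  })
}

#' Simulate per-cell DAPI intensities over rounds with planted tissue loss
#'
#' Cell-level companion to the image simulator for retention studies at
#' realistic cell counts: retained cells keep a bright nuclear DAPI mean,
#' lost cells drop to background noise from their loss round onward. The
#' planted schedule is realized exactly (rounded to whole cells).
#'
#' @param n_cells Number of cells.
#' @param rounds Number of rounds.
#' @param retention_schedule Per-round retained fraction (non-increasing,
#'   `retention_schedule[1] = 1`).
#' @param dapi_mean,bg_mean Mean intensity of retained nuclei and of
#'   background (lognormal draws).
#' @param seed Seed.
#' @return List: `dapi` (cells x rounds matrix), `retained` (logical
#'   matrix), `retention` (planted per-round fractions).
#' @export
simulate_dapi_retention <- function(n_cells, rounds, retention_schedule,
                                    dapi_mean = 3000, bg_mean = 80,
                                    seed = 1L) {
  stopifnot(length(retention_schedule) == rounds,
            all(diff(retention_schedule) <= 1e-12),
            retention_schedule[1] == 1)
  with_local_seed(seed, {
    loss_order <- sample.int(n_cells)
    retained <- matrix(TRUE, n_cells, rounds)
    for (r in seq_len(rounds)) {
      n_keep <- round(retention_schedule[r] * n_cells)
      retained[loss_order[seq_len(n_cells - n_keep)], r] <- FALSE
    }
    base <- rlnorm(n_cells, log(dapi_mean), 0.3)
    dapi <- matrix(0, n_cells, rounds,
                   dimnames = list(NULL, paste0("round", seq_len(rounds))))
    for (r in seq_len(rounds)) {
      v <- base * stats::runif(n_cells, 0.85, 1.15)
      v[!retained[, r]] <- rlnorm(sum(!retained[, r]), log(bg_mean), 0.4)
      dapi[, r] <- v
    }
    list(dapi = dapi, retained = retained, retention = colMeans(retained))
  })
}

#' Configuration for a synthetic cell table
#'
#' Emulates the statistical structure that normalization and batch
#' evaluation assume: cell types with lognormal marker profiles whose high
#' markers share a per-cell latent expression level (so co-expressed pairs
#' are strongly correlated), mutually exclusive marker pairs planted
#' through disjoint cell types, per-batch multiplicative gain and additive
#' offset, and per-core composition differences.
#'
#' @param n_cells_per_group Cells per (core, batch) group.
#' @param cores,batches Identifier vectors.
#' @param markers Marker names.
#' @param type_profiles Named list: per cell type, the character vector of
#'   markers expressed high. `NULL` = the default 3-type breast panel
#'   (epithelial CK19/Ecad, immune CD45/CD8, stromal aSMA).
#' @param type_proportions Base proportions per type (perturbed per core).
#' @param core_composition_sd Dirichlet-like jitter of type proportions
#'   across cores (0 = identical cores).
#' @param high_mean,bg_mean Location of the high-expression and background
#'   lognormal components.
#' @param latent_sdlog,marker_sdlog,bg_sdlog Lognormal spreads of the shared
#'   per-cell latent level, the marker-specific factor, and background.
#' @param batch_gain,batch_offset Per-batch multiplicative gain and additive
#'   offset (recycled over batches).
#' @param gain_marker_sdlog Lognormal spread of per-marker deviations around
#'   each batch gain (batch effects are marker-specific in practice;
#'   0 disables).
#' @param seed Seed.
#' @return A `sim_table_config` list.
#' @export
sim_table_config <- function(n_cells_per_group = 1000L,
                             cores = c("core01", "core02", "core03"),
                             batches = c("B1", "B2", "B3"),
                             markers = c("CK19", "Ecad", "CD45", "CD8",
                                         "aSMA"),
                             type_profiles = NULL,
                             type_proportions = NULL,
                             core_composition_sd = 0.2,
                             high_mean = 2000, bg_mean = 40,
                             latent_sdlog = 0.8, marker_sdlog = 0.3,
                             bg_sdlog = 0.5,
                             batch_gain = c(1, 1.6, 0.7),
                             batch_offset = 0,
                             gain_marker_sdlog = 0.15,
                             seed = 1L) {
  if (is.null(type_profiles))
    type_profiles <- list(epithelial = c("CK19", "Ecad"),
                          immune = c("CD45", "CD8"),
                          stromal = c("aSMA"))
  if (is.null(type_proportions)) {
    type_proportions <- if (identical(sort(names(type_profiles)),
                                      c("epithelial", "immune", "stromal")))
      c(epithelial = 0.40, immune = 0.35, stromal = 0.25)
    else setNames(rep(1 / length(type_profiles), length(type_profiles)),
                  names(type_profiles))
  }
  stopifnot(all(unlist(type_profiles) %in% markers),
            all(batch_gain > 0))
  structure(list(n_cells_per_group = as.integer(n_cells_per_group),
                 cores = cores, batches = batches, markers = markers,
                 type_profiles = type_profiles,
                 type_proportions = type_proportions,
                 core_composition_sd = core_composition_sd,
                 high_mean = high_mean, bg_mean = bg_mean,
                 latent_sdlog = latent_sdlog, marker_sdlog = marker_sdlog,
                 bg_sdlog = bg_sdlog,
                 batch_gain = rep(batch_gain, length.out = length(batches)),
                 batch_offset = rep(batch_offset,
                                    length.out = length(batches)),
                 gain_marker_sdlog = gain_marker_sdlog,
                 seed = as.integer(seed)),
            class = "sim_table_config")
}

#' Simulate a single-cell feature table with known ground truth
#'
#' Generates the cell table described by [sim_table_config()] and returns,
#' alongside it, the planted ground truth: per-cell types, the exclusive
#' marker pairs implied by the type profiles (pairs never high in the same
#' type, each high somewhere), the per-marker background-ceiling threshold
#' (the 99.5th percentile of the background component, on the unshifted
#' scale and per batch after gain/offset), and the batch parameters.
#'
#' @param cfg A [sim_table_config()].
#' @return List: `table` (data frame), `truth` (list with `types`,
#'   `exclusive_pairs`, `thresholds` (marker x batch matrix),
#'   `base_threshold`, `batch_gain`, `batch_offset`,
#'   `core_proportions`).
#' @export
simulate_cell_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_table_config"))
  with_local_seed(cfg$seed, {
    types <- names(cfg$type_profiles)
    # per-core composition: jittered on the log scale, shared across batches
    core_props <- sapply(cfg$cores, function(co) {
      w <- cfg$type_proportions *
        exp(rnorm(length(types), 0, cfg$core_composition_sd))
      w / sum(w)
    })
    rownames(core_props) <- types
    # marker-specific batch gains: independent lognormal jitter around each
    # batch's base gain (batch effects are marker-specific in practice)
    nm <- length(cfg$markers); nb <- length(cfg$batches)
    gain <- matrix(rep(cfg$batch_gain, each = nm), nm, nb) *
      exp(matrix(rnorm(nm * nb, 0, cfg$gain_marker_sdlog), nm, nb))
    dimnames(gain) <- list(cfg$markers, cfg$batches)
    rows <- list()
    type_all <- character(0)
    for (bi in seq_along(cfg$batches)) for (co in cfg$cores) {
      n <- cfg$n_cells_per_group
      # the planted core composition is realized exactly (largest-remainder
      # rounding), so replicate sections of a core share their composition
      raw_n <- core_props[, co] * n
      cnt <- floor(raw_n)
      rem <- n - sum(cnt)
      if (rem > 0) {
        top <- order(raw_n - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[top] <- cnt[top] + 1L
      }
      ty <- sample(rep(types, cnt))
      latent <- rlnorm(n, 0, cfg$latent_sdlog)
      m <- matrix(NA_real_, n, length(cfg$markers),
                  dimnames = list(NULL, cfg$markers))
      for (mk in cfg$markers) {
        high <- vapply(cfg$type_profiles, function(p) mk %in% p, TRUE)[ty]
        v <- rlnorm(n, log(cfg$bg_mean), cfg$bg_sdlog)
        v[high] <- cfg$high_mean * latent[high] *
          rlnorm(sum(high), 0, cfg$marker_sdlog)
        m[, mk] <- v
      }
      m <- sweep(m, 2, gain[, bi], "*") + cfg$batch_offset[bi]
      df <- data.frame(cell_id = seq_len(n), slide_id = cfg$batches[bi],
                       scene_id = "scene01", core_id = co,
                       batch_id = cfg$batches[bi],
                       stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(m))
      type_all <- c(type_all, ty)
    }
    tab <- do.call(rbind, rows)
    tab$cell_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    # exclusive ground truth: both markers high somewhere, never in one type
    high_in <- sapply(cfg$markers, function(mk)
      vapply(cfg$type_profiles, function(p) mk %in% p, TRUE))
    expressed <- colSums(high_in) > 0
    excl <- list()
    mks <- cfg$markers[expressed]
    for (i in seq_len(length(mks) - 1)) for (j in (i + 1):length(mks)) {
      if (!any(high_in[, mks[i]] & high_in[, mks[j]]))
        excl[[length(excl) + 1L]] <- c(mks[i], mks[j])
    }
    base_thr <- stats::qlnorm(0.995, log(cfg$bg_mean), cfg$bg_sdlog)
    thr <- base_thr * gain +
      matrix(cfg$batch_offset, nm, nb, byrow = TRUE)
    dimnames(thr) <- list(cfg$markers, cfg$batches)
    attr(tab, "selected_compartment") <-
      setNames(rep("cell", length(cfg$markers)), cfg$markers)
    list(table = tab,
         truth = list(types = type_all,
                      exclusive_pairs = excl,
                      thresholds = thr, base_threshold = base_thr,
                      batch_gain = setNames(cfg$batch_gain, cfg$batches),
                      gain_matrix = gain,
                      batch_offset = setNames(cfg$batch_offset, cfg$batches),
                      core_proportions = core_props),
         config = cfg)
  })
}

#' Object-level segmentation score against ground truth
#'
#' Matches predicted to true objects greedily by descending intersection
#' over union (one-to-one); predictions matched at `IoU >= iou_threshold`
#' count as true positives.
#'
#' @param pred,truth [label_mask()] or integer label matrices.
#' @param iou_threshold Match threshold (default 0.5).
#' @return List: `precision`, `recall`, `f1`, `n_pred`, `n_truth`,
#'   `count_error` (relative).
#' @export
segmentation_f1 <- function(pred, truth, iou_threshold = 0.5) {
  p <- .mask_labels(pred); g <- .mask_labels(truth)
  .check_same_shape(p, g)
  both <- p > 0L & g > 0L
  area_p <- table(p[p > 0L]); area_g <- table(g[g > 0L])
  if (!any(both)) {
    tp <- 0L
  } else {
    ov <- table(paste(p[both], g[both]))
    pairs <- do.call(rbind, strsplit(names(ov), " "))
    inter <- as.numeric(ov)
    ap <- as.numeric(area_p[pairs[, 1]])
    ag <- as.numeric(area_g[pairs[, 2]])
    iou <- inter / (ap + ag - inter)
    ord <- order(iou, decreasing = TRUE)
    used_p <- character(0); used_g <- character(0); tp <- 0L
    for (idx in ord) {
      if (iou[idx] < iou_threshold) break
      if (pairs[idx, 1] %in% used_p || pairs[idx, 2] %in% used_g) next
      used_p <- c(used_p, pairs[idx, 1]); used_g <- c(used_g, pairs[idx, 2])
      tp <- tp + 1L
    }
  }
  n_pred <- length(area_p); n_truth <- length(area_g)
  precision <- if (n_pred) tp / n_pred else NA_real_
  recall <- if (n_truth) tp / n_truth else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_pred = n_pred, n_truth = n_truth,
       count_error = abs(n_pred - n_truth) / max(n_truth, 1))
}
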