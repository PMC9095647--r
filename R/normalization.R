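#' Intensity transformation
#'
#' @param values Non-negative intensities.
#' @param kind `"raw"` (identity), `"log2"` (`log2(x + 1)`) or `"arcsinh"`
#'   (`asinh(x / cofactor)`).
#' @param cofactor Arcsinh cofactor (default 5, the cytometry convention).
#' @return Transformed values.
#' @export
transform_intensity <- function(values, kind = c("raw", "log2", "arcsinh"),
                                cofactor = 5) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE))
    stop("negative intensities are not allowed", call. = FALSE)
  switch(kind,
         raw = values,
         log2 = log2(values + 1),
         arcsinh = asinh(values / cofactor))
}

#' Feature scaling
#'
#' The standard scaling family applied per marker before clustering or
#' batch evaluation: `standard` (z-score), `minmax` (to `[0, 1]`), `maxabs`
#' (`x / max|x|`), `robust` (`(x - median) / IQR`), `quantile`
#' (rank-to-uniform on `(0, 1)`), `power` (Yeo-Johnson variance-stabilizing
#' transform, maximum-likelihood lambda, then z-scored).
#'
#' @param values Numeric vector (>= 2 distinct values for scale-dependent
#'   kinds).
#' @param kind One of `"standard"`, `"minmax"`, `"maxabs"`, `"robust"`,
#'   `"quantile"`, `"power"`.
#' @return Scaled values.
#' @export
apply_scaler <- function(values, kind = c("standard", "minmax", "maxabs",
                                          "robust", "quantile", "power")) {
  kind <- match.arg(kind)
  x <- values
  switch(kind,
         standard = {
           s <- sd(x)
           if (!is.finite(s) || s == 0) stop("zero variance", call. = FALSE)
           (x - mean(x)) / s
         },
         minmax = {
           r <- range(x)
           if (r[2] == r[1]) stop("zero range", call. = FALSE)
           (x - r[1]) / (r[2] - r[1])
         },
         maxabs = {
           m <- max(abs(x))
           if (m == 0) stop("all-zero values", call. = FALSE)
           x / m
         },
         robust = {
           iqr <- stats::IQR(x)
           if (iqr == 0) stop("zero IQR", call. = FALSE)
           (x - median(x)) / iqr
         },
         quantile = (rank(x, ties.method = "average") - 0.5) / length(x),
         power = {
           if (sd(x) == 0) stop("zero variance", call. = FALSE)
           lam <- car::powerTransform(x, family = "yjPower")$lambda
           y <- car::yjPower(x, lam)
           (y - mean(y)) / sd(y)
         })
}

#' Mutual-exclusivity score of a marker pair
#'
#' Quantifies the L-shaped joint distribution of two markers expressed in
#' disjoint cell populations. Both columns are standardized and the
#' singular values `s1 >= s2` of the resulting n x 2 matrix computed; the
#' score is `s2 / s1`. Perfectly co-expressed markers give 0 (rank-1 data);
#' for a bivariate-normal pair of correlation `r` the score is
#' `sqrt((1 - r) / (1 + r))`; an exclusive L-pair scores above the 0.5
#' selection cut-off.
#'
#' @param x,y Marker intensity columns (>= 100 cells recommended).
#' @return Score in `[0, 1]`.
#' @export
exclusivity_score <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 100)
    warning("fewer than 100 cells; exclusivity score is unstable",
            call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant marker column", call. = FALSE)
  m <- cbind((x - mean(x)) / sd(x), (y - mean(y)) / sd(y))
  d <- svd(m, nu = 0, nv = 0)$d
  unname(d[2] / d[1])
}

#' Select mutually exclusive marker pairs
#'
#' Per-marker partner selection with a primary cut-off and a fallback used
#' when no pair reaches the primary one: within a core 0.5, falling back to
#' 0.2; for global (per-batch) thresholds 0.66, falling back to 0.5.
#' Markers with no partner even at the fallback are flagged unnormalizable.
#'
#' @param table Cell table.
#' @param markers Marker columns to consider; default [marker_columns()].
#' @param scope `"core"` or `"global"` (sets the default cut-offs).
#' @param primary_cutoff,fallback_cutoff Override the scope defaults.
#' @return Data frame `marker, partner, score, cutoff` (one row per selected
#'   partner); markers with no partner are in `attr(, "unnormalizable")`.
#' @export
select_exclusive_pairs <- function(table, markers = NULL,
                                   scope = c("core", "global"),
                                   primary_cutoff = NULL,
                                   fallback_cutoff = NULL) {
  scope <- match.arg(scope)
  if (is.null(primary_cutoff))
    primary_cutoff <- if (scope == "core") 0.5 else 0.66
  if (is.null(fallback_cutoff))
    fallback_cutoff <- if (scope == "core") 0.2 else 0.5
  if (is.null(markers)) markers <- marker_columns(table)
  if (length(markers) < 2) stop("need at least 2 markers", call. = FALSE)
  nm <- length(markers)
  sc <- matrix(NA_real_, nm, nm, dimnames = list(markers, markers))
  for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
    s <- exclusivity_score(table[[markers[i]]], table[[markers[j]]])
    sc[i, j] <- s; sc[j, i] <- s
  }
  rows <- list(); unnorm <- character(0)
  for (m in markers) {
    others <- setdiff(markers, m)
    s <- setNames(sc[m, others], others)
    hit <- names(s)[!is.na(s) & s > primary_cutoff]
    cutoff <- "primary"
    if (!length(hit)) {
      hit <- names(s)[!is.na(s) & s > fallback_cutoff]
      cutoff <- "fallback"
    }
    if (!length(hit)) { unnorm <- c(unnorm, m); next }
    rows[[m]] <- data.frame(marker = m, partner = hit,
                            score = unname(s[hit]), cutoff = cutoff,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), partner = character(0),
               score = numeric(0), cutoff = character(0))
  rownames(out) <- NULL
  attr(out, "unnormalizable") <- unnorm
  attr(out, "scope") <- scope
  out
}

#' RESTORE background threshold from exclusive partners
#'
#' Cells strongly positive for an exclusive partner are by construction
#' negative for the marker, so the upper quantile of the marker's intensity
#' among those cells estimates the marker's background ceiling. One
#' candidate threshold is computed per partner (the `threshold_quantile`
#' quantile of the marker within the partner's top-`(1 - partner_quantile)`
#' cells), and the median candidate is the threshold.
#'
#' @param table Cell table.
#' @param marker Marker to threshold.
#' @param partners Character vector of partner markers, or the rows of
#'   [select_exclusive_pairs()] for this marker.
#' @param partner_quantile Partner-positivity cut (default 0.75: top
#'   quartile of partner intensity).
#' @param threshold_quantile Quantile of marker intensity within the
#'   partner-positive population (default 0.995).
#' @param min_cells Minimum partner-positive cells per candidate
#'   (default 20); smaller subpopulations are skipped with a warning.
#' @return A [threshold_record()] with provenance `"restore"`; candidates
#'   are attached as attribute `"candidates"`.
#' @export
restore_threshold <- function(table, marker, partners,
                              partner_quantile = 0.75,
                              threshold_quantile = 0.995, min_cells = 20L) {
  if (is.data.frame(partners)) partners <- partners$partner[partners$marker == marker]
  if (!length(partners)) stop("no partners supplied", call. = FALSE)
  mv <- table[[marker]]
  cands <- numeric(0)
  for (p in partners) {
    pv <- table[[p]]
    cut <- quantile(pv, partner_quantile, names = FALSE, na.rm = TRUE)
    pos <- which(pv >= cut & is.finite(mv))
    if (length(pos) < min_cells) {
      warning(sprintf("partner %s: only %d partner-positive cells (< %d); candidate skipped",
                      p, length(pos), min_cells), call. = FALSE)
      next
    }
    cands[p] <- quantile(mv[pos], threshold_quantile, names = FALSE)
  }
  if (!length(cands))
    stop("all partner candidates skipped; cannot derive a RESTORE threshold",
         call. = FALSE)
  rec <- threshold_record(marker, median(cands), "restore", "cell_mean")
  attr(rec, "candidates") <- cands
  rec
}

#' RESTORE-scale normalization
#'
#' Cells at or below the threshold are assigned a random value between 0
#' and 0.02 (uniform on `(1e-6, 0.02)`, seeded); cells above the threshold
#' are mapped affinely from `(threshold, max]` onto `(0.02, 1]`, so the
#' most intense cell maps to exactly 1 and order above the threshold is
#' preserved.
#'
#' @param values Marker intensities.
#' @param t [threshold_record()] or numeric threshold.
#' @param seed Required seed for the below-threshold random values.
#' @return Normalized values in `(0, 1]`.
#' @export
restore_scale <- function(values, t, seed) {
  if (missing(seed) || is.null(seed))
    stop("restore_scale requires a seed for reproducibility", call. = FALSE)
  tv <- .threshold_value(t)
  out <- numeric(length(values))
  above <- values > tv
  below <- !above
  if (any(below))
    out[below] <- with_local_seed(seed, runif(sum(below), 1e-6, 0.02))
  if (any(above)) {
    mx <- max(values[above])
    out[above] <- if (mx > tv) 0.02 + (values[above] - tv) / (mx - tv) * 0.98
                  else 1
  }
  out
}

#' Reverse-compartment background threshold
#'
#' The third quartile of the marker's intensity in the subcellular
#' compartment opposite its expected localization (cytoplasmic signal for a
#' nuclear marker, and vice versa) estimates its background level.
#'
#' @param table Cell table with `mean_{marker}_{compartment}` columns.
#' @param marker Marker name.
#' @param expected_compartment `"nucleus"` or `"cytoplasm"` (the marker's
#'   biologically-relevant compartment).
#' @return A [threshold_record()] with provenance `"reverse_quantile"`.
#' @export
reverse_compartment_threshold <- function(table, marker,
                                          expected_compartment = c("nucleus",
                                                                   "cytoplasm")) {
  expected_compartment <- match.arg(expected_compartment)
  reverse <- if (expected_compartment == "nucleus") "cytoplasm" else "nucleus"
  col <- sprintf("mean_%s_%s", marker, reverse)
  if (!col %in% names(table))
    stop("missing compartment column ", col, call. = FALSE)
  v <- table[[col]]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values in the reverse compartment",
                       call. = FALSE)
  threshold_record(marker, quantile(v, 0.75, names = FALSE),
                   "reverse_quantile", "cell_mean")
}

.as_feature_matrix <- function(x, features = NULL) {
  if (is.matrix(x)) return(list(mat = x, features = colnames(x), table = NULL))
  if (is.null(features)) features <- marker_columns(x)
  list(mat = as.matrix(x[, features, drop = FALSE]), features = features,
       table = x)
}

#' Select training cells for batch-model fitting
#'
#' The three parameterization modes for control-tissue training of the
#' batch adjustment: `"same"` uses a single control core, `"sampled"` pools
#' cells from several designated control cores, `"all"` uses every cell.
#'
#' @param table Cell table with `core_id`.
#' @param mode `"all"`, `"same"` or `"sampled"`.
#' @param control_cores Core ids used by `"same"` (first one) and
#'   `"sampled"` (all of them).
#' @return Logical vector marking training cells.
#' @export
training_cells <- function(table, mode = c("all", "same", "sampled"),
                           control_cores = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         all = rep(TRUE, nrow(table)),
         same = {
           if (is.null(control_cores)) stop("control_cores required",
                                            call. = FALSE)
           table$core_id == control_cores[1]
         },
         sampled = {
           if (is.null(control_cores)) stop("control_cores required",
                                            call. = FALSE)
           table$core_id %in% control_cores
         })
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Per-batch, per-feature location shifts (gamma) and scale factors (delta)
#' are estimated on standardized data and shrunk toward common parametric
#' priors (normal for gamma, inverse-gamma for delta; moment-matched,
#' iterated to convergence), then removed. The model can be fitted on a
#' training subset (control cores present in every batch, see
#' [training_cells()]) and applied batch-wise to all cells. With a single
#' batch the input is returned unchanged.
#'
#' @param x Cell table or numeric matrix (cells x features).
#' @param batch Batch label per cell.
#' @param features Feature columns when `x` is a table; default
#'   [marker_columns()].
#' @param training Logical/integer subset of cells to fit on; default all.
#' @param eb Empirical-Bayes shrinkage; `FALSE` uses the raw per-batch
#'   estimates (the no-shrinkage limit that exactly equalizes training
#'   means and variances).
#' @param mean_only Adjust locations only, leaving scales untouched.
#' @return `x` with the feature columns adjusted; the fitted model (per
#'   batch gamma/delta) is attached as attribute `"batch_model"`.
#' @export
combat_adjust <- function(x, batch, features = NULL, training = NULL,
                          eb = TRUE, mean_only = FALSE) {
  fx <- .as_feature_matrix(x, features)
  dat <- t(fx$mat)                     # features x cells
  batch <- as.character(batch)
  if (length(batch) != ncol(dat))
    stop("batch must have one label per cell", call. = FALSE)
  batches <- unique(batch)
  if (length(batches) < 2) return(x)
  train <- if (is.null(training)) rep(TRUE, ncol(dat)) else {
    tr <- rep(FALSE, ncol(dat)); tr[training] <- TRUE
    if (is.logical(training)) tr <- training
    tr
  }
  for (b in batches)
    if (!any(train & batch == b))
      stop("batch ", b, " has no training cells", call. = FALSE)
  dt <- dat[, train, drop = FALSE]
  bt <- batch[train]
  n_b <- vapply(batches, function(b) sum(bt == b), 0)
  # pooled grand mean and within-batch-pooled variance on training cells
  b_hat <- vapply(batches, function(b) rowMeans(dt[, bt == b, drop = FALSE]), dat[, 1])
  b_hat <- matrix(b_hat, nrow = nrow(dt))
  grand <- as.vector(b_hat %*% (n_b / sum(n_b)))
  resid <- dt - b_hat[, match(bt, batches), drop = FALSE]
  var_pooled <- rowSums(resid^2) / sum(n_b)
  if (any(var_pooled <= 0))
    stop("zero-variance feature in training cells: ",
         paste(rownames(dat)[var_pooled <= 0], collapse = ", "), call. = FALSE)
  sdp <- sqrt(var_pooled)
  z <- (dt - grand) / sdp
  gamma_hat <- vapply(batches, function(b) rowMeans(z[, bt == b, drop = FALSE]), z[, 1])
  gamma_hat <- matrix(gamma_hat, nrow = nrow(z))
  delta_hat <- vapply(batches, function(b) {
    zb <- z[, bt == b, drop = FALSE]
    rowSums((zb - rowMeans(zb))^2) / max(ncol(zb) - 1, 1)
  }, z[, 1])
  delta_hat <- matrix(delta_hat, nrow = nrow(z))
  if (eb && nrow(z) >= 2) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (j in seq_along(batches)) {
      g <- gamma_hat[, j]; d <- delta_hat[, j]; n <- n_b[j]
      g_bar <- mean(g); t2 <- var(g)
      m <- mean(d); s2 <- var(d)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      zb <- z[, bt == batches[j], drop = FALSE]
      g_new <- g; d_new <- d
      for (it in 1:100) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2 * n * g + d_old * g_bar) / (t2 * n + d_old)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
        if (max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                abs(d_new - d_old) / pmax(abs(d_old), 1e-12)) < 1e-4) break
      }
      gamma_star[, j] <- g_new; delta_star[, j] <- d_new
    }
  } else {
    gamma_star <- gamma_hat; delta_star <- delta_hat
  }
  if (mean_only) delta_star[] <- 1
  # apply to ALL cells batch-wise
  z_all <- (dat - grand) / sdp
  for (j in seq_along(batches)) {
    sel <- batch == batches[j]
    z_all[, sel] <- (z_all[, sel, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta_star[, j])
  }
  adj <- z_all * sdp + grand
  model <- list(batches = batches, gamma = gamma_star, delta = delta_star,
                grand_mean = grand, var_pooled = var_pooled,
                n_training = sum(train))
  if (is.matrix(x)) {
    out <- t(adj)
    dimnames(out) <- dimnames(x)
  } else {
    out <- x
    out[, fx$features] <- t(adj)
  }
  attr(out, "batch_model") <- model
  out
}

#' Mean-only batch correction (regress out)
#'
#' Per feature and batch, subtracts the batch mean and restores the grand
#' mean; variances are untouched.
#'
#' @param x Cell table or numeric matrix (cells x features).
#' @param batch Batch label per cell.
#' @param features Feature columns when `x` is a table.
#' @return Adjusted `x`.
#' @export
regress_out_batch <- function(x, batch, features = NULL) {
  fx <- .as_feature_matrix(x, features)
  m <- fx$mat
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) return(x)
  grand <- colMeans(m)
  for (b in unique(batch)) {
    sel <- batch == b
    m[sel, ] <- sweep(m[sel, , drop = FALSE], 2,
                      colMeans(m[sel, , drop = FALSE]) - grand)
  }
  if (is.matrix(x)) return(m)
  x[, fx$features] <- m
  x
}

#' Serialize threshold records to CSV
#'
#' @param records List of [threshold_record()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_thresholds <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(marker = r$marker, value = r$value, provenance = r$provenance,
               scope = r$scope, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
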