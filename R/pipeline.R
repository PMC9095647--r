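#' Validate a pipeline configuration
#'
#' A configuration is a named list (usually read from YAML, see
#' [read_pipeline_config()]) with: `seed` (required), `output_dir`
#' (required), exactly one of `simulate` (arguments for
#' [sim_image_config()]) or `input_dir` (directory of TIFFs following the
#' filename convention), optional per-stage parameter lists (`register`,
#' `afsub`, `segment`, `extract`, `qc`, `normalize`, `eval`) and stage
#' toggles (`stages`, default: all upstream stages on, `eval` on only when
#' the table has >= 2 batches). Every stochastic stage must carry a seed:
#' the global `seed` covers simulation and evaluation, and
#' `normalize$method = "restore"` additionally requires `normalize$seed`
#' for the below-threshold random values.
#'
#' @param config Named list.
#' @return The validated config (with defaults filled in); errors describe
#'   the offending field.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$seed))
    stop("config validation: 'seed' is required", call. = FALSE)
  if (is.null(config$output_dir))
    stop("config validation: 'output_dir' is required", call. = FALSE)
  if (is.null(config$simulate) && is.null(config$input_dir))
    stop("config validation: one of 'simulate' or 'input_dir' is required",
         call. = FALSE)
  defaults <- list(register = list(), afsub = list(algorithm = "baseline"),
                  segment = list(expand_px = 5), extract = list(),
                  qc = list(), normalize = list(method = "none"),
                  eval = list())
  for (nm in names(defaults))
    config[[nm]] <- utils::modifyList(defaults[[nm]],
                                      if (is.null(config[[nm]])) list()
                                      else config[[nm]])
  if (identical(config$normalize$method, "restore") &&
      is.null(config$normalize$seed))
    stop("config validation: normalize$seed is required for the restore ",
         "method (seeded below-threshold values)", call. = FALSE)
  if (is.null(config$stages))
    config$stages <- c("register", "afsub", "segment", "extract", "qc",
                       "normalize")
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

.manifest_add <- function(manifest, stage, path, params = list()) {
  manifest$artifacts[[length(manifest$artifacts) + 1L]] <-
    list(stage = stage, path = basename(path),
         md5 = unname(tools::md5sum(path)), params = params)
  manifest
}

#' Run the processing pipeline end to end
#'
#' Executes the stages in order (register, AF-subtract, segment, extract,
#' QC, normalize, optional batch evaluation) on a simulated scene or a
#' directory of TIFFs, writing every artifact (registered images, masks,
#' transform table, cell table, QC tables, normalized table) plus a JSON
#' run manifest listing parameters, seeds and MD5 checksums. Rerunning an
#' identical configuration reproduces identical checksums. A stage failure
#' aborts with the stage name; artifacts already written are retained.
#'
#' @param config Config list or YAML path (see
#'   [validate_pipeline_config()]).
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cyclicproc")),
                   seed = config$seed, artifacts = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  blanks <- NULL
  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", {
      cfg <- do.call(sim_image_config,
                     c(config$simulate, list(seed = config$seed)))
      simulate_image_experiment(cfg)
    })
    stack <- sim$stack
    blanks <- sim$blanks
  } else {
    stack <- run_stage("input", {
      files <- list.files(config$input_dir, pattern = "\\.tiff?$",
                          full.names = TRUE)
      assemble_stack(files)
    })
  }
  if ("register" %in% config$stages) {
    stack <- run_stage("register",
      do.call(register_stack, c(list(stack = stack), config$register)))
    tf <- file.path(out_dir, "transforms.csv")
    write_transforms(stack$transforms, tf)
    manifest <- .manifest_add(manifest, "register", tf, config$register)
  }
  if ("afsub" %in% config$stages && !is.null(blanks)) {
    stack <- run_stage("afsub",
      correct_stack(stack, blanks,
                    algorithm = config$afsub$algorithm,
                    channels = intersect(af_corrected_channels(),
                                         stack$channels)))
  }
  masks <- NULL
  if ("segment" %in% config$stages) {
    masks <- run_stage("segment", {
      proj <- project_dapi(stack)
      nuc <- do.call(segment_nuclei,
                     c(list(dapi_proj = proj),
                       config$segment[setdiff(names(config$segment),
                                              "expand_px")]))
      cell <- expand_labels(nuc, config$segment$expand_px)
      list(nucleus = nuc, cell = cell,
           cytoplasm = derive_cytoplasm(cell, nuc))
    })
    for (cp in names(masks)) {
      mp <- file.path(out_dir, sprintf("mask_%s.tif", cp))
      write_image(masks[[cp]]$labels, mp)
      manifest <- .manifest_add(manifest, "segment", mp, config$segment)
    }
  }
  tab <- NULL
  if ("extract" %in% config$stages && !is.null(masks)) {
    tab <- run_stage("extract", suppressWarnings(
      build_cell_table(stack, masks,
                       marker_compartments = unlist(config$extract$marker_compartments))))
    tp <- file.path(out_dir, "cell_table.csv")
    write_cell_table(tab, tp)
    manifest <- .manifest_add(manifest, "extract", tp, config$extract)
  }
  if ("qc" %in% config$stages && !is.null(tab)) {
    qc <- run_stage("qc", {
      mks <- marker_columns(tab)
      do.call(rbind, lapply(mks, function(m) {
        q <- suppressWarnings(sbr_from_quantiles(tab[[m]]))
        data.frame(marker = m, q_low = q$dynamic_range[1],
                   q_high = q$dynamic_range[2], sbr_est = q$sbr_est)
      }))
    })
    qp <- file.path(out_dir, "qc_quantile_sbr.csv")
    utils::write.csv(qc, qp, row.names = FALSE)
    manifest <- .manifest_add(manifest, "qc", qp, config$qc)
  }
  if ("normalize" %in% config$stages && !is.null(tab) &&
      !identical(config$normalize$method, "none")) {
    tab <- run_stage("normalize", {
      mks <- marker_columns(tab)
      if (config$normalize$method == "restore") {
        pairs <- select_exclusive_pairs(tab, mks, scope = "global")
        for (m in setdiff(mks, attr(pairs, "unnormalizable"))) {
          rec <- restore_threshold(tab, m, pairs)
          tab[[m]] <- restore_scale(tab[[m]], rec,
                                    seed = config$normalize$seed)
        }
        tab
      } else if (config$normalize$method == "scaler") {
        for (m in mks) tab[[m]] <- apply_scaler(tab[[m]],
                                                config$normalize$kind %||% "minmax")
        tab
      } else stop("unknown normalize method ", config$normalize$method)
    })
    np <- file.path(out_dir, "cell_table_normalized.csv")
    write_cell_table(tab, np)
    manifest <- .manifest_add(manifest, "normalize", np, config$normalize)
  }
  if ("eval" %in% config$stages && !is.null(tab) &&
      length(unique(tab$batch_id)) >= 2) {
    ev <- run_stage("eval", {
      mks <- marker_columns(tab)
      g <- build_knn(tab, k = config$eval$k %||% kbet_default_k(tab$batch_id),
                     features = mks)
      kbet_rejection_rate(g, tab$batch_id, seed = config$seed)
    })
    ep <- file.path(out_dir, "kbet.csv")
    utils::write.csv(data.frame(rejection_rate = ev$rejection_rate,
                                k = ev$k, alpha = ev$alpha,
                                n_subsets = ev$n_subsets, seed = ev$seed),
                     ep, row.names = FALSE)
    manifest <- .manifest_add(manifest, "eval", ep, config$eval)
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
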