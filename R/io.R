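#' Read a trace table (delimited text)
#'
#' Expects comma-separated text with a header whose first column is `t`
#' (seconds, strictly increasing); every remaining column is one numeric
#' trace. One data column yields a `data.frame(t, value)` of class
#' `trace`; several yield a `trace_ensemble`.
#'
#' @param path File path.
#' @return A `trace` data.frame or a `trace_ensemble`.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr))
    stop("parse error (line 1): duplicate column headers: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  if (length(hdr) < 2 || trimws(hdr[1]) != "t")
    stop("parse error (line 1): first column must be 't'")
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  num <- suppressWarnings(
    as.data.frame(lapply(raw, as.numeric), check.names = FALSE))
  bad <- which(rowSums(is.na(num) & !is.na(raw) & raw != "") > 0)
  if (length(bad))
    stop("parse error (line ", bad[1] + 1L, "): non-numeric cell")
  if (any(is.na(num)))
    stop("parse error: missing values in table")
  tt <- num[[1]]
  if (any(diff(tt) <= 0)) {
    i <- which(diff(tt) <= 0)[1]
    stop("parse error (line ", i + 2L, "): time must be strictly ",
         "increasing")
  }
  if (ncol(num) == 2L) {
    out <- data.frame(t = tt, value = num[[2]])
    class(out) <- c("trace", class(out))
    return(out)
  }
  structure(list(t = tt, traces = t(as.matrix(num[, -1, drop = FALSE])),
                 labels = data.frame(
                   condition = rep(NA_character_, ncol(num) - 1L),
                   compartment = rep(NA_character_, ncol(num) - 1L),
                   stringsAsFactors = FALSE),
                 provenance = list(file = path)),
            class = "trace_ensemble")
}

#' Write a trace, ensemble or aggregate to delimited text
#'
#' Traces and aggregates are written as plain CSV (`t` first); ensembles
#' are written wide (`t`, `roi_1`, ...) together with a JSON sidecar
#' (`<path>.json`) carrying labels and provenance.
#'
#' @param x A `trace` data.frame, `model_trajectory`, `trace_ensemble` or
#'   `aggregate_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  if (inherits(x, "trace_ensemble")) {
    df <- data.frame(t = x$t, t(x$traces), check.names = FALSE)
    names(df) <- c("t", paste0("roi_", seq_len(nrow(x$traces))))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    side <- list(labels = x$labels,
                 provenance = serialize_provenance(x$provenance))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else if (inherits(x, c("aggregate_trace", "model_trajectory"))) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                     quote = FALSE)
  } else if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported object for write_trace_table")
  invisible(path)
}

serialize_provenance <- function(p) {
  lapply(p, function(el) {
    if (inherits(el, c("noise_model", "larg_params",
                       "rho_circuit_params"))) unclass(el)
    else if (is.list(el)) serialize_provenance(el)
    else el
  })
}

param_units <- function(nm) {
  u <- c(k_on = "1/s", k_off = "1/s", v_on_gap = "units/s",
         km_gap = "units", k_off_gap = "1/s", v_on_rho = "units/s",
         km_on_rho = "units", v_off_rho = "1/s", km_off_rho = "units")
  unname(u[nm])
}

#' Serialize a fit result to JSON
#'
#' Writes estimates (with unit strings), loss, convergence and at-bound
#' flags, the bounds used and the multistart seed.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  est <- lapply(seq_along(fit$estimates), function(i)
    list(value = unname(fit$estimates[i]),
         unit = param_units(names(fit$estimates)[i])))
  names(est) <- names(fit$estimates)
  out <- list(variant = fit$variant, estimates = est, loss = fit$loss,
              n_iter = fit$n_iter, converged = fit$converged,
              at_bound = as.list(fit$at_bound_flags),
              bounds = list(lower = as.list(fit$bounds_used$lower),
                            upper = as.list(fit$bounds_used$upper)),
              seed = fit$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML with blocks `protocol`, `condition`, `noise`,
#' `ensemble`, `fit` and a top-level `seed`; all seeds must be explicit
#' and every fit must request at least one start.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate (and default-fill) a pipeline configuration
#'
#' @param cfg A named list, e.g. from [read_run_config()].
#' @return The validated `run_config`.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(
    protocol = list(), condition = "membrane_wt",
    noise = list(additive_sd = 0.05, roi_scale_sd = 0.3),
    ensemble = list(n_roi = 2000, n_boot = 1000, ci_level = 0.99),
    fit = list(n_starts = 20, variants = c("WT", "KO")),
    metrics = list(enabled = TRUE),
    seed = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("config validation: an explicit integer seed is required")
  if (is.null(cfg$fit$n_starts) || cfg$fit$n_starts < 1)
    stop("config validation: fit$n_starts must be >= 1")
  if (!cfg$condition %in% c("membrane_wt", "membrane_ko", "fa_wt",
                            "fa_ko"))
    stop("config validation: unknown condition ", cfg$condition)
  if (cfg$ensemble$n_roi < 1)
    stop("config validation: ensemble$n_roi must be >= 1")
  cfg$protocol <- do.call(stimulus_protocol, cfg$protocol)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulation / aggregation / fitting pipeline
#'
#' Executes simulate -> ROI ensemble -> aggregate -> fit (both requested
#' variants) -> kinetics metrics, writing every product plus a manifest
#' (package version, seeds, config and output checksums) under
#' `out_dir`. All randomness flows from the config seed, so a rerun with
#' an identical config is bit-identical for every deterministic stage.
#'
#' @param config A `run_config` (see [read_run_config()]) or a named list
#'   accepted by [validate_run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted results and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error"))
      stop("pipeline stage '", name, "' failed: ",
           attr(res, "condition")$message, call. = FALSE)
    res
  }
  paths <- list()

  truth <- ref_circuit_params(cfg$condition)
  larg_true <- ref_larg_params()
  traj <- stage("simulate",
                simulate_circuit(larg_true, truth, cfg$protocol))
  paths$trajectory <- file.path(out_dir, "trajectory.csv")
  write_trace_table(traj, paths$trajectory)

  nm <- noise_model(cfg$noise$additive_sd, cfg$noise$roi_scale_sd,
                    seed = cfg$seed)
  ens <- stage("ensemble",
               generate_roi_ensemble(traj, nm, n_roi = cfg$ensemble$n_roi,
                                     condition = toupper(sub(".*_", "",
                                                             cfg$condition)),
                                     seed = cfg$seed))
  agg <- stage("aggregate",
               aggregate_ensemble(ens, cfg$protocol$baseline_window,
                                  ci_level = cfg$ensemble$ci_level,
                                  n_boot = cfg$ensemble$n_boot,
                                  seed = cfg$seed + 1L))
  paths$aggregate <- file.path(out_dir, "aggregate.csv")
  write_trace_table(agg, paths$aggregate)

  larg_traj <- simulate_larg(larg_true, cfg$protocol)
  larg_fit <- stage("fit_larg", fit_larg_kinetics(
    data.frame(t = larg_traj$t, value = larg_traj$larg), cfg$protocol,
    seed = cfg$seed + 2L))
  paths$larg_fit <- file.path(out_dir, "fit_larg.json")
  write_fit_result(larg_fit, paths$larg_fit)

  fits <- list()
  for (v in cfg$fit$variants) {
    f <- stage(paste0("fit_", v),
               fit_rho_circuit(agg, larg_fit, v, cfg$protocol,
                               n_starts = cfg$fit$n_starts,
                               seed = cfg$seed + 3L))
    fits[[v]] <- f
    paths[[paste0("fit_", v)]] <- file.path(out_dir,
                                            paste0("fit_", v, ".json"))
    write_fit_result(f, paths[[paste0("fit_", v)]])
  }

  metrics <- NULL
  if (isTRUE(cfg$metrics$enabled)) {
    metrics <- stage("metrics",
                     observed_rates(data.frame(t = agg$t,
                                               value = agg$center),
                                    cfg$protocol))
    paths$metrics <- file.path(out_dir, "metrics.csv")
    utils::write.csv(data.frame(condition = cfg$condition,
                                k_on_obs = metrics$k_on_obs,
                                k_off_obs = metrics$k_off_obs,
                                peak_amplitude = metrics$peak_amplitude,
                                t_peak = metrics$t_peak),
                     paths$metrics, row.names = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_out <- cfg
  cfg_out$protocol <- unclass(cfg$protocol)
  jsonlite::write_json(unclass(cfg_out), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package = "rhoflux",
    version = as.character(utils::packageVersion("rhoflux")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(config = cfg, fits = fits, aggregate = agg,
                 metrics = metrics, paths = paths))
}

#' Write / read a grayscale image stack as multipage 16-bit TIFF
#'
#' Intensities are stored as `value / scale` in the unit range; use the
#' same `scale` when reading back.
#'
#' @param stack Numeric array (rows x cols x frames) or matrix.
#' @param path TIFF file path.
#' @param scale Full-scale intensity mapped to the 16-bit maximum.
#' @return `path` (write) or the numeric array (read).
#' @export
write_image_stack <- function(stack, path, scale = 65535) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  img <- EBImage::Image(pmin(pmax(stack / scale, 0), 1))
  EBImage::writeImage(img, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, scale = 65535) {
  img <- EBImage::readImage(path)
  a <- as.array(img) * scale
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  a
}

#' Write / read an ROI set as delimited text
#'
#' Columns: `row`, `col` (0-based pixel coordinates), `radius`, `class`,
#' `pair_id`.
#'
#' @param rois A `roi_set` data.frame.
#' @param path CSV file path.
#' @return `path` (write) or the `roi_set` (read).
#' @export
write_roi_set <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "radius", "class", "pair_id")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("roi_set", class(df))
  df
}

#' Binary stimulation mask for one ROI class
#'
#' @param rois A `roi_set`.
#' @param size Image side length (px).
#' @param class ROI class to render (`"FA"` or `"non-FA"`).
#' @return Logical matrix with `TRUE` inside the selected ROI disks.
#' @export
roi_stimulation_mask <- function(rois, size, class = "FA") {
  g <- pixel_grids(size)
  m <- matrix(FALSE, size, size)
  sel <- rois[rois$class == class, , drop = FALSE]
  for (i in seq_len(nrow(sel)))
    m <- m | ((g$row - sel$row[i])^2 + (g$col - sel$col[i])^2 <=
                sel$radius[i]^2)
  m
}
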