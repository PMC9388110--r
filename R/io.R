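#' Read a long-format trace table
#'
#' Reads `cell_id,time_h,channel,value` CSV and validates it: duplicate
#' `(cell_id, channel, time_h)` keys are an error (reported with row
#' numbers), every `(cell_id, channel)` series must sit on a uniform time
#' grid, and all values must be finite. A header-only file yields an empty
#' table.
#'
#' @param path CSV file path.
#' @return A `data.table` with the four canonical columns.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- data.table::fread(path, colClasses = list(
    character = c("cell_id", "channel"), numeric = c("time_h", "value")))
  need <- c("cell_id", "time_h", "channel", "value")
  if (!all(need %in% names(tab)))
    stop("trace table needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (nrow(tab) == 0L) return(tab[, need, with = FALSE])
  if (anyNA(tab$value) || any(!is.finite(tab$value)))
    stop("non-finite trace values in ", path, call. = FALSE)
  key <- paste(tab$cell_id, tab$channel, tab$time_h)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop(sprintf("duplicated (cell_id, channel, time_h) rows at lines %s",
                 paste(head(rows + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  grp <- split(tab$time_h, paste(tab$cell_id, tab$channel, sep = "/"))
  for (g in names(grp)) {
    ts <- sort(grp[[g]])
    if (length(ts) >= 3L) {
      dts <- diff(ts)
      if (diff(range(dts)) > 1e-6 * mean(dts))
        stop("non-uniform time grid for ", g, call. = FALSE)
    }
  }
  tab[, need, with = FALSE]
}

#' Write a long-format trace table
#'
#' Writes the canonical `cell_id,time_h,channel,value` CSV (times rounded
#' to 4 decimal places in hours).
#'
#' @param table Trace table (`data.table`/data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(table, path) {
  tab <- data.table::as.data.table(table)
  tab$time_h <- round(tab$time_h, 4)
  data.table::fwrite(tab[, c("cell_id", "time_h", "channel", "value"),
                         with = FALSE], path)
  invisible(path)
}

#' Write generator ground truth as JSON
#'
#' @param pop A [generate_population()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(pop, path) {
  jsonlite::write_json(pop$ground_truth, path, auto_unbox = TRUE,
                       digits = 10, null = "null", na = "null")
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param generator [generator_config()] for the analyzed (stimulated)
#'   population.
#' @param control [generator_config()] for the unstimulated control
#'   population used to calibrate the ground-truth cutoff; defaults to the
#'   generator config with `condition = "control"`, no differentiating
#'   cells, and a shifted seed.
#' @param span,half_window Smoothing span and slope half-window (hours).
#' @param n_thresholds ROC grid size.
#' @param n_bins Phase histogram bins for the Fourier fit.
#' @param k_max Maximum mixture components.
#' @param min_period,min_prominence,r2_min Anchor-detection settings.
#' @param max_control_fraction Control-contamination bound for the
#'   ground-truth cutoff.
#' @param out_dir Output directory (`NULL` for in-memory results only).
#' @return A list of class `cg_run_config`.
#' @export
run_config <- function(generator, control = NULL, span = 6, half_window = 4,
                       n_thresholds = 200, n_bins = 24, k_max = 5,
                       min_period = 12, min_prominence = 0.1, r2_min = 0.5,
                       max_control_fraction = 0.03, out_dir = NULL) {
  stopifnot(inherits(generator, "cg_generator_config"))
  if (is.null(control)) {
    control <- generator
    control$condition <- "control"
    control$frac_differentiating <- 0
    control$seed <- generator$seed + 1000L
  }
  structure(list(generator = generator, control = control, span = span,
                 half_window = half_window, n_thresholds = n_thresholds,
                 n_bins = n_bins, k_max = k_max, min_period = min_period,
                 min_prominence = min_prominence, r2_min = r2_min,
                 max_control_fraction = max_control_fraction,
                 out_dir = out_dir),
            class = "cg_run_config")
}

#' Run the full commitment/phase analysis pipeline
#'
#' Generates (or accepts) a stimulated population and a control population,
#' calibrates the ground-truth fate cutoff on the control terminals, scans
#' ROC thresholds, assigns first-crossing commitment times, detects
#' reporter anchors, projects commitments into phase-time space, and fits
#' the commitment-time Gaussian mixture and commitment-phase Fourier
#' models. Deterministic for a fixed configuration. When `out_dir` is set,
#' writes `commitment.json`, `phase_time.csv`, `fits.json`, and
#' `manifest.json`.
#'
#' @param config A [run_config()].
#' @param population,control_population Optional pre-generated
#'   [generate_population()] objects (generated from the config when
#'   omitted).
#' @return A list of class `cg_result_bundle` with elements `cutoff`,
#'   `labels`, `roc`, `records`, `phase_points`, `exclusions`, `gmm`,
#'   `fourier`, `anchors`, `config`.
#' @export
run_pipeline <- function(config, population = NULL,
                         control_population = NULL) {
  stopifnot(inherits(config, "cg_run_config"))
  if (config$generator$n_cells <= 0L)
    stop("generator n_cells must be positive", call. = FALSE)
  if (is.null(population)) population <- generate_population(config$generator)
  if (is.null(control_population))
    control_population <- generate_population(config$control)

  smooth_all <- function(trs) lapply(trs, smooth_moving_average,
                                     span = config$span)
  pparg <- smooth_all(population_traces(population, "pparg"))
  pparg_ctrl <- smooth_all(population_traces(control_population, "pparg"))
  term <- vapply(pparg, function(tr) tr$value[length(tr$value)], numeric(1))
  term_ctrl <- vapply(pparg_ctrl, function(tr) tr$value[length(tr$value)],
                      numeric(1))
  cutoff <- ground_truth_cutoff(term_ctrl, config$max_control_fraction)
  labels <- fate_labels(term, cutoff)
  roc <- roc_threshold_scan(pparg, labels, config$n_thresholds)
  records <- assign_commitment_times(pparg, roc$optimal_threshold)

  reporter <- smooth_all(population_traces(population, "reporter"))
  anchors <- lapply(reporter, detect_anchors, min_period = config$min_period,
                    min_prominence = config$min_prominence,
                    r2_min = config$r2_min)
  usable <- vapply(anchors, function(a) length(a$anchor_times) >= 2L,
                   logical(1))
  maps <- lapply(anchors[usable], build_phase_map)

  n_no_anchor <- 0L; n_outside <- 0L
  pts <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$cell_id[i]
    if (is.null(maps[[id]])) { n_no_anchor <- n_no_anchor + 1L; next }
    row <- commitment_phase(maps[[id]], records$commit_time[i], cell_id = id)
    if (is.null(row)) { n_outside <- n_outside + 1L; next }
    pts[[length(pts) + 1L]] <- row
  }
  phase_points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(cell_id = character(0), commit_time = numeric(0),
               commit_phase = numeric(0), time_since_last_peak = numeric(0))

  gmm <- if (nrow(records) >= 2L)
    fit_commitment_time_gmm(records$commit_time, config$k_max) else NULL
  fourier <- if (nrow(phase_points) >= 2L)
    suppressWarnings(fit_phase_fourier(phase_points$commit_phase,
                                       config$n_bins)) else NULL

  out <- structure(list(
    cutoff = cutoff, labels = labels, roc = roc, records = records,
    phase_points = phase_points,
    exclusions = c(no_anchors = n_no_anchor, outside_map = n_outside),
    gmm = gmm, fourier = fourier, anchors = anchors, config = config),
    class = "cg_result_bundle")

  if (!is.null(config$out_dir)) write_result_bundle(out, config$out_dir)
  out
}

#' @export
print.cg_result_bundle <- function(x, ...) {
  cat(sprintf(paste0("<cg_result_bundle> %d cells, cutoff %.3g, AUC %.3f, ",
                     "%d commitments (%d with phase; excluded: %d no-anchor,",
                     " %d outside map)\n"),
              nrow(x$labels), x$cutoff, x$roc$auc, nrow(x$records),
              nrow(x$phase_points), x$exclusions[["no_anchors"]],
              x$exclusions[["outside_map"]]))
  invisible(x)
}

# internal: serialize a result bundle + reproducibility manifest
write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(ground_truth_cutoff = res$cutoff,
         optimal_threshold = res$roc$optimal_threshold,
         auc = res$roc$auc,
         corner_distance = res$roc$corner_distance,
         n_committed = nrow(res$records),
         records = res$records),
    file.path(out_dir, "commitment.json"),
    auto_unbox = TRUE, digits = 10)
  pp <- res$phase_points
  names(pp) <- c("cell_id", "commit_time_h", "phase_rad",
                 "time_since_peak_h")
  data.table::fwrite(data.table::as.data.table(pp),
                     file.path(out_dir, "phase_time.csv"))
  fits <- list(exclusions = as.list(res$exclusions))
  if (!is.null(res$gmm))
    fits$gmm <- res$gmm[c("k", "weights", "means", "sds", "bic")]
  if (!is.null(res$fourier))
    fits$fourier <- res$fourier[c("a0", "a1", "b1", "peak_phase", "gof")]
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = 10)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(res$config, cfg_path, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  manifest <- list(
    package = "clockgate",
    version = as.character(utils::packageVersion("clockgate")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    generator_seed = res$config$generator$seed,
    control_seed = res$config$control$seed,
    exclusions = as.list(res$exclusions))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
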