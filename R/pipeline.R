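# End-to-end orchestration: generate -> measure -> classify -> report, with a
# validated, file-round-trippable configuration and per-stage seed substreams.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline: acquisition geometry, the
#' section-sampling interval, the connection-counting thresholds, the
#' overlap-angle limit, the beneath-vacuole footprint margin, the population
#' preset and seed, and output paths. All thresholds must be positive. The
#' configuration round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param seed Global integer seed; per-stage substreams are derived from it.
#' @param preset `"population"` or `"table1_fixture"`.
#' @param n_cells_per_area Cells per flow area.
#' @param sampling_interval Measurement sampling interval in sections.
#' @param height_threshold Projection-height threshold (um).
#' @param area_threshold Contact-area threshold (um^2).
#' @param angle_limit Overlap axis-angle limit (degrees).
#' @param footprint_margin Beneath-vacuole footprint dilation (um).
#' @param beneath_mode `"footprint"` or `"section"`.
#' @param pixel_size,section_thickness Acquisition geometry (um).
#' @param out_dir Report directory (`NULL` for none).
#' @param write_stacks Also write the generated stacks and truth tables.
#' @return A validated list of class `vm_config`.
#' @export
run_config <- function(seed = 1L, preset = "population",
                       n_cells_per_area = 15L, sampling_interval = 40L,
                       height_threshold = 0.3, area_threshold = 0.5,
                       angle_limit = 45, footprint_margin = 0.5,
                       beneath_mode = "footprint", pixel_size = 0.0101,
                       section_thickness = 0.13, out_dir = NULL,
                       write_stacks = FALSE) {
  cfg <- list(seed = as.integer(seed), preset = preset,
              n_cells_per_area = as.integer(n_cells_per_area),
              sampling_interval = as.integer(sampling_interval),
              height_threshold = height_threshold,
              area_threshold = area_threshold, angle_limit = angle_limit,
              footprint_margin = footprint_margin,
              beneath_mode = beneath_mode, pixel_size = pixel_size,
              section_thickness = section_thickness, out_dir = out_dir,
              write_stacks = isTRUE(write_stacks))
  class(cfg) <- "vm_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param config A `vm_config`.
#' @return Invisibly `TRUE`; stops on the first violated constraint.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "vm_config"))
  pos <- c("sampling_interval", "height_threshold", "area_threshold",
           "angle_limit", "footprint_margin", "pixel_size",
           "section_thickness", "n_cells_per_area")
  for (f in pos) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field `", f, "` must be a positive number")
  }
  if (!config$preset %in% c("population", "table1_fixture"))
    stop("config field `preset` must be 'population' or 'table1_fixture'")
  if (!config$beneath_mode %in% c("footprint", "section"))
    stop("config field `beneath_mode` must be 'footprint' or 'section'")
  invisible(TRUE)
}

#' Write / read a configuration as YAML
#'
#' @param config A `vm_config`.
#' @param path YAML file path.
#' @return `path` / the validated `vm_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(run_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic dataset prescribed by the configuration, measures
#' every cell, classifies connections, vacuoles and pores, assembles the
#' flow-area summary and comparison statistics, and (when `out_dir` is set)
#' renders the CSV report. Deterministic for a fixed configuration: the global
#' seed is expanded into independent per-stage substreams so each stage is
#' individually reproducible.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the dataset, the morphometry table, the
#'   connectivity tables, the summary, the vacuole-type distribution, the
#'   statistics, and the report file paths (if written).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message("[vacuomorph] ", ...)
  acq <- acquisition_params(config$pixel_size, config$section_thickness)

  say("stage 1/4: generating dataset (preset ", config$preset,
      ", seed ", config$seed, ")")
  ds <- generate_dataset(n_cells_per_area = config$n_cells_per_area,
                         seed = config$seed, preset = config$preset,
                         rasterize = TRUE, acquisition = acq)
  labels <- ds$truth$cells[, c("cell_id", "flow_area")]

  say("stage 2/4: morphometry on ", length(ds$stacks), " cells")
  morpho <- measure_cells(ds$stacks, cells = labels,
                          interval = config$sampling_interval)

  say("stage 3/4: connectivity classification")
  conn <- classify_cells(ds$stacks, cells = labels,
                         margin = config$footprint_margin,
                         mode = config$beneath_mode,
                         height_threshold = config$height_threshold,
                         area_threshold = config$area_threshold)

  say("stage 4/4: summary tables and statistics")
  smry <- summarize_flow_areas(conn$cells, conn$gvs, conn$bpores)
  gvdist <- gv_type_distribution(conn$gvs)
  stats_list <- list()
  for (m in c("length", "nonnuclear_width", "volume", "ol_mean")) {
    v <- morpho[[m]]
    ok <- is.finite(v)
    if (sum(ok) > 3 && length(unique(morpho$flow_area[ok])) > 1)
      stats_list[[m]] <- compare_by_flow_area(v[ok], morpho$flow_area[ok])
  }
  if (nrow(conn$cells) > 3)
    stats_list$total_connections <-
      compare_by_flow_area(conn$cells$total, conn$cells$flow_area)
  gg <- conn$gvs
  gg <- gg[is.finite(gg$connections_per_volume), , drop = FALSE]
  if (nrow(gg) && length(unique(gg$gv_type)) > 1)
    stats_list$connection_ratio_by_gv_type <-
      compare_ratios_by_gv_type(gg$connections_per_volume, gg$gv_type)

  report_files <- NULL
  if (!is.null(config$out_dir)) {
    results <- list(table1 = as.data.frame(smry), gv_types = gvdist,
                    dimensions = morpho,
                    connections_by_type = conn$cells,
                    gv_connections = conn$gvs,
                    overlap = morpho[, c("cell_id", "flow_area", "ol_mean")],
                    stats = stats_list)
    report_files <- render_report(results, config$out_dir)
    if (config$write_stacks)
      write_dataset(ds, file.path(config$out_dir, "stacks"))
    say("report written to ", config$out_dir)
  }
  invisible(list(dataset = ds, morphometry = morpho, connectivity = conn,
                 summary = smry, gv_types = gvdist, stats = stats_list,
                 report_files = report_files, config = config))
}
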