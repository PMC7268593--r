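# The three-stage batch workflow: convert (raw -> phase/amplitude),
# roi (detection + per-ROI correction), sphere (model fits + statistics).
#
# Every stage writes only into "<input>_dm" next to the input.  Stages are
# cached: a stage is recomputed only when the content hash of its inputs or
# of the configuration sections it depends on changes
# (convert <- [meta, holo]; roi <- [roi, bg]; sphere <- [sphere]).

.results_dir <- function(input_path) {
  paste0(sub("/+$", "", input_path), "_dm")
}

.cfg_subset_text <- function(doc, sections) {
  full <- serialize_config(doc)
  keep <- character()
  lines <- strsplit(full, "\n")[[1]]
  sec <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) sec <- gsub("[][]", "", ln)
    if (!is.null(sec) && sec %in% sections && !grepl("^#", ln) && ln != "")
      keep <- c(keep, ln)
  }
  paste(keep, collapse = "\n")
}

.stage_hash_file <- function(results_dir, stage) {
  file.path(results_dir, sprintf(".cache_%s.md5", stage))
}

.stage_cached <- function(results_dir, stage, hash, outputs) {
  f <- .stage_hash_file(results_dir, stage)
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash) &&
    all(file.exists(file.path(results_dir, outputs)))
}

.stage_mark <- function(results_dir, stage, hash) {
  writeLines(hash, .stage_hash_file(results_dir, stage))
}

.load_config <- function(results_dir, overrides = list(), profile = NULL) {
  doc <- if (!is.null(profile)) {
    parse_config(readLines(profile, warn = FALSE))
  } else if (file.exists(file.path(results_dir, "pipeline.cfg"))) {
    parse_config(readLines(file.path(results_dir, "pipeline.cfg"),
                           warn = FALSE))
  } else {
    default_config()
  }
  config_override(doc, overrides)
}

.require_meta <- function(doc, interactive = FALSE) {
  need <- c("wavelength_nm", "pixel_size_um", "medium_index")
  missing <- need[vapply(need, function(k) is.na(doc$meta[[k]]), TRUE)]
  if (!length(missing)) return(doc)
  if (!interactive)
    stop("missing configuration: ",
         paste0("meta.", missing, collapse = ", "))
  for (k in missing) {
    v <- as.numeric(readline(sprintf("Enter meta.%s: ", k)))
    doc <- config_override(doc, stats::setNames(list(v), paste0("meta.", k)))
  }
  doc
}

.meta_units <- function(doc) {
  list(wavelength = doc$meta$wavelength_nm * 1e-9,
       pixel_size = doc$meta$pixel_size_um * 1e-6,
       medium_index = doc$meta$medium_index)
}

#' Convert raw data to phase and amplitude
#'
#' Reads the raw series, reconstructs off-axis holograms (or passes through
#' phase inputs), and writes the sensor multi-page TIF, the HDF5 store and
#' the configuration file into the results directory `<input>_dm`.
#' Wavelength, pixel size and medium index must be present in the
#' configuration (or are prompted for when `interactive = TRUE`).
#'
#' @param input_path folder, zip archive or multi-page TIF of raw images.
#' @param overrides named list of configuration overrides, names like
#'   `"roi.size_um"`.
#' @param profile optional path to a configuration file that replaces the
#'   stored configuration wholesale.
#' @param interactive prompt for missing metadata instead of failing.
#' @return Pipeline state (list), invisibly: `results_dir`, `dataset_id`,
#'   `config`, `n_images`.
#' @export
dm_convert <- function(input_path, overrides = list(), profile = NULL,
                       interactive = FALSE) {
  if (!file.exists(input_path)) stop("input not found: ", input_path)
  rd <- .results_dir(input_path)
  if (!dir.exists(rd)) dir.create(rd, recursive = TRUE)
  doc <- .require_meta(.load_config(rd, overrides, profile), interactive)
  did <- dataset_identifier(input_path)
  state <- list(input_path = input_path, results_dir = rd, dataset_id = did,
                config = doc)
  writeLines(serialize_config(doc), file.path(rd, "pipeline.cfg"))
  hash <- text_md5(paste(did, .cfg_subset_text(doc, c("meta", "holo")),
                         sep = "\n"))
  outs <- "sensor_data.tif"
  if (.stage_cached(rd, "convert", hash, outs)) {
    sp_log(state, "convert", "cached, skipping")
    state$n_images <- length(.read_sidecar(file.path(rd, outs))$pages) / 2
    return(invisible(state))
  }
  mu <- .meta_units(doc)
  raws <- read_image_series(input_path, doc$meta$time_interval_s)
  sp_log(state, "convert", "loaded ", length(raws), " raw images")
  qpis <- vector("list", length(raws))
  for (i in seq_along(raws)) {
    meta <- c(mu, list(time = raws[[i]]$time,
                       identifier = sprintf("%s_%d", did, i)))
    if (doc$meta$data_type == "phase") {
      qpis[[i]] <- qpimage(raws[[i]]$pixels,
                           wavelength = mu$wavelength,
                           pixel_size = mu$pixel_size,
                           medium_index = mu$medium_index,
                           time = raws[[i]]$time,
                           identifier = meta$identifier)
    } else {
      carrier <- if (identical(doc$holo$sideband, "auto")) NULL else
        structure(list(kx = doc$holo$sideband[1], ky = doc$holo$sideband[2],
                       mode = "fixed"), class = "carrier_spec")
      qpis[[i]] <- reconstruct_hologram(
        raws[[i]], carrier = carrier,
        filter_name = doc$holo$filter_name,
        size_rel = doc$holo$filter_size_rel,
        meta = meta, invert_phase = doc$holo$invert_phase)
    }
  }
  write_qpi_stack(qpis, file.path(rd, "sensor_data.tif"))
  if (isTRUE(doc$output$write_h5)) {
    h5 <- file.path(rd, "sensor_data.h5")
    h5_store_init(h5)
    for (i in seq_along(qpis)) h5_write_image(h5, i, qpis[[i]])
  }
  .stage_mark(rd, "convert", hash)
  sp_log(state, "convert", "wrote sensor data for ", length(qpis), " images")
  state$n_images <- length(qpis)
  invisible(state)
}

.roi_bg_spec <- function(doc, roi_shape) {
  b <- doc$bg$roi_border_px
  if (b == 0) b <- max(1L, round(0.1 * min(roi_shape)))
  thr <- doc$bg$roi_binary_threshold
  bg_spec(profile = doc$bg$roi_profile, border_px = b,
          binary_threshold = if (is.na(thr)) NULL else thr,
          offset_mode = doc$bg$roi_offset_mode)
}

#' Detect, correct and export regions of interest
#'
#' Runs [dm_convert()] if needed, applies the whole-sensor background
#' correction, detects ROIs per the `[roi]` configuration, honors the
#' `ignore data` list, applies the per-ROI background correction and writes
#' the ROI TIF stack plus the ROI table `rois.tsv`.
#'
#' @inheritParams dm_convert
#' @return Pipeline state with elements `rois` (data.frame) and `n_rois`.
#' @export
dm_extract_roi <- function(input_path, overrides = list(), profile = NULL,
                           interactive = FALSE) {
  state <- dm_convert(input_path, overrides, profile, interactive)
  rd <- state$results_dir
  doc <- state$config
  conv_hash <- readLines(.stage_hash_file(rd, "convert"), warn = FALSE)[1]
  hash <- text_md5(paste(conv_hash, .cfg_subset_text(doc, c("roi", "bg")),
                         sep = "\n"))
  outs <- c("roi_data.tif", "rois.tsv")
  if (.stage_cached(rd, "roi", hash, outs)) {
    sp_log(state, "roi", "cached, skipping")
    state$rois <- utils::read.delim(file.path(rd, "rois.tsv"))
    state$n_rois <- nrow(state$rois)
    return(invisible(state))
  }
  qpis <- read_qpi_stack(file.path(rd, "sensor_data.tif"))
  mu <- .meta_units(doc)
  size_px <- doc$roi$size_um / doc$meta$pixel_size_um
  sensor_thr <- doc$bg$sensor_binary_threshold
  sensor_spec <- bg_spec(profile = doc$bg$sensor_profile,
                         border_px = doc$bg$sensor_border_px,
                         binary_threshold = if (is.na(sensor_thr)) NULL else
                           sensor_thr,
                         offset_mode = doc$bg$sensor_offset_mode)
  roi_qpis <- list(); roi_rows <- list()
  for (i in seq_along(qpis)) {
    q <- correct_background(qpis[[i]], sensor_spec)
    rois <- find_rois(q$phase, size_px = size_px,
                      variation = doc$roi$size_variation,
                      pad_px = doc$roi$pad_border_px,
                      threshold_method = doc$roi$threshold,
                      exclude_border_px = doc$roi$exclude_border_px,
                      image_index = i, dataset = state$dataset_id)
    rois <- filter_ignored(rois, doc$roi$`ignore data`)
    for (rr in rois) {
      rq <- extract_roi(q, rr, .roi_bg_spec(doc, c(rr$r1 - rr$r0,
                                                   rr$c1 - rr$c0)))
      roi_qpis[[length(roi_qpis) + 1L]] <- rq
      roi_rows[[length(roi_rows) + 1L]] <-
        data.frame(image = rr$image_index, roi = rr$roi_index,
                   r0 = rr$r0, r1 = rr$r1, c0 = rr$c0, c1 = rr$c1,
                   identifier = rr$identifier)
    }
  }
  roi_tab <- if (length(roi_rows)) do.call(rbind, roi_rows) else
    data.frame(image = integer(), roi = integer(), r0 = integer(),
               r1 = integer(), c0 = integer(), c1 = integer(),
               identifier = character())
  utils::write.table(roi_tab, file.path(rd, "rois.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(roi_qpis)) {
    write_qpi_stack(roi_qpis, file.path(rd, "roi_data.tif"))
  } else {
    # no ROIs: still create an (empty-sidecar) placeholder so caching works
    jsonlite::write_json(list(pages = list()),
                         .sidecar_path(file.path(rd, "roi_data.tif")),
                         auto_unbox = TRUE)
    file.create(file.path(rd, "roi_data.tif"))
  }
  if (isTRUE(doc$output$write_h5) &&
      file.exists(file.path(rd, "sensor_data.h5"))) {
    h5 <- file.path(rd, "sensor_data.h5")
    for (k in seq_along(roi_qpis))
      try(h5_write_roi(h5, roi_tab$image[k], roi_tab$roi[k],
                       roi_qpis[[k]]$phase), silent = TRUE)
  }
  .stage_mark(rd, "roi", hash)
  sp_log(state, "roi", "extracted ", nrow(roi_tab), " ROIs")
  state$rois <- roi_tab
  state$n_rois <- nrow(roi_tab)
  invisible(state)
}

.fallback_init <- function(rq) {
  g <- grid_of(rq)
  sphere_params(g$medium_index + 0.01,
                0.25 * min(g$shape) * g$pixel_size,
                (g$shape[1] - 1) / 2, (g$shape[2] - 1) / 2,
                stats::median(rq$phase))
}

#' Fit sphere models to all ROIs and export statistics
#'
#' Runs the earlier stages if needed, fits each ROI per the `[sphere]`
#' configuration, and writes the statistics TSV
#' `sphere_<method>_<model>_statistics.tsv`, the fit-visualization TIF
#' `sphere_<method>_<model>_images.tif` (pages: data phase, model phase,
#' residuals, data amplitude, model amplitude per ROI) and the fitted phase
#' into the HDF5 store.
#'
#' @inheritParams dm_convert
#' @return Pipeline state with `records` (data.frame) and `stats_path`.
#' @export
dm_analyze_sphere <- function(input_path, overrides = list(), profile = NULL,
                              interactive = FALSE) {
  state <- dm_extract_roi(input_path, overrides, profile, interactive)
  rd <- state$results_dir
  doc <- state$config
  method <- doc$sphere$method
  model <- if (method == "edge") "projection" else doc$sphere$model
  tag <- sprintf("sphere_%s_%s", method, model)
  stats_file <- paste0(tag, "_statistics.tsv")
  roi_hash <- readLines(.stage_hash_file(rd, "roi"), warn = FALSE)[1]
  hash <- text_md5(paste(roi_hash, .cfg_subset_text(doc, "sphere"),
                         sep = "\n"))
  if (.stage_cached(rd, "sphere", hash, stats_file)) {
    sp_log(state, "sphere", "cached, skipping")
    state$records <- utils::read.delim(file.path(rd, stats_file))
    state$stats_path <- file.path(rd, stats_file)
    return(invisible(state))
  }
  roi_qpis <- if (state$n_rois > 0)
    read_qpi_stack(file.path(rd, "roi_data.tif")) else list()
  if (!length(roi_qpis)) {
    warning("no ROIs to analyze; writing empty statistics table")
    cat(records_tsv(summarize_fits(list(), list())),
        file = file.path(rd, stats_file))
    .stage_mark(rd, "sphere", hash)
    state$records <- utils::read.delim(file.path(rd, stats_file))
    state$stats_path <- file.path(rd, stats_file)
    return(invisible(state))
  }
  sc <- doc$sphere$sc_coefficients
  if (identical(sc, "auto")) sc <- rytov_sc_default_coeffs()
  fits <- vector("list", length(roi_qpis))
  vis_pages <- list(); vis_meta <- list()
  for (k in seq_along(roi_qpis)) {
    rq <- roi_qpis[[k]]
    init <- tryCatch(edge_estimate(rq), error = function(e) .fallback_init(rq))
    if (method == "edge") {
      mdl <- model_phase_image(init, grid_of(rq), "projection", 1L)
      resid <- rq$phase - mdl
      fits[[k]] <- structure(
        list(params = init, params_corrected = NULL, model = "projection",
             cost = sum(resid^2), n_iterations = 0L, converged = TRUE,
             residual_image = resid),
        class = "sphere_fit")
    } else {
      fits[[k]] <- fit_sphere_image(rq, model = model, init = init,
                                    tol = doc$sphere$tol,
                                    max_evals = doc$sphere$max_evals,
                                    sc_coeffs = sc)
    }
    if (isTRUE(doc$output$write_fit_images)) {
      f <- fits[[k]]
      mdl <- model_phase_image(f$params, grid_of(rq),
                               if (model == "rytov-sc") "rytov" else model, 1L)
      amdl <- if (model %in% c("rytov", "rytov-sc"))
        suppressWarnings(rytov_field(f$params, grid_of(rq))$amplitude) else
        matrix(1, nrow(rq$phase), ncol(rq$phase))
      pg <- list(rq$phase, mdl, f$residual_image, rq$amplitude, amdl)
      kinds <- c("data phase", "model phase", "residuals",
                 "data amplitude", "model amplitude")
      vis_pages <- c(vis_pages, pg)
      vis_meta <- c(vis_meta, lapply(kinds, function(kd)
        list(identifier = rq$identifier, kind = kd)))
    }
  }
  records <- summarize_fits(fits, roi_qpis,
                            alpha = doc$sphere$refraction_increment_ml_g,
                            method = method)
  cat(records_tsv(records), file = file.path(rd, stats_file))
  if (length(vis_pages))
    .write_tif_scaled(vis_pages, file.path(rd, paste0(tag, "_images.tif")),
                      page_meta = vis_meta)
  if (isTRUE(doc$output$write_h5) &&
      file.exists(file.path(rd, "sensor_data.h5"))) {
    h5 <- file.path(rd, "sensor_data.h5")
    for (k in seq_along(roi_qpis)) {
      f <- fits[[k]]
      mdl <- roi_qpis[[k]]$phase - f$residual_image
      loc <- state$rois[k, ]
      grp <- sprintf("image_%d/roi_%d", loc$image, loc$roi)
      try(rhdf5::h5delete(h5, paste0(grp, "/phase_fit")), silent = TRUE)
      try(rhdf5::h5write(mdl, h5, paste0(grp, "/phase_fit")), silent = TRUE)
    }
  }
  .stage_mark(rd, "sphere", hash)
  sp_log(state, "sphere", "fitted ", length(fits), " ROIs (", tag, ")")
  state$records <- records
  state$stats_path <- file.path(rd, stats_file)
  invisible(state)
}
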