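# Raw image series input (folder / zip / multi-page TIF) and pipeline
# outputs (multi-page float32 TIF with a JSON metadata sidecar, HDF5 store).
#
# TIF dialect: libtiff float pages must lie in [0, 1], so every page is
# stored as (value - offset) / scale with the per-page offset/scale and the
# acquisition metadata (identifier, time, pixel size, wavelength) recorded
# in "<file>.meta.json" next to the TIF.  Round-trips preserve phase to
# float32 quantization (~1e-6 rad for typical phase ranges).

.read_tif_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

.page_matrix <- function(page) {
  if (length(dim(page)) == 3) page <- page[, , 1]  # first channel
  m <- as.matrix(page)
  attributes(m) <- list(dim = dim(m))
  m
}

.sidecar_path <- function(path) paste0(path, ".meta.json")

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::fromJSON(sp, simplifyVector = FALSE)
}

# apply per-page scale/offset from a sidecar, if present
.decode_page <- function(m, meta_page) {
  if (is.null(meta_page)) return(m)
  m * (meta_page$scale %||% 1) + (meta_page$offset %||% 0)
}

.tif_time <- function(page, path, index, dt) {
  info <- attributes(page)
  if (!is.null(info$date.time)) {
    t <- suppressWarnings(as.POSIXct(info$date.time, format = "%Y:%m:%d %H:%M:%S",
                                     tz = "UTC"))
    if (!is.na(t)) return(as.numeric(t))
  }
  mt <- file.mtime(path)
  if (!is.na(mt)) return(as.numeric(mt))
  (index - 1) * dt
}

.is_sid4bio <- function(path) grepl("sid4", tolower(basename(path)))

#' Read a raw image series
#'
#' Accepts a folder of single-page TIF files, a zip archive of such files,
#' or one multi-page TIF stack.  Folder/zip members are ordered by
#' numeric-aware filename sort (so `img_2` precedes `img_10`); stack pages
#' keep their page order.  Acquisition times are taken from a metadata
#' sidecar written by this package, else the TIF DateTime tag, else the file
#' modification time, else the index-based fallback `(index - 1) * dt`.
#'
#' @param path folder, `.zip` file, or TIF file.
#' @param time_interval_s fallback frame spacing in seconds.
#' @return List of raw images: each a list with `pixels` (matrix),
#'   `source_name`, `time` (s), `index` (1-based).
#' @export
read_image_series <- function(path, time_interval_s = 1.0) {
  if (!file.exists(path)) stop("input not found: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no images found in ", path)
    return(.read_series_files(files[natural_order(files)], time_interval_s))
  }
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("series_")
    dir.create(exdir)
    utils::unzip(path, exdir = exdir, setTimes = TRUE)
    files <- list.files(exdir, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE, recursive = TRUE)
    if (!length(files)) stop("no images found in ", path)
    return(.read_series_files(files[natural_order(files)], time_interval_s))
  }
  # multi-page TIF stack
  if (.is_sid4bio(path)) stop("unsupported format: SID4Bio")
  pages <- .read_tif_pages(path)
  meta <- .read_sidecar(path)
  lapply(seq_along(pages), function(i) {
    mp <- if (!is.null(meta)) meta$pages[[i]] else NULL
    px <- .decode_page(.page_matrix(pages[[i]]), mp)
    if (!all(is.finite(px))) stop("unreadable page ", i, " in ", path)
    tm <- if (!is.null(mp$time)) mp$time else
      .tif_time(pages[[i]], path, i, time_interval_s)
    list(pixels = px, source_name = sprintf("%s#%d", basename(path), i),
         time = tm, index = i)
  })
}

.read_series_files <- function(files, dt) {
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    if (.is_sid4bio(f)) stop("unsupported format: SID4Bio")
    pages <- tryCatch(.read_tif_pages(f),
                      error = function(e) stop("unreadable image ", basename(f),
                                               ": ", conditionMessage(e)))
    meta <- .read_sidecar(f)
    mp <- if (!is.null(meta)) meta$pages[[1]] else NULL
    px <- .decode_page(.page_matrix(pages[[1]]), mp)
    if (!all(is.finite(px))) stop("unreadable image ", basename(f))
    tm <- if (!is.null(mp$time)) mp$time else .tif_time(pages[[1]], f, i, dt)
    out[[i]] <- list(pixels = px, source_name = basename(f), time = tm,
                     index = i)
  }
  out
}

# write matrices as float32 pages scaled to [0, 1]; page_meta is a list of
# per-page metadata lists merged with the computed offset/scale
.write_tif_scaled <- function(pages, path, page_meta = NULL, extra = NULL) {
  enc <- vector("list", length(pages))
  meta_pages <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    enc[[i]] <- (m - lo) / scale
    meta_pages[[i]] <- c(list(offset = lo, scale = scale),
                         if (!is.null(page_meta)) page_meta[[i]])
  }
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(c(list(pages = meta_pages), extra),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write quantitative phase images to a multi-page TIF stack
#'
#' Pages are interleaved `(phase_1, amplitude_1, phase_2, amplitude_2, ...)`,
#' stored as float32 with per-page offset/scale and identifier/time/pixel
#' size in the JSON sidecar.  All images must share pixel size and
#' wavelength.
#'
#' @param images list of [qpimage()].
#' @param path output TIF path.
#' @return `path`, invisibly.
#' @export
write_qpi_stack <- function(images, path) {
  if (!length(images)) stop("nothing to write")
  ps <- vapply(images, `[[`, 0, "pixel_size")
  wl <- vapply(images, `[[`, 0, "wavelength")
  if (diff(range(ps)) > 0 || diff(range(wl)) > 0)
    stop("mixed pixel size or wavelength across images")
  pages <- list(); page_meta <- list()
  for (q in images) {
    base <- list(identifier = q$identifier, time = q$time,
                 pixel_size_um = q$pixel_size * 1e6,
                 wavelength_nm = q$wavelength * 1e9,
                 medium_index = q$medium_index)
    pages <- c(pages, list(q$phase, q$amplitude))
    page_meta <- c(page_meta,
                   list(c(base, kind = "phase"), c(base, kind = "amplitude")))
  }
  .write_tif_scaled(pages, path, page_meta)
}

#' Read back a stack written by [write_qpi_stack()]
#'
#' @param path TIF path with its JSON sidecar.
#' @return List of [qpimage()].
#' @export
read_qpi_stack <- function(path) {
  meta <- .read_sidecar(path)
  if (is.null(meta)) stop("no metadata sidecar for ", path)
  pages <- .read_tif_pages(path)
  n <- length(pages) / 2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mp_p <- meta$pages[[2 * i - 1]]; mp_a <- meta$pages[[2 * i]]
    ph <- .decode_page(.page_matrix(pages[[2 * i - 1]]), mp_p)
    am <- .decode_page(.page_matrix(pages[[2 * i]]), mp_a)
    out[[i]] <- qpimage(ph, am,
                        wavelength = mp_p$wavelength_nm * 1e-9,
                        pixel_size = mp_p$pixel_size_um * 1e-6,
                        medium_index = mp_p$medium_index,
                        time = mp_p$time, identifier = mp_p$identifier)
  }
  out
}

# ---- HDF5 results store ----------------------------------------------------

h5_store_init <- function(path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  invisible(path)
}

h5_write_image <- function(path, i, qpi) {
  grp <- sprintf("image_%d", i)
  rhdf5::h5createGroup(path, grp)
  rhdf5::h5write(qpi$phase, path, paste0(grp, "/phase"))
  rhdf5::h5write(qpi$amplitude, path, paste0(grp, "/amplitude"))
  invisible(path)
}

h5_write_roi <- function(path, image_index, roi_index, phase,
                         phase_fit = NULL, attrs = NULL) {
  grp <- sprintf("image_%d/roi_%d", image_index, roi_index)
  rhdf5::h5createGroup(path, grp)
  rhdf5::h5write(phase, path, paste0(grp, "/phase"))
  if (!is.null(phase_fit))
    rhdf5::h5write(phase_fit, path, paste0(grp, "/phase_fit"))
  if (!is.null(attrs)) {
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, grp)
    for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], gid, nm)
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}
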