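# INI-style pipeline configuration: "[section]" / "key = value" lines, "#"
# comments, case-insensitive keys, spaces allowed in key names, values never
# quoted.  Every key is typed and validated; unknown sections or keys are
# rejected with an error naming them.  serialize(parse(t)) is idempotent.

# key registry: type, default, constraints, description
.config_spec <- function() {
  num <- function(default, min = -Inf, desc = "") {
    list(type = "float", default = default, min = min, desc = desc)
  }
  list(
    meta = list(
      "wavelength_nm"   = num(NA_real_, 0, "imaging wavelength [nm] (required)"),
      "pixel_size_um"   = num(NA_real_, 0, "detector pixel size [um] (required)"),
      "medium_index"    = num(NA_real_, 1, "refractive index of the medium (required)"),
      "time_interval_s" = num(1.0, 0, "frame spacing fallback when no timestamps exist [s]"),
      "data_type"       = list(type = "enum", default = "hologram",
                               choices = c("hologram", "phase"),
                               desc = "raw input interpretation")
    ),
    holo = list(
      "filter_name" = list(type = "enum", default = "smooth disk",
                           choices = c("disk", "smooth disk", "gauss", "square"),
                           desc = "sideband filter type"),
      "filter_size_rel" = num(1 / 3, 0, "filter size as fraction of carrier distance"),
      "sideband" = list(type = "sideband", default = "auto",
                        desc = "auto or fixed carrier 'kx,ky' [rad/px]"),
      "invert_phase" = list(type = "bool", default = FALSE,
                            desc = "flip the reconstructed phase sign")
    ),
    roi = list(
      "size_um" = num(10, 0, "approximate specimen diameter [um]"),
      "size_variation" = num(0.5, 0, "allowed relative deviation of the diameter"),
      "pad_border_px" = list(type = "int", default = 10L, min = 0,
                             desc = "ROI bounding-box padding [px]"),
      "exclude_border_px" = list(type = "int", default = 5L, min = 0,
                                 desc = "discard objects this close to the image border [px]"),
      "threshold" = list(type = "threshold", default = "otsu",
                         desc = "otsu | dm-nuclei | numeric value [rad]"),
      "ignore data" = list(type = "ignore_list", default = list(),
                           desc = "ROIs excluded from analysis, e.g. 9.4, 12.1")
    ),
    bg = list(
      "sensor_profile" = list(type = "enum", default = "tilt",
                              choices = c("offset", "tilt", "poly2o", "image"),
                              desc = "whole-sensor background model"),
      "sensor_border_px" = list(type = "int", default = 10L, min = 0,
                                desc = "sensor background border frame [px]"),
      "sensor_binary_threshold" = num(NA_real_, -Inf, "sensor background phase threshold [rad]"),
      "sensor_offset_mode" = list(type = "enum", default = "mean",
                                  choices = c("mean", "median"),
                                  desc = "offset estimator"),
      "roi_profile" = list(type = "enum", default = "poly2o",
                           choices = c("offset", "tilt", "poly2o", "image"),
                           desc = "per-ROI background model"),
      "roi_border_px" = list(type = "int", default = 0L, min = 0,
                             desc = "per-ROI border frame [px]; 0 = 10% of ROI size"),
      "roi_binary_threshold" = num(NA_real_, -Inf, "per-ROI background phase threshold [rad]"),
      "roi_offset_mode" = list(type = "enum", default = "mean",
                               choices = c("mean", "median"),
                               desc = "offset estimator")
    ),
    sphere = list(
      "method" = list(type = "enum", default = "image",
                      choices = c("edge", "image"), desc = "analysis method"),
      "model" = list(type = "enum", default = "projection",
                     choices = c("projection", "rytov", "rytov-sc"),
                     desc = "sphere model for image fits"),
      "refraction_increment_ml_g" = num(0.18, 0, "refraction increment alpha [mL/g]"),
      "max_evals" = list(type = "int", default = 250L, min = 1,
                         desc = "model evaluations per parameter"),
      "tol" = num(1e-9, 0, "relative cost-improvement stopping tolerance"),
      "sc_coefficients" = list(type = "sc_coeffs", default = "auto",
                               desc = "auto or 'c_n0,c_n1,c_r0,c_r1'")
    ),
    output = list(
      "write_fit_images" = list(type = "bool", default = TRUE,
                                desc = "write per-ROI fit visualization TIF"),
      "write_h5" = list(type = "bool", default = TRUE,
                        desc = "write the HDF5 results store")
    )
  )
}

.parse_value <- function(raw, def, where) {
  raw <- trimws(raw)
  bad <- function(why) stop(sprintf("config %s: %s (got '%s')", where, why, raw))
  switch(def$type,
    float = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v) && !identical(tolower(raw), "na")) bad("expected a number")
      if (!is.na(v) && is.finite(def$min) && v < def$min) bad(sprintf("must be >= %g", def$min))
      v
    },
    int = {
      v <- suppressWarnings(as.integer(raw))
      if (is.na(v)) bad("expected an integer")
      if (!is.null(def$min) && v < def$min) bad(sprintf("must be >= %d", def$min))
      v
    },
    bool = {
      lv <- tolower(raw)
      if (!lv %in% c("true", "false", "yes", "no", "1", "0")) bad("expected a boolean")
      lv %in% c("true", "yes", "1")
    },
    enum = {
      if (!raw %in% def$choices)
        bad(paste0("expected one of: ", paste(def$choices, collapse = ", ")))
      raw
    },
    threshold = {
      v <- suppressWarnings(as.numeric(raw))
      if (!is.na(v)) v else if (raw %in% c("otsu", "dm-nuclei")) raw else
        bad("expected otsu, dm-nuclei or a number")
    },
    sideband = {
      if (identical(raw, "auto")) return("auto")
      v <- suppressWarnings(as.numeric(strsplit(raw, ",")[[1]]))
      if (length(v) != 2 || anyNA(v)) bad("expected auto or 'kx,ky'")
      v
    },
    sc_coeffs = {
      if (identical(raw, "auto")) return("auto")
      v <- suppressWarnings(as.numeric(strsplit(raw, ",")[[1]]))
      if (length(v) != 4 || anyNA(v)) bad("expected auto or 4 numbers")
      stats::setNames(v, c("c_n0", "c_n1", "c_r0", "c_r1"))
    },
    ignore_list = {
      if (raw == "") return(list())
      parts <- trimws(strsplit(raw, ",")[[1]])
      lapply(parts, function(p) {
        iv <- suppressWarnings(as.integer(strsplit(p, "\\.")[[1]]))
        if (length(iv) != 2 || anyNA(iv)) bad("expected entries like 9.4")
        iv
      })
    },
    stop("unhandled config type"))
}

.format_value <- function(v, def) {
  switch(def$type,
    bool = if (isTRUE(v)) "true" else "false",
    ignore_list = paste(vapply(v, function(p) sprintf("%d.%d", p[1], p[2]), ""),
                        collapse = ", "),
    sideband = if (identical(v, "auto")) "auto" else
      paste(format(v, digits = 15), collapse = ","),
    sc_coeffs = if (identical(v, "auto")) "auto" else
      paste(format(unname(v), digits = 15), collapse = ","),
    float = format(v, digits = 15),
    int = format(v),
    as.character(v))
}

#' Default pipeline configuration
#'
#' All sections and keys at their documented defaults.
#' @return A `config_doc` (nested named list, `sections$key`).
#' @export
default_config <- function() {
  spec <- .config_spec()
  doc <- lapply(spec, function(sec) lapply(sec, `[[`, "default"))
  structure(doc, class = "config_doc")
}

#' Parse pipeline configuration text
#'
#' Line-based INI dialect: `[section]` headers, `key = value` entries, `#`
#' comments.  Keys are case-insensitive and may contain spaces; values are
#' typed and validated.  Missing keys are filled with defaults; unknown
#' sections or keys raise an error naming them.
#'
#' @param text configuration text (single string or character vector of
#'   lines).
#' @return A `config_doc`.
#' @export
parse_config <- function(text) {
  spec <- .config_spec()
  doc <- default_config()
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  section <- NULL
  for (ln in trimws(lines)) {
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(trimws(substr(ln, 2, nchar(ln) - 1)))
      if (!section %in% names(spec))
        stop("unknown config section: [", section, "]")
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: '", ln, "'")
    if (is.null(section)) stop("config entry before any [section]: '", ln, "'")
    eq <- regexpr("=", ln, fixed = TRUE)
    key <- tolower(trimws(substr(ln, 1, eq - 1)))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!key %in% names(spec[[section]]))
      stop("unknown config key: ", section, ".", key)
    doc[[section]][[key]] <- .parse_value(val, spec[[section]][[key]],
                                          paste0(section, ".", key))
  }
  .validate_config(doc)
  doc
}

.validate_config <- function(doc) {
  m <- doc$meta
  chk <- function(ok, what) if (!isTRUE(ok)) stop("config meta.", what)
  if (!is.na(m$wavelength_nm)) chk(m$wavelength_nm > 0, "wavelength_nm must be > 0")
  if (!is.na(m$pixel_size_um)) chk(m$pixel_size_um > 0, "pixel_size_um must be > 0")
  if (!is.na(m$medium_index)) chk(m$medium_index >= 1, "medium_index must be >= 1.0")
  if (doc$roi$size_variation <= 0 || doc$roi$size_variation >= 1)
    stop("config roi.size_variation must be in (0, 1)")
  invisible(doc)
}

#' Serialize a configuration to text
#'
#' Produces a complete commented template: every known key appears with its
#' current value, preceded by a `#` comment describing it.
#' `parse_config(serialize_config(parse_config(t)))` equals
#' `parse_config(t)`.
#'
#' @param doc a `config_doc`.
#' @return Single character string of configuration text.
#' @export
serialize_config <- function(doc) {
  spec <- .config_spec()
  out <- character()
  for (sec in names(spec)) {
    out <- c(out, sprintf("[%s]", sec))
    for (key in names(spec[[sec]])) {
      def <- spec[[sec]][[key]]
      out <- c(out, paste0("# ", def$desc),
               sprintf("%s = %s", key, .format_value(doc[[sec]][[key]], def)))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

# apply named overrides like list("roi.size_um" = 7, "sphere.model" = "rytov-sc");
# values may be R values or raw strings (strings are run through the parser)
config_override <- function(doc, overrides) {
  spec <- .config_spec()
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    sec <- tolower(parts[1])
    key <- tolower(paste(parts[-1], collapse = "."))
    if (!sec %in% names(spec) || !key %in% names(spec[[sec]]))
      stop("unknown config key: ", sec, ".", key)
    v <- overrides[[nm]]
    if (is.character(v) && length(v) == 1)
      v <- .parse_value(v, spec[[sec]][[key]], nm)
    doc[[sec]][[key]] <- v
  }
  .validate_config(doc)
  doc
}
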