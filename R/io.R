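# Readers/writers for the pipeline's on-disk formats: TIFF stacks,
# localization CSV (with ThunderSTORM-style aliasing), trace CSV,
# kymograph CSV + JSON metadata, and JSON parameter sidecars.

#' Write / read an image stack as a multi-page TIFF
#'
#' Frames (and channels, interleaved within frame) are written as 32-bit
#' TIFF pages. Intensities are min-max scaled into the TIFF's unit range;
#' the affine scale travels, with the calibration and channel names, in a
#' JSON sidecar (`<path>.json`) and is inverted on read.
#'
#' @param stack An [image_stack()].
#' @param path Output file (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  span <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[4])) {
    pages[[k]] <- (stack$data[t, , , c] - lo) / span
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            frame_interval_s = stack$frame_interval_s,
                            channels = stack$channels,
                            n_frames = d[1],
                            intensity_offset = lo,
                            intensity_scale = span),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_c <- length(meta$channels)
  n_t <- length(pages) / n_c
  d1 <- dim(pages[[1]])
  data <- array(0, dim = c(n_t, d1[1], d1[2], n_c))
  k <- 1L
  for (t in seq_len(n_t)) for (c in seq_len(n_c)) {
    data[t, , , c] <- pages[[k]] * meta$intensity_scale +
      meta$intensity_offset
    k <- k + 1L
  }
  image_stack(data, meta$pixel_size_um, meta$frame_interval_s,
              meta$channels)
}

#' Write / read a localization table as CSV
#'
#' The native header is `x_nm,y_nm,z_nm,frame,precision_nm` (z optional).
#' `read_localizations()` also accepts ThunderSTORM-style exports via
#' `aliases`, a named map from native names to the column names found in
#' the file (e.g. `c(x_nm = "x [nm]", precision_nm = "uncertainty [nm]")`).
#'
#' @param locs A `localization_table`.
#' @param path CSV file path.
#' @param aliases Named character map for nonstandard headers.
#' @return The table (readers) or `path`, invisibly (writers).
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path, aliases = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(aliases)) {
    for (native in names(aliases)) {
      hit <- match(aliases[[native]], names(d))
      if (!is.na(hit)) names(d)[hit] <- native
    }
  }
  if (!all(c("x_nm", "y_nm") %in% names(d)))
    stopf("localization CSV needs x_nm and y_nm columns (use aliases?)")
  if (!"frame" %in% names(d)) d$frame <- seq_len(nrow(d))
  if (!"precision_nm" %in% names(d)) d$precision_nm <- NA_real_
  if (any(d$precision_nm < 0, na.rm = TRUE))
    stopf("precision must be >= 0")
  structure(d, class = c("localization_table", "data.frame"))
}

#' Serialize a kymograph to CSV plus JSON metadata
#'
#' CSV rows are arclength positions, columns are frames (the transpose of
#' the in-memory layout); calibrations and the baseline window go to
#' `<path>.json`.
#'
#' @param kym A [kymograph()].
#' @param path CSV file path.
#' @export
write_kymograph <- function(kym, path) {
  stopifnot(inherits(kym, "kymograph"))
  utils::write.table(t(kym$values), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(arclength_step_um = kym$arclength_step_um,
                            frame_interval_s = kym$frame_interval_s,
                            channel = kym$channel,
                            baseline_window = kym$baseline_window),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- t(unname(as.matrix(utils::read.csv(path, header = FALSE))))
  kymograph(vals, meta$arclength_step_um, meta$frame_interval_s,
            meta$channel,
            if (length(meta$baseline_window)) meta$baseline_window)
}

#' Write / read a trace set as CSV plus JSON metadata
#'
#' @param traces A [trace_set()].
#' @param path CSV file path (one column per ROI, one row per frame).
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  utils::write.csv(as.data.frame(traces$traces), path, row.names = FALSE)
  jsonlite::write_json(list(channels = as.list(traces$channels),
                            baseline_window = traces$baseline_window,
                            stimulus_frame = traces$stimulus_frame,
                            frame_interval_s = traces$frame_interval_s),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  trace_set(m, channels = unlist(meta$channels)[colnames(m)],
            baseline_window = meta$baseline_window,
            stimulus_frame = meta$stimulus_frame,
            frame_interval_s = meta$frame_interval_s)
}

#' Write an analysis result as a JSON sidecar
#'
#' Strips classes and writes plain values; used for helix parameters,
#' contraction reports, ground-truth exports, and manifests.
#'
#' @param x A list-like result.
#' @param path Output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, function(col)
    if (is.factor(col)) as.character(col) else col)))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.factor(x)) return(as.character(x))
  if (is.table(x)) return(as.list(stats::setNames(as.numeric(x), names(x))))
  x
}
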