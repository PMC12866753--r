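# On-disk formats: flat binary float32 + JSON sidecar for traces and
# matrices, CSV for tables (hypnogram, trial table, spindle events).

#' Write / read a numeric trace (flat binary float32 + JSON sidecar)
#'
#' @param x numeric vector.
#' @param path output path for the binary data; the sidecar is `<path>.json`.
#' @param rate sampling rate, Hz.
#' @param channel channel name recorded in the sidecar.
#' @return `path`, invisibly (writer); list `values`, `rate`, `channel`
#'   (reader).
#' @export
write_trace <- function(x, path, rate, channel = "trace") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  jsonlite::write_json(list(n = length(x), rate = rate, channel = channel,
                            dtype = "float32", endian = "little"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @param path path written by [write_trace()].
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = meta$n, size = 4, endian = "little")
  list(values = vals, rate = meta$rate, channel = meta$channel)
}

#' Write / read a raster (flat binary float32 + JSON sidecar)
#'
#' @param r [raster()] object.
#' @param path output path; sidecar at `<path>.json`.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "sg_raster"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(r$counts), con, size = 4, endian = "little")
  jsonlite::write_json(list(n_neurons = nrow(r$counts),
                            n_frames = ncol(r$counts),
                            frame_duration = r$frame_duration,
                            dtype = "float32", order = "column-major"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = meta$n_neurons * meta$n_frames,
                  size = 4, endian = "little")
  raster(matrix(vals, meta$n_neurons, meta$n_frames), meta$frame_duration)
}

#' Hypnogram / trial-table / spindle CSV round trips
#'
#' @param x data.frame to write.
#' @param path file path.
#' @export
write_hypnogram <- function(x, path) {
  write.csv(x[, c("start_s", "end_s", "state")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_hypnogram
#' @export
write_trial_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_trial_table <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_hypnogram
#' @export
write_spindles <- function(x, path) {
  write.csv(as.data.frame(x)[, c("start_s", "end_s")], path,
            row.names = FALSE)
  invisible(path)
}
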