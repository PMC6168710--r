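#' Write / read the pipeline's trial container
#'
#' An epoch set is stored as one little-endian float64 tensor file
#' (`epochs.bin`, trial x channel x sample in column-major order) plus a
#' JSON sidecar (`epochs.json`) holding the dimensions, sampling rate,
#' labels, channel names, codebook and, when present, the generator
#' parameters and seed.
#'
#' @param ep An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or an `epoch_set` (read).
#' @export
write_epochs <- function(ep, dir) {
  stopifnot(inherits(ep, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeBin(as.numeric(ep$data), file.path(dir, "epochs.bin"),
           size = 8, endian = "little")
  params <- attr(ep, "params")
  meta <- list(dim = dim(ep$data), fs = ep$fs, labels = ep$labels,
               channel_labels = ep$channel_labels,
               codebook = if (!is.null(ep$codebook)) list(
                 session_id = attr(ep$codebook, "session_id"),
                 target_id = ep$codebook$target_id,
                 frequency = ep$codebook$frequency,
                 phase = ep$codebook$phase),
               params = if (!is.null(params)) unclass(params))
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  x <- readBin(file.path(dir, "epochs.bin"), "double", n = prod(d),
               size = 8, endian = "little")
  dim(x) <- d
  cb <- NULL
  if (!is.null(meta$codebook)) {
    cb <- data.frame(target_id = meta$codebook$target_id,
                     frequency = meta$codebook$frequency,
                     phase = meta$codebook$phase)
    attr(cb, "session_id") <- meta$codebook$session_id
    class(cb) <- c("session_codebook", "data.frame")
  }
  epoch_set(x, meta$labels, meta$fs, meta$channel_labels, cb)
}
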