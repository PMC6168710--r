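#' Stimulus codebooks for the six-target frequency/phase-tagged experiment
#'
#' Each of the four experimental sessions assigns every one of the six
#' on-screen targets a unique combination of flicker frequency (Hz) and
#' phase offset (radians). `make_codebook()` returns that assignment as a
#' data frame with one row per target.
#'
#' @param session_id Integer session number, 1 to 4.
#'
#' @return A `session_codebook`: a data frame with columns `target_id`
#'   (1..6), `frequency` (Hz) and `phase` (radians in `[0, 2*pi)`), and a
#'   `session_id` attribute.
#' @examples
#' make_codebook(2)
#' @export
make_codebook <- function(session_id) {
  if (!is.numeric(session_id) || length(session_id) != 1 || is.na(session_id) ||
      session_id != as.integer(session_id) || !(session_id %in% 1:4)) {
    stop("`session_id` must be a single integer in 1..4, got: ",
         deparse(substitute(session_id)), " = ", paste(session_id, collapse = ","))
  }
  freq <- switch(session_id,
    `1` = c(12, 14, 12, 14, 12, 14),
    `2` = c(13, 14, 13, 14, 13, 14),
    `3` = c(11, 15, 13, 13, 11, 15),
    `4` = c(13, 15, 14, 14, 13, 15)
  )
  phase <- switch(session_id,
    `1` = c(0, 2, 4, 4, 2, 0) * pi / 3,
    `2` = c(0, 2, 4, 4, 2, 0) * pi / 3,
    `3` = c(0, 1, 0, 1, 1, 0) * pi,
    `4` = c(0, 1, 0, 1, 1, 0) * pi
  )
  cb <- data.frame(target_id = 1:6, frequency = freq, phase = phase %% (2 * pi))
  attr(cb, "session_id") <- as.integer(session_id)
  class(cb) <- c("session_codebook", "data.frame")
  validate_codebook(cb)
  cb
}

validate_codebook <- function(cb) {
  stopifnot(is.data.frame(cb),
            all(c("target_id", "frequency", "phase") %in% names(cb)))
  if (nrow(cb) != 6) stop("a session codebook must have exactly six targets")
  if (any(cb$frequency <= 0)) stop("frequencies must be positive")
  if (any(cb$phase < 0 | cb$phase >= 2 * pi)) stop("phases must lie in [0, 2*pi)")
  key <- paste(cb$frequency, round(cb$phase, 12))
  if (anyDuplicated(key)) stop("(frequency, phase) pairs must be distinct within a session")
  invisible(cb)
}

#' @export
print.session_codebook <- function(x, ...) {
  cat("Session", attr(x, "session_id") %||% "?",
      "codebook (frequency Hz / phase rad):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
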