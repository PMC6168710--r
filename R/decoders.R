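#' Decoder specifications with a common fit/predict contract
#'
#' `decoder()` builds a specification for one of the three classifiers
#' ("naive", "fbcca", "stbf"), which [fit_decoder()] turns into a fitted
#' model; [predict_epochs()] classifies trials with any fitted model.
#' A custom decoder (e.g. a stub for testing) can be supplied as
#' `decoder("custom", fit = function(train) model)` where `model` has a
#' `predict_epochs()` method, or `fit` returns a list with a `predict`
#' function.
#'
#' @param name `"naive"`, `"fbcca"`, `"stbf"` or `"custom"`.
#' @param ... Arguments forwarded to the underlying `fit_*` function
#'   (e.g. `channel` for naive, `h`, `subbands`, `reference_only` for
#'   fbcca, `shrinkage` for stbf); for `"custom"`, a `fit` function.
#' @return An `ssvep_decoder` specification.
#' @export
decoder <- function(name = c("naive", "fbcca", "stbf", "custom"), ...) {
  name <- match.arg(name)
  args <- list(...)
  if (name == "custom" && !is.function(args$fit))
    stop('a "custom" decoder needs a `fit` function')
  structure(list(name = name, args = args), class = "ssvep_decoder")
}

#' @rdname decoder
#' @param spec An `ssvep_decoder` specification.
#' @param train Training [epoch_set()].
#' @export
fit_decoder <- function(spec, train) {
  stopifnot(inherits(spec, "ssvep_decoder"))
  switch(spec$name,
    naive  = do.call(fit_naive, c(list(train), spec$args)),
    fbcca  = do.call(fit_fbcca, c(list(train), spec$args)),
    stbf   = do.call(fit_stbf, c(list(train), spec$args)),
    custom = {
      m <- spec$args$fit(train)
      if (is.list(m) && is.function(m$predict) && !inherits(m, "ssvep_model"))
        class(m) <- c("custom_model", "ssvep_model", class(m))
      m
    })
}

#' @export
predict_epochs.custom_model <- function(model, ep, ...) model$predict(model, ep)

## Bands a decoder needs, for pre-filtering full-length epochs once.
decoder_bands <- function(spec) {
  switch(spec$name,
    naive = classifier_bands()["naive"],
    fbcca = spec$args$subbands %||% classifier_bands()[c("fbcca_sb1", "fbcca_sb2")],
    stbf  = classifier_bands()["stbf"],
    custom = list())
}

#' Serialize a fitted model to a JSON + binary-tensor bundle
#'
#' Writes `model.json` (structure, scalars, class) and one little-endian
#' float64 `.bin` file per numeric array into `dir`. [load_model()]
#' restores the model.
#'
#' @param model A fitted `ssvep_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tensors <- list()
  strip <- function(x, path) {
    if (is.numeric(x) && length(x) > 1) {
      key <- paste0("t", length(tensors) + 1)
      tensors[[key]] <<- x
      list(.tensor = key, dim = dim(x) %||% length(x),
           names = names(x) %||% NA)
    } else if (is.data.frame(x)) {
      lapply(as.list(x), function(col) strip(col, path))  # column-wise
    } else if (is.list(x)) {
      lapply(x, function(el) strip(el, path))
    } else x
  }
  skel <- strip(unclass(model), "")
  for (key in names(tensors))
    writeBin(as.numeric(tensors[[key]]),
             file.path(dir, paste0(key, ".bin")), size = 8, endian = "little")
  jsonlite::write_json(list(class = class(model), skeleton = skel),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  restore <- function(x) {
    if (is.list(x) && !is.null(x$.tensor)) {
      v <- readBin(file.path(dir, paste0(x$.tensor, ".bin")), "double",
                   n = prod(unlist(x$dim)), size = 8, endian = "little")
      d <- unlist(x$dim)
      if (length(d) > 1) dim(v) <- d
      nm <- unlist(x$names)
      if (!all(is.na(nm))) names(v) <- nm
      v
    } else if (is.list(x)) {
      lapply(x, restore)
    } else x
  }
  model <- restore(meta$skeleton)
  ## data-frame codebooks survive as lists of columns; rebuild them
  if (!is.null(model$codebook)) {
    model$codebook <- data.frame(lapply(model$codebook, unlist))
    class(model$codebook) <- c("session_codebook", "data.frame")
  }
  if (!is.null(model$band)) class(model$band) <- "band_spec"
  if (!is.null(model$subbands))
    model$subbands <- lapply(model$subbands, function(b) {
      class(b) <- "band_spec"; b
    })
  class(model) <- unlist(meta$class)
  model
}
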