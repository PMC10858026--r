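#' Multi-channel pseudoimage stacks
#'
#' An IMC pseudoimage stack is an H x W x C array of non-negative ion counts
#' at a fixed resolution of 1 pixel per square micrometre, channel-bound to a
#' marker panel. Stacks are exchanged as multi-page 16-bit OME-TIFF files,
#' one page per channel, values stored as raw dual counts.
#'
#' @name channel_stack
NULL

#' Construct a channel stack
#'
#' @param pixels H x W x C array (or H x W matrix for a single channel) of
#'   non-negative integer counts. Rows are y (micrometres), columns x.
#' @param panel An `imc_panel` with `C` channels.
#' @param sample_id Sample identifier.
#' @return An `imc_stack`: list with elements `pixels`, `panel`, `sample_id`,
#'   `pixel_area_um2` (always 1).
#' @export
channel_stack <- function(pixels, panel, sample_id = "sample") {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(length(dim(pixels)) == 3L)
  if (dim(pixels)[3L] != n_channels(panel)) {
    stop("stack has ", dim(pixels)[3L], " channels but panel has ",
         n_channels(panel), call. = FALSE)
  }
  if (any(pixels < 0)) stop("pixel counts must be non-negative", call. = FALSE)
  structure(list(pixels = pixels, panel = panel, sample_id = sample_id,
                 pixel_area_um2 = 1.0),
            class = "imc_stack")
}

#' Read a multi-page OME-TIFF stack
#'
#' Values are read exactly as stored (no rescaling or clipping). The page
#' count must equal the panel's channel count and the storage type must be
#' integer (16-bit unsigned as exported from the acquisition software).
#'
#' @param path Path to a multi-page TIFF.
#' @param panel An `imc_panel`.
#' @param sample_id Sample identifier; defaults to the file stem.
#' @return An `imc_stack`.
#' @export
read_stack <- function(path, panel,
                       sample_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("stack file does not exist: ", path,
                               call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != n_channels(panel)) {
    stop("stack ", path, " has ", length(pages), " pages but panel has ",
         n_channels(panel), " channels", call. = FALSE)
  }
  if (!all(vapply(pages, is.integer, logical(1))) ||
      any(vapply(pages, function(p) any(p < 0L), logical(1)))) {
    stop("stack ", path, " has a non-integer (or non-unsigned) pixel type; ",
         "expected unsigned 16-bit counts", call. = FALSE)
  }
  pixels <- array(0L, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) pixels[, , k] <- pages[[k]]
  channel_stack(pixels, panel, sample_id)
}

#' Write a stack as a multi-page 16-bit TIFF
#'
#' Counts above the 16-bit range (65535) are clipped at write time with a
#' warning, matching the 16-bit export convention.
#'
#' @param stack An `imc_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  if (any(px > 65535)) {
    warning("clipping ", sum(px > 65535), " pixel(s) above 65535 to 16-bit",
            call. = FALSE)
    px[px > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(px)[3L]),
                  function(k) px[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Extract one channel plane by marker name or index
#'
#' @param stack An `imc_stack`.
#' @param marker Marker name (as in the panel) or 1-based channel index.
#' @return H x W matrix of counts.
#' @export
channel_plane <- function(stack, marker) {
  i <- if (is.character(marker)) marker_index(stack$panel, marker)
       else as.integer(marker)
  stack$pixels[, , i]
}

#' @export
print.imc_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("IMC stack '%s': %d x %d px (1 um^2/px), %d channels\n",
              x$sample_id, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' @export
dim.imc_stack <- function(x) dim(x$pixels)
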