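#' Marker panel handling
#'
#' A panel binds the pages of a multi-channel IMC pseudoimage stack to
#' biological markers: each row names a marker, its metal isotope tag, its
#' 0-based page index in the exported OME-TIFF, and a coarse target class.
#'
#' @name panel
NULL

.target_classes <- c("fiber_marker", "ecm", "cell_marker", "cytokine",
                     "nuclei", "vessel", "fat")

#' Load and validate a marker panel
#'
#' Reads a panel CSV with columns `marker_name`, `metal_tag`, `channel_index`
#' (0-based, contiguous) and `target_class`, and validates its invariants:
#' unique metal tags, unique and contiguous channel indices, unambiguous
#' marker names, and exactly one `nuclei` entry.
#'
#' @param path Path to a panel CSV. The default is the panel shipped with the
#'   package (16 antibodies plus an iridium DNA intercalator channel, as used
#'   for dystrophic muscle sections).
#' @return An object of class `imc_panel`: a data.frame with the four panel
#'   columns, rows ordered by `channel_index`, plus attribute `n_channels`.
#' @examples
#' p <- load_panel()
#' n_channels(p)
#' @export
load_panel <- function(path = default_panel_path()) {
  if (!file.exists(path)) {
    stop("panel file does not exist: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("marker_name", "metal_tag", "channel_index", "target_class")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("panel file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_panel(tab[required])
}

#' @rdname load_panel
#' @param markers A data.frame with the four panel columns (e.g. built in
#'   code rather than read from disk).
#' @export
as_panel <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (nrow(markers) == 0L) stop("panel has no markers", call. = FALSE)
  dup_tag <- unique(markers$metal_tag[duplicated(markers$metal_tag)])
  if (length(dup_tag)) {
    stop("duplicate metal tag: ", paste(dup_tag, collapse = ", "),
         call. = FALSE)
  }
  dup_name <- unique(markers$marker_name[duplicated(markers$marker_name)])
  if (length(dup_name)) {
    stop("duplicate marker name: ", paste(dup_name, collapse = ", "),
         call. = FALSE)
  }
  idx <- as.integer(markers$channel_index)
  if (anyNA(idx) || !setequal(idx, seq_len(nrow(markers)) - 1L)) {
    stop("channel_index must be 0-based, unique and contiguous 0..",
         nrow(markers) - 1L, call. = FALSE)
  }
  bad_class <- setdiff(unique(markers$target_class), .target_classes)
  if (length(bad_class)) {
    stop("unknown target_class: ", paste(bad_class, collapse = ", "),
         "; expected one of ", paste(.target_classes, collapse = ", "),
         call. = FALSE)
  }
  n_nuc <- sum(markers$target_class == "nuclei")
  if (n_nuc != 1L) {
    stop("panel must contain exactly one nuclei entry (found ", n_nuc, ")",
         call. = FALSE)
  }
  markers <- markers[order(idx), , drop = FALSE]
  markers$channel_index <- sort(idx)
  rownames(markers) <- NULL
  structure(markers, class = c("imc_panel", "data.frame"))
}

#' @rdname load_panel
#' @export
default_panel_path <- function() {
  system.file("extdata", "panel_default.csv", package = "imcmyo",
              mustWork = TRUE)
}

#' @rdname load_panel
#' @param panel An `imc_panel`.
#' @export
n_channels <- function(panel) nrow(panel)

#' Look up a marker's channel index
#'
#' @param panel An `imc_panel`.
#' @param marker_name Marker name as in the panel.
#' @return The 1-based row/page index of the marker (for indexing the third
#'   dimension of a stack's pixel array).
#' @export
marker_index <- function(panel, marker_name) {
  i <- match(marker_name, panel$marker_name)
  if (anyNA(i)) {
    stop("marker not in panel: ",
         paste(marker_name[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Name of the nuclei channel in a panel
#' @param panel An `imc_panel`.
#' @export
nuclei_marker <- function(panel) {
  panel$marker_name[panel$target_class == "nuclei"][1L]
}

#' @export
print.imc_panel <- function(x, ...) {
  cat("IMC marker panel:", nrow(x), "channels\n")
  print.data.frame(x, ...)
  invisible(x)
}
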