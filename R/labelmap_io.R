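# Label maps persist as an integer NIfTI plus a JSON sidecar holding the
# structure descriptors (name, color, transparency, priority).

#' Write a label map to NIfTI + JSON sidecar
#'
#' @param labelmap a [label_map()].
#' @param path NIfTI path (`.nii`/`.nii.gz`); the sidecar is written next to
#'   it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "label_map"))
  vol <- image_volume(labelmap$labels + 0, spacing = labelmap$spacing,
                      origin = labelmap$origin, direction = labelmap$direction)
  write_volume(vol, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(labelmap$structures, side, digits = NA)
  invisible(path)
}

#' Read a label map from NIfTI + JSON sidecar
#'
#' @param path NIfTI path written by [write_label_map()].
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  vol <- read_volume(path, "nifti")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side))
    stop(sprintf("missing structure sidecar: %s", side), call. = FALSE)
  structures <- jsonlite::fromJSON(side)
  label_map(round(vol$data), structures, spacing = vol$spacing,
            origin = vol$origin, direction = vol$direction)
}
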