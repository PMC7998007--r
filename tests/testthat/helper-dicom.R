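# Synthetic DICOM writer (Explicit VR Little Endian, single-frame) used to
# build series fixtures in code at test time.

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.elem_short <- function(grp, ele, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
  c(.u16raw(grp), .u16raw(ele), charToRaw(vr), .u16raw(length(value_raw)),
    value_raw)
}

.elem_long <- function(grp, ele, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  c(.u16raw(grp), .u16raw(ele), charToRaw(vr), as.raw(c(0, 0)),
    .u32raw(length(value_raw)), value_raw)
}

.ds_raw <- function(x) charToRaw(paste(sprintf("%g", x), collapse = "\\"))

# `slice`: integer matrix indexed [x, y] (x = column index, fastest in the
# pixel stream); position = ImagePositionPatient (mm).
write_test_dicom <- function(path, slice, position,
                             orientation = c(1, 0, 0, 0, 1, 0),
                             pixel_spacing = c(1, 1),
                             series_uid = "1.2.3.4") {
  nx <- nrow(slice); ny <- ncol(slice)
  # pixel stream: rows (y) outer, columns (x) inner -> as.integer(slice) is
  # already x-fastest, which matches
  px_raw <- writeBin(as.integer(slice), raw(), size = 2, endian = "little")
  meta <- .elem_short(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1"))
  body <- c(
    .elem_short(0x0020, 0x000E, "UI", charToRaw(series_uid)),
    .elem_short(0x0020, 0x0032, "DS", .ds_raw(position)),
    .elem_short(0x0020, 0x0037, "DS", .ds_raw(orientation)),
    .elem_short(0x0028, 0x0010, "US", .u16raw(ny)),   # Rows
    .elem_short(0x0028, 0x0011, "US", .u16raw(nx)),   # Columns
    .elem_short(0x0028, 0x0030, "DS",
                .ds_raw(c(pixel_spacing[2], pixel_spacing[1]))),
    .elem_short(0x0028, 0x0100, "US", .u16raw(16)),
    .elem_short(0x0028, 0x0103, "US", .u16raw(0)),
    .elem_long(0x7FE0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# write a z-stack of slices as one file per slice
write_test_dicom_series <- function(dir, vol3d, z_positions,
                                    series_uid = "1.2.3.4",
                                    file_order = seq_along(z_positions)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (idx in seq_along(file_order)) {
    k <- file_order[idx]
    write_test_dicom(file.path(dir, sprintf("im%02d.dcm", idx)),
                     vol3d[, , k], position = c(0, 0, z_positions[k]),
                     series_uid = series_uid)
  }
  invisible(dir)
}
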