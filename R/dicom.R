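# Minimal DICOM series reader: uncompressed single-frame files, Explicit or
# Implicit VR Little Endian. Only the tags needed to reconstruct geometry and
# intensities are interpreted; everything else is skipped by length.

.dcm_ts_implicit <- "1.2.840.10008.1.2"
.dcm_ts_explicit <- "1.2.840.10008.1.2.1"

.dcm_u16 <- function(raw) readBin(raw, "integer", n = length(raw) / 2, size = 2,
                                  signed = FALSE, endian = "little")
.dcm_u32 <- function(raw) readBin(raw, "integer", n = 1, size = 4,
                                  endian = "little")
.dcm_ds <- function(raw) as.numeric(strsplit(trimws(rawToChar(raw)), "\\\\")[[1]])
.dcm_str <- function(raw) {
  s <- rawToChar(raw[raw != as.raw(0)])
  trimws(s)
}

# Parse one DICOM file into a named list of raw values for the tags we use.
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("format error: not a DICOM part-10 file: %s", path), call. = FALSE)
  pos <- 133L
  wanted <- c("00020010", "0008103e", "0020000e", "00200032", "00200037",
              "00280010", "00280011", "00280030", "00280100", "00280103",
              "00281052", "00281053", "7fe00010")
  out <- list()
  explicit <- TRUE   # file meta group is always explicit VR LE
  ts <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(bytes)
  while (pos + 7L <= n) {
    grp <- .dcm_u16(bytes[pos:(pos + 1L)])
    ele <- .dcm_u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (grp > 2L && is.null(ts)) {
      # leaving file meta: switch to the negotiated transfer syntax
      ts <- .dcm_ts_explicit
    }
    use_explicit <- if (grp == 2L) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- .dcm_u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- .dcm_u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      len <- .dcm_u32(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len < 0 || pos + len - 1L > n)
      stop(sprintf("format error: truncated DICOM element in %s", path), call. = FALSE)
    key <- sprintf("%04x%04x", grp, ele)
    if (key %in% wanted)
      out[[key]] <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    if (key == "00020010") {
      tsv <- .dcm_str(out[[key]])
      if (tsv == .dcm_ts_implicit) explicit <- FALSE
      else if (tsv == .dcm_ts_explicit) explicit <- TRUE
      else stop(sprintf("format error: unsupported transfer syntax %s", tsv),
                call. = FALSE)
      ts <- tsv
    }
    pos <- pos + len
  }
  out
}

# Read a directory of DICOM files belonging to one series into an image_volume.
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop("format error: no files in DICOM directory", call. = FALSE)
  parsed <- lapply(files, parse_dicom_file)

  need <- c("00200032", "00200037", "00280010", "00280011", "00280030", "7fe00010")
  for (i in seq_along(parsed))
    if (!all(need %in% names(parsed[[i]])))
      stop(sprintf("format error: %s lacks required image tags", files[i]),
           call. = FALSE)

  uid <- vapply(parsed, function(p)
    if (is.null(p[["0020000e"]])) "" else .dcm_str(p[["0020000e"]]), "")
  if (length(unique(uid)) > 1L)
    stop("format error: files belong to more than one series", call. = FALSE)

  rows <- vapply(parsed, function(p) .dcm_u16(p[["00280010"]]), 0L)
  cols <- vapply(parsed, function(p) .dcm_u16(p[["00280011"]]), 0L)
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    stop("format error: heterogeneous slice dimensions in series", call. = FALSE)

  iop <- .dcm_ds(parsed[[1]][["00200037"]])
  for (p in parsed)
    if (max(abs(.dcm_ds(p[["00200037"]]) - iop)) > 1e-6)
      stop("format error: heterogeneous slice orientation in series", call. = FALSE)
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  ipp <- t(vapply(parsed, function(p) .dcm_ds(p[["00200032"]]), numeric(3)))
  zpos <- as.numeric(ipp %*% normal)
  ord <- order(zpos)
  parsed <- parsed[ord]; ipp <- ipp[ord, , drop = FALSE]; zpos <- zpos[ord]

  ps <- .dcm_ds(parsed[[1]][["00280030"]])     # (between rows, between columns)
  spacing_xy <- c(ps[2], ps[1])

  nz <- length(parsed)
  if (nz >= 2) {
    gaps <- diff(zpos)
    if (any(gaps <= 0))
      stop("geometry error: duplicate slice positions in series", call. = FALSE)
    if (max(gaps) - min(gaps) > 1e-3)
      stop("geometry error: non-uniform inter-slice spacing", call. = FALSE)
    dz <- mean(gaps)
  } else {
    dz <- 1.0
  }

  nx <- cols[1]; ny <- rows[1]
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    p <- parsed[[k]]
    bits <- if (!is.null(p[["00280100"]])) .dcm_u16(p[["00280100"]]) else 16L
    signed <- !is.null(p[["00280103"]]) && .dcm_u16(p[["00280103"]]) == 1L
    raw_px <- p[["7fe00010"]]
    px <- if (bits == 16L) {
      readBin(raw_px, "integer", n = length(raw_px) / 2, size = 2,
              signed = signed, endian = "little")
    } else if (bits == 8L) {
      readBin(raw_px, "integer", n = length(raw_px), size = 1, signed = signed)
    } else stop("format error: unsupported BitsAllocated", call. = FALSE)
    if (length(px) != nx * ny)
      stop("format error: pixel data size mismatch", call. = FALSE)
    slope <- if (!is.null(p[["00281053"]])) .dcm_ds(p[["00281053"]]) else 1
    inter <- if (!is.null(p[["00281052"]])) .dcm_ds(p[["00281052"]]) else 0
    arr[, , k] <- matrix(px * slope + inter, nrow = nx)   # x fastest within a row
  }

  image_volume(arr, spacing = c(spacing_xy, dz), origin = ipp[1, ],
               direction = cbind(row_dir, col_dir, normal))
}
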