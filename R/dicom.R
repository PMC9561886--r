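# Minimal DICOM support: explicit-VR little-endian, single-frame MR slices.
# Covers what the phantom exporter emits and what the tests read back; real
# scanner archives in other transfer syntaxes are rejected loudly rather than
# misparsed.

.dcm_uid_root <- "1.2.826.0.1.3680043.8.498."  # pydicom's public test root

.dcm_even <- function(raw, pad = as.raw(0L)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

.dcm_element <- function(group, elem, vr, value_raw) {
  value_raw <- .dcm_even(value_raw,
                         pad = if (vr %in% c("UI", "OB")) as.raw(0L)
                               else charToRaw(" "))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

.dcm_str <- function(group, elem, vr, s) .dcm_element(group, elem, vr, charToRaw(s))
.dcm_us <- function(group, elem, v)
  .dcm_element(group, elem, "US", writeBin(as.integer(v), raw(), size = 2,
                                           endian = "little"))
.dcm_ds <- function(group, elem, v)
  .dcm_str(group, elem, "DS", paste(sprintf("%.10g", v), collapse = "\\"))

.dcm_new_uid <- function(seed_chunk) {
  paste0(.dcm_uid_root, seed_chunk)
}

#' Quantize intensities onto a 16-bit DICOM-representable grid
#'
#' DICOM stores 16-bit integers plus a rescale slope/intercept; exporting a
#' floating-point volume is therefore lossy unless the volume is first snapped
#' to the stored grid. `slope` defaults to 2^-10 (exactly representable as a
#' short decimal string) so a quantized volume survives a DICOM round trip
#' bit-faithfully.
#'
#' @param vol an [volume()].
#' @param slope,intercept rescale parameters; stored value k satisfies
#'   `v = intercept + k * slope`, k in 0..65535.
#' @return a [volume()] on the quantized grid.
#' @export
quantize_intensities <- function(vol, slope = 2^-10, intercept = -16) {
  k <- round((vol$data - intercept) / slope)
  if (any(k < 0) || any(k > 65535))
    stop("intensities outside the representable range for this slope/intercept")
  volume(intercept + k * slope, vol$geometry)
}

#' Write a volume as a DICOM series (one file per slice)
#'
#' Explicit-VR little-endian, MR SOP class, with geometry carried in
#' ImagePositionPatient / ImageOrientationPatient / PixelSpacing. Intended for
#' phantom export and round-trip testing; apply [quantize_intensities()] first
#' if bit-faithful reading matters.
#'
#' @param vol an [volume()]; intensities must fall on the slope/intercept grid
#'   within the 16-bit range.
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale parameters used to encode intensities.
#' @param shuffle_names if TRUE, write files under position-scrambled names
#'   (testing aid: readers must sort spatially, not lexically).
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(vol, dir, slope = 2^-10, intercept = -16,
                               shuffle_names = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- vol$geometry
  d <- dim(vol$data)
  series_uid <- .dcm_new_uid(paste0(sample.int(1e8, 1), ".1"))
  study_uid <- .dcm_new_uid(paste0(sample.int(1e8, 1), ".2"))
  iop <- c(g$orientation[, 1], g$orientation[, 2])
  name_order <- if (shuffle_names) sample.int(d[3]) else seq_len(d[3])
  for (z in seq_len(d[3])) {
    sl <- vol$data[, , z]
    k <- round((sl - intercept) / slope)
    if (any(k < 0) || any(k > 65535)) stop("intensity outside 16-bit range")
    ipp <- voxel_to_physical(g, c(0, 0, z - 1))
    sop_uid <- .dcm_new_uid(paste0(sample.int(1e8, 1), ".3.", z))
    body <- c(
      .dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.4"),
      .dcm_str(0x0008, 0x0018, "UI", sop_uid),
      .dcm_str(0x0008, 0x0060, "CS", "MR"),
      .dcm_str(0x0010, 0x0010, "PN", "PHANTOM"),
      .dcm_str(0x0010, 0x0020, "LO", "SYNTHETIC"),
      .dcm_ds(0x0018, 0x0050, g$spacing[3]),
      .dcm_str(0x0020, 0x000D, "UI", study_uid),
      .dcm_str(0x0020, 0x000E, "UI", series_uid),
      .dcm_str(0x0020, 0x0013, "IS", as.character(z)),
      .dcm_ds(0x0020, 0x0032, ipp),
      .dcm_ds(0x0020, 0x0037, iop),
      .dcm_us(0x0028, 0x0002, 1),
      .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_us(0x0028, 0x0010, d[2]),  # Rows = y
      .dcm_us(0x0028, 0x0011, d[1]),  # Columns = x
      .dcm_ds(0x0028, 0x0030, c(g$spacing[2], g$spacing[1])),
      .dcm_us(0x0028, 0x0100, 16),
      .dcm_us(0x0028, 0x0101, 16),
      .dcm_us(0x0028, 0x0102, 15),
      .dcm_us(0x0028, 0x0103, 0),
      .dcm_ds(0x0028, 0x1052, intercept),
      .dcm_ds(0x0028, 0x1053, slope),
      .dcm_element(0x7FE0, 0x0010, "OW",
                   writeBin(as.integer(k), raw(), size = 2, endian = "little"))
    )
    meta_elems <- c(
      .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4"),
      .dcm_str(0x0002, 0x0003, "UI", sop_uid),
      .dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    meta <- c(.dcm_element(0x0002, 0x0000, "UL",
                           writeBin(length(meta_elems), raw(), size = 4,
                                    endian = "little")),
              meta_elems)
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", name_order[z])), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

# Parse one explicit-VR little-endian file into a tag -> value list.
.dcm_parse <- function(path) {
  raw <- readBin(path, raw(), file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  out <- list()
  u16 <- function(i) readBin(raw[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    value <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr, value = value)
    pos <- vstart + len
  }
  out
}

.dcm_chr <- function(el) {
  v <- el$value
  while (length(v) > 0 && v[length(v)] == as.raw(0L)) v <- v[-length(v)]
  sub(" +$", "", rawToChar(v))
}
.dcm_num <- function(el) as.numeric(strsplit(.dcm_chr(el), "\\\\")[[1]])
.dcm_u16 <- function(el) readBin(el$value, "integer", size = 2,
                                 endian = "little", signed = FALSE)

#' Read a DICOM series directory as a volume
#'
#' All files in the directory must belong to one series (one SeriesInstanceUID)
#' in the explicit-VR little-endian transfer syntax. Slices are sorted by their
#' position projected onto the slice normal; slice spacing must be uniform
#' within 1e-3 mm.
#'
#' @param dir directory containing the series.
#' @return an [volume()] in the internal LPS frame.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("empty DICOM directory: ", dir)
  slices <- lapply(files, .dcm_parse)
  ts <- vapply(slices, function(s) .dcm_chr(s[["0002,0010"]]), "")
  if (any(ts != "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax: ", ts[ts != "1.2.840.10008.1.2.1"][1])
  uid <- vapply(slices, function(s) .dcm_chr(s[["0020,000e"]]), "")
  if (length(unique(uid)) != 1)
    stop("directory contains ", length(unique(uid)), " distinct series")
  iop <- .dcm_num(slices[[1]][["0020,0037"]])
  cx <- iop[1:3]; cy <- iop[4:6]
  normal <- c(cx[2] * cy[3] - cx[3] * cy[2],
              cx[3] * cy[1] - cx[1] * cy[3],
              cx[1] * cy[2] - cx[2] * cy[1])
  ipp <- t(vapply(slices, function(s) .dcm_num(s[["0020,0032"]]), numeric(3)))
  proj <- drop(ipp %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]; proj <- proj[ord]
  nz <- length(slices)
  ps <- .dcm_num(slices[[1]][["0028,0030"]])  # (row, col) = (y, x)
  rows <- .dcm_u16(slices[[1]][["0028,0010"]])
  cols <- .dcm_u16(slices[[1]][["0028,0011"]])
  if (nz > 1) {
    steps <- diff(proj)
    if (max(steps) - min(steps) > 1e-3)
      stop("non-uniform slice spacing (corrupt series?)")
    dz <- mean(steps)
    zdir <- (ipp[2, ] - ipp[1, ]) / dz
  } else {
    dz <- .dcm_num(slices[[1]][["0018,0050"]])
    zdir <- normal
  }
  dat <- array(0, c(cols, rows, nz))
  for (z in seq_len(nz)) {
    s <- slices[[z]]
    slope <- .dcm_num(s[["0028,1053"]]); icpt <- .dcm_num(s[["0028,1052"]])
    k <- readBin(s[["7fe0,0010"]]$value, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = FALSE)
    dat[, , z] <- array(icpt + k * slope, c(cols, rows))
  }
  geom <- geometry(spacing = c(ps[2], ps[1], abs(dz)), origin = ipp[1, ],
                   orientation = cbind(cx, cy, zdir, deparse.level = 0))
  volume(dat, geom)
}
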