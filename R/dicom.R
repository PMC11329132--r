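# Minimal DICOM series support: Explicit VR Little Endian only, geometry +
# pixel module subset (enough for axial CT slice stacks). Not a general
# DICOM implementation; unknown elements are skipped on read, and writing
# emits exactly the elements below.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

int_le <- function(x, size) writeBin(as.integer(x), raw(0), size = size, endian = "little")

dcm_pad <- function(payload, pad_byte) {
  if (length(payload) %% 2L == 1L) c(payload, pad_byte) else payload
}

dcm_element <- function(group, element, vr, payload) {
  payload <- dcm_pad(payload, if (vr == "UI") as.raw(0L) else as.raw(0x20))
  hdr <- c(int_le(group, 2), int_le(element, 2), charToRaw(vr))
  if (vr %in% LONG_VRS)
    c(hdr, as.raw(c(0L, 0L)), int_le(length(payload), 4), payload)
  else
    c(hdr, int_le(length(payload), 2), payload)
}

dcm_str <- function(group, element, vr, s) dcm_element(group, element, vr, charToRaw(s))
dcm_us  <- function(group, element, x) dcm_element(group, element, "US", int_le(x, 2))
dcm_ds  <- function(group, element, x)
  dcm_str(group, element, "DS", paste(formatC(x, format = "fg", digits = 10), collapse = "\\"))

# Deterministic UID under the 2.25 (UUID-derived) root.
make_uid <- function(...) {
  h <- 0
  for (v in utf8ToInt(paste(..., sep = "/"))) h <- (h * 293 + v) %% 1e14
  paste0("2.25.", sprintf("%.0f", h))
}

write_dicom_slice <- function(path, pixels, z_mm, instance, thickness, interval,
                              pixel_spacing, intercept, series_uid, study_uid) {
  sop_uid <- make_uid(series_uid, instance)
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", DICOM_SOP_CT),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", int_le(length(meta), 4)), meta)
  pix <- as.integer(t(pixels))           # DICOM pixel data is row-major
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", DICOM_SOP_CT),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_ds(0x0018, 0x0050, thickness),
    dcm_ds(0x0018, 0x0088, interval),
    dcm_str(0x0020, 0x000D, "UI", study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_ds(0x0020, 0x0032, c(0, 0, z_mm)),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(pixels)),
    dcm_us(0x0028, 0x0011, ncol(pixels)),
    dcm_ds(0x0028, 0x0030, pixel_spacing),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 12L),
    dcm_us(0x0028, 0x0102, 11L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_ds(0x0028, 0x1052, intercept),
    dcm_ds(0x0028, 0x1053, 1),
    dcm_element(0x7FE0, 0x0010, "OW", int_le(pix, 2)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
}

write_volume_dicom <- function(volume, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_slices(volume)
  series_uid <- make_uid("series", volume$source, n)
  study_uid <- make_uid("study", volume$source)
  for (i in seq_len(n)) {
    write_dicom_slice(file.path(dir, sprintf("slice_%04d.dcm", i)),
                      get_slice(volume, i), z_mm = (i - 1) * volume$interval,
                      instance = i, thickness = volume$thickness,
                      interval = volume$interval,
                      pixel_spacing = volume$pixel_spacing,
                      intercept = volume$intercept,
                      series_uid = series_uid, study_uid = study_uid)
  }
  invisible(dir)
}

read_u16 <- function(bytes) readBin(bytes, "integer", n = length(bytes) / 2,
                                    size = 2, signed = FALSE, endian = "little")

parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stopf("%s is not a DICOM part-10 file", path)
  pos <- 133L
  out <- list()
  n <- length(bytes)
  while (pos + 8L <= n + 1L) {
    group <- read_u16(bytes[pos:(pos + 1L)])
    element <- read_u16(bytes[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 12L
    } else {
      len <- read_u16(bytes[(pos + 6L):(pos + 7L)])
      pos <- pos + 8L
    }
    payload <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- switch(vr,
      US = read_u16(payload),
      UL = readBin(payload, "integer", size = 4, endian = "little"),
      OW = read_u16(payload),
      OB = payload,
      {
        while (length(payload) &&
               payload[length(payload)] %in% as.raw(c(0x00, 0x20)))
          payload <- payload[-length(payload)]
        s <- rawToChar(payload)
        if (vr %in% c("DS", "IS")) as.numeric(strsplit(s, "\\\\", fixed = FALSE)[[1]])
        else s
      })
    if (key == "0002,0010" && out[[key]] != DICOM_TS_EXPLICIT_LE)
      stopf("unsupported transfer syntax %s in %s", out[[key]], path)
  }
  out
}

dcm_req <- function(el, key, what, path) {
  if (is.null(el[[key]])) stopf("DICOM file %s lacks %s (%s)", path, what, key)
  el[[key]]
}

read_volume_dicom <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stopf("no DICOM files in %s", dir)
  parsed <- lapply(files, parse_dicom_file)
  geom <- function(p, f) list(
    rows = dcm_req(p, "0028,0010", "Rows", f),
    cols = dcm_req(p, "0028,0011", "Columns", f),
    spacing = dcm_req(p, "0028,0030", "PixelSpacing", f),
    thickness = dcm_req(p, "0018,0050", "SliceThickness", f),
    interval = dcm_req(p, "0018,0088", "SpacingBetweenSlices", f),
    z = dcm_req(p, "0020,0032", "ImagePositionPatient", f)[3],
    series = dcm_req(p, "0020,000E", "SeriesInstanceUID", f))
  gs <- Map(geom, parsed, files)
  ref <- gs[[1]]
  for (g in gs) {
    if (g$rows != ref$rows || g$cols != ref$cols ||
        any(abs(g$spacing - ref$spacing) > 1e-9))
      stopf("mixed in-plane geometry within DICOM series in %s", dir)
    if (!identical(g$series, ref$series))
      stopf("multiple series identities within %s", dir)
  }
  ord <- order(vapply(gs, `[[`, numeric(1), "z"))
  vox <- array(0L, dim = c(length(files), ref$rows, ref$cols))
  for (i in seq_along(ord)) {
    p <- parsed[[ord[i]]]
    pix <- dcm_req(p, "7FE0,0010", "PixelData", files[[ord[i]]])
    vox[i, , ] <- matrix(pix, nrow = ref$rows, ncol = ref$cols, byrow = TRUE)
  }
  intercept <- parsed[[1]][["0028,1052"]] %||% -1024
  ct_volume(clip(vox, 0, 4095), thickness = ref$thickness,
            interval = ref$interval, pixel_spacing = ref$spacing,
            intercept = intercept, source = dir)
}
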