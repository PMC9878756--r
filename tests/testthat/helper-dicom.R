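# Byte-level DICOM writer for test fixtures, independent of the package's
# reader. Writes single-frame monochrome files in explicit or implicit VR
# little endian (the file meta group is always explicit, per the standard).

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dicom_element <- function(group, elem, vr, value, explicit = TRUE) {
  if (length(value) %% 2 == 1) {
    # even-length padding: NUL for UI, space for text VRs
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    value <- c(value, pad)
  }
  head <- c(u16le(group), u16le(elem))
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (explicit) {
    if (vr %in% long_vrs) {
      c(head, charToRaw(vr), as.raw(c(0, 0)), u32le(length(value)), value)
    } else {
      c(head, charToRaw(vr), u16le(length(value)), value)
    }
  } else {
    c(head, u32le(length(value)), value)
  }
}

write_test_dicom <- function(path, pixels, spacing_mm = c(0.2, 0.2),
                             bits = 8L, explicit = TRUE) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  # pixel data row by row
  vals <- as.integer(t(pixels))
  pd <- if (bits <= 8) {
    as.raw(vals)
  } else {
    as.raw(as.vector(rbind(vals %% 256, vals %/% 256)))
  }
  if (length(pd) %% 2 == 1) pd <- c(pd, as.raw(0))
  meta <- dicom_element(0x0002, 0x0010, "UI", charToRaw(ts), explicit = TRUE)
  body <- c(
    dicom_element(0x0028, 0x0010, "US", u16le(rows), explicit),
    dicom_element(0x0028, 0x0011, "US", u16le(cols), explicit),
    dicom_element(0x0028, 0x0030, "DS",
                  charToRaw(paste(spacing_mm, collapse = "\\")), explicit),
    dicom_element(0x0028, 0x0100, "US", u16le(bits), explicit),
    dicom_element(0x7fe0, 0x0010, "OW", pd, explicit)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
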