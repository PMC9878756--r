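# Image and report I/O. PNG images carry no physical spacing, so it must be
# supplied by the caller; DICOM files carry PixelSpacing (mm per pixel, row
# spacing first) which is converted to cm. The DICOM reader below is a
# minimal parser for uncompressed single-frame monochrome files in the
# implicit or explicit little-endian transfer syntaxes -- the subset
# portable chest films are stored in.

#' Read a radiograph from PNG or DICOM
#'
#' @param path Path to a `.png` or `.dcm`/`.dicom` file.
#' @param spacing_row,spacing_col Pixel spacing in cm/px. Required for PNG
#'   (PNG has no spacing metadata); ignored for DICOM, where the
#'   PixelSpacing attribute is used.
#' @param image_id Identifier; defaults to the file name.
#' @return A [radiograph()] with intensities on the 0..255 scale for 8-bit
#'   input (16-bit DICOM keeps its native scale).
#' @export
read_image <- function(path, spacing_row = NULL, spacing_col = spacing_row,
                       image_id = basename(path)) {
  assert_that(file.exists(path), "io", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (is.null(spacing_row)) {
      stop_ett("missing_spacing",
               "PNG images carry no pixel spacing: supply spacing_row (cm/px) or use --spacing on the command line")
    }
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    radiograph(px * 255, spacing_row, spacing_col, image_id)
  } else if (ext %in% c("dcm", "dicom")) {
    read_dicom(path, image_id = image_id)
  } else {
    stop_ett("io", sprintf("unsupported image format: .%s", ext))
  }
}

#' Minimal DICOM reader
#'
#' Parses uncompressed single-frame monochrome DICOM (implicit or explicit
#' VR, little endian), extracting Rows, Columns, BitsAllocated,
#' PixelSpacing and PixelData. PixelSpacing is a DS pair "row\\col" in mm
#' and is converted to cm.
#'
#' @param path File path.
#' @param image_id Identifier.
#' @return A [radiograph()].
#' @export
read_dicom <- function(path, image_id = basename(path)) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  assert_that(length(raw) > 132 && rawToChar(raw[129:132]) == "DICM",
              "io", "not a DICOM file (missing DICM magic)")
  u16 <- function(pos) as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])
  u32 <- function(pos) {
    as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1]) +
      65536 * as.numeric(raw[pos + 2]) + 16777216 * as.numeric(raw[pos + 3])
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  pos <- 133
  explicit <- TRUE  # file meta group is always explicit little endian
  transfer_syntax <- NULL
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2)
    if (!is.null(transfer_syntax) && group != 0x0002) {
      # leaving the meta group: switch syntax for the main dataset
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      transfer_syntax <- NULL
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); hdr <- 12L
      } else {
        len <- u16(pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4); hdr <- 8L
    }
    assert_that(len != 4294967295, "io",
                "undefined-length DICOM elements (sequences/compressed pixel data) are not supported")
    start <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0002,0010", "0028,0010", "0028,0011", "0028,0030",
                   "0028,0100", "7fe0,0010")) {
      tags[[key]] <- raw[start:(start + len - 1)]
    }
    if (key == "0002,0010") {
      v <- tags[[key]]
      transfer_syntax <- trimws(rawToChar(v[v != as.raw(0)]))
    }
    pos <- start + len
  }
  need <- c("0028,0010", "0028,0011", "0028,0030", "7fe0,0010")
  missing_tags <- setdiff(need, names(tags))
  assert_that(length(missing_tags) == 0, "io",
              sprintf("DICOM missing required elements: %s",
                      paste(missing_tags, collapse = ", ")))
  us <- function(key) as.integer(tags[[key]][1]) + 256L * as.integer(tags[[key]][2])
  rows <- us("0028,0010"); cols <- us("0028,0011")
  bits <- if ("0028,0100" %in% names(tags)) us("0028,0100") else 16L
  sp <- strsplit(rawToChar(tags[["0028,0030"]]), "\\\\")[[1]]
  spacing_mm <- as.numeric(trimws(sp))
  assert_that(length(spacing_mm) == 2 && all(spacing_mm > 0), "io",
              "invalid PixelSpacing attribute")
  pd <- tags[["7fe0,0010"]]
  vals <- if (bits <= 8) {
    as.integer(pd[seq_len(rows * cols)])
  } else {
    idx <- seq_len(rows * cols)
    as.integer(pd[2 * idx - 1]) + 256L * as.integer(pd[2 * idx])
  }
  # DICOM pixel data is stored row by row
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  radiograph(m, spacing_row = spacing_mm[1] / 10,
             spacing_col = spacing_mm[2] / 10, image_id = image_id)
}

#' Assemble a run report
#'
#' The report captures everything needed to audit or re-run one
#' assessment: the paired prediction, the calibrated uncertainty, the
#' placement call, and a trust flag that is lowered whenever the
#' uncertainty exceeds a configurable ceiling (by default 2 cm -- at the
#' standard threshold an uncertainty that large forces every call to
#' too_low, so the numeric result carries no information).
#'
#' @param prediction A `paired_prediction`.
#' @param uncertainty_cm Calibrated uncertainty U_pred, cm.
#' @param call A `placement_call` row.
#' @param image_id Image identifier.
#' @param trust_ceiling_cm Uncertainty above which the result is flagged
#'   untrusted (default 2).
#' @param params Named list snapshot of the parameters used.
#' @param warnings Character vector of warnings accumulated during the run.
#' @return List of class `run_report`.
#' @export
run_report <- function(prediction, uncertainty_cm, call, image_id,
                       trust_ceiling_cm = 2.0, params = list(),
                       warnings = character(0)) {
  structure(list(
    schema_version = 1L,
    image_id = image_id,
    tip = list(row = unname(prediction$tip[1]), col = unname(prediction$tip[2]),
               confidence = prediction$conf_tip),
    carina = list(row = unname(prediction$carina[1]),
                  col = unname(prediction$carina[2]),
                  confidence = prediction$conf_carina),
    level_C = prediction$level_C,
    distance_cm = prediction$distance_cm,
    uncertainty_cm = uncertainty_cm,
    threshold_cm = call$threshold_cm[1],
    placement = call$label[1],
    trusted = uncertainty_cm <= trust_ceiling_cm,
    trust_ceiling_cm = trust_ceiling_cm,
    params = params,
    warnings = as.character(warnings)
  ), class = "run_report")
}

report_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE, null = "null")
}

#' Write a run report with its polyline and overlay
#'
#' Writes `<prefix>.json` (schema-stable, canonical key order),
#' `<prefix>_polyline.csv` (0-based row, col) and `<prefix>_overlay.png`
#' (the input image with the segmentation polyline, landmark markers, the
#' U_pred value burned into the top-left corner, and a warning banner when
#' the run is untrusted).
#'
#' @param report A [run_report()].
#' @param out_prefix Output path prefix.
#' @param polyline Optional `ett_polyline` matrix.
#' @param image Optional [radiograph()] used to render the overlay.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_prefix, polyline = NULL, image = NULL) {
  paths <- character(0)
  json_path <- paste0(out_prefix, ".json")
  writeLines(report_to_json(report), json_path)
  paths <- c(paths, json_path)
  if (!is.null(polyline)) {
    csv_path <- paste0(out_prefix, "_polyline.csv")
    utils::write.csv(as.data.frame(unclass(polyline)[, 1:2, drop = FALSE]),
                     csv_path, row.names = FALSE)
    paths <- c(paths, csv_path)
  }
  if (!is.null(image)) {
    png_path <- paste0(out_prefix, "_overlay.png")
    rgb <- render_overlay(image, polyline = polyline,
                          tip = c(report$tip$row, report$tip$col),
                          carina = c(report$carina$row, report$carina$col),
                          u_pred = report$uncertainty_cm,
                          trusted = report$trusted)
    png::writePNG(rgb, png_path)
    paths <- c(paths, png_path)
  }
  invisible(paths)
}

#' @rdname write_report
#' @param path Path of a report JSON.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(obj, class = "run_report")
}
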