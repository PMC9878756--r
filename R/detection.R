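# The landmark-detector seam. Any callable producing landmark_detection
# records (one bounding box + confidence per landmark class) can feed the
# pipeline; the phantom module ships an oracle implementation and the
# detections-JSON reader accepts output from an external neural detector.

ETT_CLASSES <- c("ett_tip", "carina")
PLACEMENT_CLASSES <- c("good", "too_high", "too_low", "bronchial_insertion")

#' Landmark detection record
#'
#' One detector output: a bounding box for either the ETT tip or the carina,
#' with a confidence score.
#'
#' @param label `"ett_tip"` or `"carina"`.
#' @param box A [box_px()].
#' @param confidence Score in `[0, 1]`.
#' @return Object of class `landmark_detection`.
#' @export
landmark_detection <- function(label, box, confidence) {
  assert_that(label %in% ETT_CLASSES, "invalid_argument",
              sprintf("label must be one of: %s", paste(ETT_CLASSES, collapse = ", ")))
  assert_that(is.numeric(confidence) && length(confidence) == 1 &&
                confidence >= 0 && confidence <= 1,
              "invalid_argument", "confidence must be a single value in [0, 1]")
  structure(list(label = label, box = box, confidence = as.numeric(confidence)),
            class = "landmark_detection")
}

#' Convert an annotated landmark point to a training-style bounding box
#'
#' Builds the square box (default side 200 px) centered on an annotated
#' landmark, the same convention used to turn clinician point annotations
#' into detector targets. The box is never clipped here, so
#' `box_center(annotation_to_box(p)) == p` exactly, including fractional
#' points and even sides.
#'
#' @param landmark Point `c(row, col)`.
#' @param box_side Side length in pixels (> 0), default 200.
#' @return A [box_px()].
#' @examples
#' annotation_to_box(c(600, 400))          # box (500, 300, 200, 200)
#' @export
annotation_to_box <- function(landmark, box_side = 200) {
  assert_that(is.numeric(box_side) && length(box_side) == 1 && box_side > 0,
              "invalid_argument", "box_side must be positive")
  box_px(top = landmark[[1]] - box_side / 2, left = landmark[[2]] - box_side / 2,
         height = box_side, width = box_side)
}

#' Keep the best detection per landmark class
#'
#' Reduces a multi-box detector output to at most one detection per class by
#' highest confidence. Ties break toward the detection whose box top is
#' smaller (higher on the image), then smaller left, so the result does not
#' depend on input order.
#'
#' @param detections List of [landmark_detection()] records.
#' @return Named list mapping class to its best detection; classes absent
#'   from the input are absent from the output.
#' @export
select_best_per_class <- function(detections) {
  out <- list()
  if (length(detections) == 0) return(out)
  for (cls in ETT_CLASSES) {
    cand <- Filter(function(d) d$label == cls, detections)
    if (length(cand) == 0) next
    conf <- vapply(cand, function(d) d$confidence, numeric(1))
    tops <- vapply(cand, function(d) d$box[["top"]], numeric(1))
    lefts <- vapply(cand, function(d) d$box[["left"]], numeric(1))
    best <- order(-conf, tops, lefts)[1]
    out[[cls]] <- cand[[best]]
  }
  out
}

#' Pair the tip and carina detections into one prediction
#'
#' Takes the best detection for each class, places the landmark at the box
#' center, and derives the quantities the downstream rules work from: the
#' level of confidence `C` (the *minimum* of the two confidences) and the
#' predicted ETT-carina distance `D_pred` in cm.
#'
#' @param best Named list as returned by [select_best_per_class()], holding
#'   both `ett_tip` and `carina`.
#' @param image A [radiograph()] (only its spacings are used).
#' @return Object of class `paired_prediction` with fields `tip`, `carina`
#'   (points), `conf_tip`, `conf_carina`, `level_C`, `distance_cm`.
#' @export
make_paired_prediction <- function(best, image) {
  for (cls in ETT_CLASSES) {
    if (is.null(best[[cls]])) {
      stop_ett("missing_landmark",
               sprintf("no '%s' detection available for pairing", cls),
               missing_class = cls)
    }
  }
  tip <- box_center(best$ett_tip$box)
  carina <- box_center(best$carina$box)
  conf_tip <- best$ett_tip$confidence
  conf_carina <- best$carina$confidence
  structure(list(
    tip = tip, carina = carina,
    conf_tip = conf_tip, conf_carina = conf_carina,
    level_C = min(conf_tip, conf_carina),
    distance_cm = px_distance_cm(tip, carina, image$spacing_row, image$spacing_col)
  ), class = "paired_prediction")
}

#' @export
print.paired_prediction <- function(x, ...) {
  cat(sprintf(paste0("<paired_prediction: tip (%.1f, %.1f) @%.2f, ",
                     "carina (%.1f, %.1f) @%.2f, C = %.2f, D = %.2f cm>\n"),
              x$tip[1], x$tip[2], x$conf_tip, x$carina[1], x$carina[2],
              x$conf_carina, x$level_C, x$distance_cm))
  invisible(x)
}

#' Read and write landmark detections as JSON
#'
#' The interchange format is a JSON array of records
#' `{image_id, label, top, left, height, width, confidence}`.
#'
#' @param path File path.
#' @return `read_detections()`: a named list mapping image_id to a list of
#'   [landmark_detection()] records.
#' @export
read_detections <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (r in recs) {
    d <- landmark_detection(r$label,
                            box_px(r$top, r$left, r$height, r$width),
                            r$confidence)
    id <- as.character(r$image_id)
    out[[id]] <- c(out[[id]], list(d))
  }
  out
}

#' @rdname read_detections
#' @param detections Named list (image_id -> list of detections).
#' @export
write_detections <- function(detections, path) {
  rows <- list()
  for (id in names(detections)) {
    for (d in detections[[id]]) {
      rows[[length(rows) + 1]] <- list(
        image_id = id, label = d$label,
        top = d$box[["top"]], left = d$box[["left"]],
        height = d$box[["height"]], width = d$box[["width"]],
        confidence = d$confidence)
    }
  }
  writeLines(jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read and write rater annotations as CSV
#'
#' Columns: `image_id, rater_id, session_tag, tip_row, tip_col, carina_row,
#' carina_col, quality, placement_class`. Empty cells mean the rater could
#' not locate the landmark (allowed by the annotation protocol).
#'
#' @param path File path.
#' @return A data frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character",
                                        rater_id = "character",
                                        session_tag = "character"))
  num_cols <- c("tip_row", "tip_col", "carina_row", "carina_col")
  for (cc in num_cols) ann[[cc]] <- as.numeric(ann[[cc]])
  ann$quality <- as.integer(ann$quality)
  bad_q <- !is.na(ann$quality) & !(ann$quality %in% 0:3)
  assert_that(!any(bad_q), "invalid_argument", "quality scores must be in 0..3")
  ann$placement_class[!is.na(ann$placement_class) & ann$placement_class == ""] <- NA
  bad_p <- !is.na(ann$placement_class) & !(ann$placement_class %in% PLACEMENT_CLASSES)
  assert_that(!any(bad_p), "invalid_argument",
              sprintf("placement_class must be one of: %s",
                      paste(PLACEMENT_CLASSES, collapse = ", ")))
  ann
}

#' @rdname read_annotations
#' @param annotations Data frame of annotations.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, na = "")
  invisible(path)
}
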