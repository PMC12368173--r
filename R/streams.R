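#' Canonical standard views and their planes
#'
#' Six canonical cranial-ultrasound standard views acquired through the
#' anterior fontanelle: anterior horn (AHV), third ventricle (TVV) and
#' lateral-ventricle body (BV) views in the coronal sweep; midsagittal (MSV)
#' and left/right parasagittal (LPSV/RPSV) views in the sagittal sweep.
#'
#' @format `view_labels()` returns the six labels; `view_plane()` maps a view
#'   to `"coronal"` or `"sagittal"`; `canonical_view_order()` returns the
#'   anatomical sweep order for a plane (coronal: anterior to posterior,
#'   AHV, TVV, BV; sagittal: left to right, LPSV, MSV, RPSV).
#' @param view A view label.
#' @param plane `"coronal"` or `"sagittal"`.
#' @export
view_labels <- function() c("AHV", "TVV", "BV", "MSV", "RPSV", "LPSV")

#' @rdname view_labels
#' @export
view_plane <- function(view) {
  map <- c(AHV = "coronal", TVV = "coronal", BV = "coronal",
           MSV = "sagittal", RPSV = "sagittal", LPSV = "sagittal")
  out <- unname(map[view])
  if (anyNA(out)) stop("unknown view label: ",
                       paste(view[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' @rdname view_labels
#' @export
canonical_view_order <- function(plane) {
  switch(match.arg(plane, c("coronal", "sagittal")),
         coronal = c("AHV", "TVV", "BV"),
         sagittal = c("LPSV", "MSV", "RPSV"))
}

#' A single anatomical-structure detection
#'
#' @param structure Structure label (character scalar).
#' @param confidence Detector confidence in \[0, 1\].
#' @param box A [rotated_box()].
#' @return An object of class `detection`.
#' @export
detection <- function(structure, confidence, box) {
  stopifnot(is.character(structure), length(structure) == 1,
            is.numeric(confidence), length(confidence) == 1,
            confidence >= 0, confidence <= 1,
            inherits(box, "rotated_box"))
  structure(list(structure = structure, confidence = as.numeric(confidence),
                 box = box), class = "detection")
}

#' Detections of one video frame
#'
#' @param frame_index 0-based frame index.
#' @param detections List of [detection()] objects (possibly empty).
#' @return An object of class `frame_detections`.
#' @export
frame_detections <- function(frame_index, detections = list()) {
  stopifnot(length(frame_index) == 1, frame_index >= 0,
            frame_index == as.integer(frame_index))
  stopifnot(all(vapply(detections, inherits, logical(1), "detection")))
  structure(list(frame_index = as.integer(frame_index),
                 detections = detections), class = "frame_detections")
}

#' A sweep-video detection stream
#'
#' The per-frame output of a rotated-box detector run over one coronal or
#' sagittal sweep video, the only representation of the video the pipeline
#' sees.
#'
#' @param plane `"coronal"` or `"sagittal"`.
#' @param frames List of [frame_detections()], strictly increasing
#'   `frame_index`.
#' @param meta Free-form named list of metadata.
#' @return An object of class `sweep_stream`.
#' @export
sweep_stream <- function(plane, frames, meta = list()) {
  plane <- match.arg(plane, c("coronal", "sagittal"))
  stopifnot(all(vapply(frames, inherits, logical(1), "frame_detections")))
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (length(idx) > 1 && any(diff(idx) <= 0)) {
    stop("frame_index must be strictly increasing within a stream",
         call. = FALSE)
  }
  structure(list(plane = plane, frames = frames, meta = meta),
            class = "sweep_stream")
}

#' @export
print.sweep_stream <- function(x, ...) {
  n_det <- sum(vapply(x$frames, function(f) length(f$detections), integer(1)))
  cat(sprintf("<sweep_stream plane=%s frames=%d detections=%d>\n",
              x$plane, length(x$frames), n_det))
  invisible(x)
}
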