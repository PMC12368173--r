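#' Scoring configuration for standard-view extraction
#'
#' Bundles the anatomical base scores, the per-view candidate criteria and
#' the clustering parameters used by the extraction stage. A frame's score is
#' the sum over retained detections of base score times detector confidence;
#' a frame becomes a candidate for a view when every required structure of
#' that view is detected at or above `min_confidence` and no forbidden
#' structure is present.
#'
#' @param base_scores Named numeric vector, structure label to nonnegative
#'   base score. Every structure referenced by any criterion must have one.
#' @param criteria Named list, view label to a list with elements
#'   `required` (character vector of structures), `min_confidence`
#'   (scalar in \[0, 1\]) and optionally `forbidden` (character vector).
#' @param detector_conf_floor Detections below this confidence are ignored
#'   entirely (scoring and criteria alike). Default 0.5, matching the usual
#'   operating point of detector post-processing.
#' @param dbscan_eps DBSCAN radius in the min-max normalized
#'   (frame index, score) feature space. Default 0.1.
#' @param dbscan_min_samples DBSCAN core-point threshold, self included.
#'   Default 3.
#' @return An object of class `scoring_config`.
#' @seealso [default_scoring_config()]
#' @export
scoring_config <- function(base_scores, criteria, detector_conf_floor = 0.5,
                           dbscan_eps = 0.1, dbscan_min_samples = 3) {
  stopifnot(is.numeric(base_scores), !is.null(names(base_scores)),
            all(base_scores >= 0),
            detector_conf_floor >= 0, detector_conf_floor <= 1,
            dbscan_eps > 0, dbscan_min_samples >= 1)
  for (v in names(criteria)) {
    view_plane(v) # validates the label
    cr <- criteria[[v]]
    stopifnot(is.character(cr$required), length(cr$required) >= 1,
              cr$min_confidence >= 0, cr$min_confidence <= 1)
    if (is.null(cr$forbidden)) criteria[[v]]$forbidden <- character(0)
    referenced <- c(cr$required, criteria[[v]]$forbidden)
    missing <- setdiff(cr$required, names(base_scores))
    if (length(missing) > 0) {
      stop("configuration error: no base score for structure(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(base_scores = base_scores, criteria = criteria,
                 detector_conf_floor = detector_conf_floor,
                 dbscan_eps = dbscan_eps,
                 dbscan_min_samples = as.integer(dbscan_min_samples)),
            class = "scoring_config")
}

#' Default scoring configuration
#'
#' The shipped defaults encode the usual sonographic definition of each
#' standard view: paired anterior horns for AHV, the third ventricle for
#' TVV, the lateral-ventricle body plus choroid plexus for BV, corpus
#' callosum plus cerebellar vermis for MSV, and the side-specific lateral
#' ventricle plus thalamus for the parasagittal views. Base scores weight
#' view-defining midline structures slightly above accompanying ones; the
#' exact values are tunable and carry no clinical meaning beyond their
#' ordering.
#'
#' @param ... Overrides passed on to [scoring_config()]
#'   (e.g. `detector_conf_floor`, `dbscan_eps`).
#' @return A `scoring_config`.
#' @export
default_scoring_config <- function(...) {
  base <- c(
    anterior_horn_left = 2, anterior_horn_right = 2,
    third_ventricle = 2,
    lateral_ventricle_body = 2, choroid_plexus = 1.5,
    corpus_callosum = 2, cerebellar_vermis = 1.5,
    lateral_ventricle_left = 2, thalamus_left = 1.5,
    lateral_ventricle_right = 2, thalamus_right = 1.5
  )
  crit <- list(
    AHV = list(required = c("anterior_horn_left", "anterior_horn_right"),
               min_confidence = 0.5),
    TVV = list(required = "third_ventricle", min_confidence = 0.5),
    BV = list(required = c("lateral_ventricle_body", "choroid_plexus"),
              min_confidence = 0.5),
    MSV = list(required = c("corpus_callosum", "cerebellar_vermis"),
               min_confidence = 0.5),
    LPSV = list(required = c("lateral_ventricle_left", "thalamus_left"),
                min_confidence = 0.5),
    RPSV = list(required = c("lateral_ventricle_right", "thalamus_right"),
                min_confidence = 0.5)
  )
  scoring_config(base_scores = base, criteria = crit, ...)
}

#' Structure vocabulary of a scoring configuration
#'
#' @param config A `scoring_config`.
#' @return Character vector of all structure labels with a base score.
#' @export
structure_vocabulary <- function(config) names(config$base_scores)
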