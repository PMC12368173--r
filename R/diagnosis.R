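#' Condition labels of the per-image multi-label head
#'
#' Fixed six-label vocabulary used for per-image prediction: normal, IVH
#' (intraventricular hemorrhage), ependymal cyst, ventricular dilation,
#' hydrocephalus and PVL (periventricular leukomalacia).
#'
#' @return Character vector of the six labels.
#' @export
condition_labels <- function() {
  c("normal", "IVH", "ependymal_cyst", "ventricular_dilation",
    "hydrocephalus", "PVL")
}

#' Per-image multi-label prediction
#'
#' @param probs Named numeric vector over all six [condition_labels()],
#'   each in \[0, 1\]. Being multi-label, probabilities need not sum to 1.
#' @param view View label or `"unknown"`.
#' @return An object of class `image_prediction`.
#' @export
image_prediction <- function(probs, view = "unknown") {
  stopifnot(setequal(names(probs), condition_labels()),
            all(probs >= 0 & probs <= 1))
  structure(list(view = view, probs = probs[condition_labels()]),
            class = "image_prediction")
}

#' Case-level diagnostic input
#'
#' @param images Nonempty list of [image_prediction()]s (typically the 3-6
#'   standard views of one neonate).
#' @param binary_severe_prob Case-level severity probability from the
#'   binary head, in \[0, 1\].
#' @return An object of class `case_input`.
#' @export
case_input <- function(images, binary_severe_prob) {
  if (length(images) == 0) stop("invalid case: no images", call. = FALSE)
  stopifnot(all(vapply(images, inherits, logical(1), "image_prediction")),
            binary_severe_prob >= 0, binary_severe_prob <= 1)
  structure(list(images = images,
                 binary_severe_prob = as.numeric(binary_severe_prob)),
            class = "case_input")
}

#' Positive labels of one image at a threshold
#'
#' @param pred An [image_prediction()].
#' @param tau Probability threshold in (0, 1), closed (a probability equal
#'   to `tau` is positive). Default 0.5.
#' @return Character vector of positive condition labels.
#' @export
positive_labels <- function(pred, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  names(pred$probs)[pred$probs >= tau]
}

#' Is an image abnormal?
#'
#' An image is abnormal when it is not predicted to be exclusively normal,
#' i.e. when at least one non-normal label is positive. An image with no
#' positive label at all carries no abnormal evidence and counts as not
#' abnormal.
#'
#' @inheritParams positive_labels
#' @return Logical scalar.
#' @export
is_abnormal <- function(pred, tau = 0.5) {
  length(setdiff(positive_labels(pred, tau), "normal")) > 0
}

#' Multi-label severe rule over a case's images
#'
#' The multi-label head flags a case severe when at least one single image
#' shows PVL, hydrocephalus, or the combination of IVH and ventricular
#' dilation co-occurring on that same image.
#'
#' @param images List of [image_prediction()]s.
#' @param tau Probability threshold, see [positive_labels()].
#' @return Logical scalar.
#' @export
multilabel_case_severe <- function(images, tau = 0.5) {
  any(vapply(images, function(img) {
    pos <- positive_labels(img, tau)
    ("PVL" %in% pos) || ("hydrocephalus" %in% pos) ||
      (("IVH" %in% pos) && ("ventricular_dilation" %in% pos))
  }, logical(1)))
}

#' Ensemble severity decision for one case
#'
#' Combines the binary case head with the multi-label rule: the binary head
#' alone can call a case severe; when it predicts non-severe, the case is
#' still classified severe if the multi-label rule fires and at least two
#' images are abnormal. Equivalently:
#' `severe = binary_severe OR (multilabel_severe AND abnormal_count >= 2)`.
#'
#' @param case A [case_input()].
#' @param tau Probability threshold applied to both heads (closed).
#' @return An object of class `case_decision` with fields `severe`,
#'   `binary_severe`, `multilabel_severe`, `abnormal_count` and a textual
#'   `rationale`.
#' @export
ensemble_decision <- function(case, tau = 0.5) {
  if (!inherits(case, "case_input")) {
    stop("invalid case: expected a case_input", call. = FALSE)
  }
  binary_severe <- case$binary_severe_prob >= tau
  ml_severe <- multilabel_case_severe(case$images, tau)
  abn <- sum(vapply(case$images, is_abnormal, logical(1), tau = tau))
  severe <- binary_severe || (ml_severe && abn >= 2)
  rationale <- if (binary_severe) {
    "binary head predicted severe"
  } else if (ml_severe && abn >= 2) {
    sprintf("multi-label severe findings with %d abnormal images (>= 2)", abn)
  } else if (ml_severe) {
    sprintf("multi-label severe findings but only %d abnormal image(s)", abn)
  } else {
    "no severe findings"
  }
  structure(list(severe = severe, binary_severe = binary_severe,
                 multilabel_severe = ml_severe,
                 abnormal_count = as.integer(abn), rationale = rationale),
            class = "case_decision")
}

#' @export
print.case_decision <- function(x, ...) {
  cat(sprintf("<case_decision severe=%s (%s)>\n",
              x$severe, x$rationale))
  invisible(x)
}

#' Ground-truth findings of a case
#'
#' @param findings Character vector drawn from the finding vocabulary
#'   `IVH_I`, `IVH_II`, `IVH_III`, `IVH_IV`, `ependymal_cyst`,
#'   `minor_ventricular_dilation`, `hydrocephalus`, `PVL`; empty = normal.
#'   IVH grades are mutually exclusive.
#' @return An object of class `case_condition`.
#' @export
case_condition <- function(findings = character(0)) {
  vocab <- c("IVH_I", "IVH_II", "IVH_III", "IVH_IV", "ependymal_cyst",
             "minor_ventricular_dilation", "hydrocephalus", "PVL")
  findings <- unique(as.character(findings))
  bad <- setdiff(findings, vocab)
  if (length(bad) > 0) {
    stop("unknown finding(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sum(findings %in% c("IVH_I", "IVH_II", "IVH_III", "IVH_IV")) > 1) {
    stop("IVH grades are mutually exclusive", call. = FALSE)
  }
  structure(list(findings = findings), class = "case_condition")
}

#' Papile-based severity label of a ground-truth condition
#'
#' Cases with grade III or IV IVH, PVL or hydrocephalus are severe (label
#' 1); grade I or II IVH, ependymal cysts, minor ventricular dilation and
#' normal cases are non-severe (label 0).
#'
#' @param cond A [case_condition()].
#' @return Integer 0 or 1.
#' @export
papile_case_label <- function(cond) {
  severe_set <- c("IVH_III", "IVH_IV", "PVL", "hydrocephalus")
  as.integer(length(intersect(cond$findings, severe_set)) > 0)
}
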