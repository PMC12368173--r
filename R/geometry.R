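#' Rotated bounding box
#'
#' A rotated rectangle in image coordinates (x rightward, y downward),
#' parameterised by its centre, side lengths and a rotation angle in degrees.
#' The canonical angle range is the half-open interval \[-90, 90): rotating a
#' rectangle by 90 degrees while swapping width and height leaves its point
#' set unchanged, so every rectangle has exactly one representative in that
#' range (up to the width/height swap applied on the way there).
#'
#' @param cx,cy Centre coordinates in pixels.
#' @param w,h Width and height in pixels; must be nonzero (negative values
#'   are folded to their absolute value).
#' @param angle_deg Rotation in degrees, counter-clockwise positive in the
#'   mathematical sense; any finite value is accepted and normalised.
#' @return An object of class `rotated_box` with fields `cx`, `cy`, `w`,
#'   `h`, `angle_deg`, already in canonical form.
#' @examples
#' rotated_box(10, 10, 4, 2, 0)
#' rotated_box(10, 10, 4, 2, 95) # canonicalised to angle 5 with w/h swapped
#' @export
rotated_box <- function(cx, cy, w, h, angle_deg) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(w), is.finite(h),
            is.finite(angle_deg))
  normalize_box(structure(
    list(cx = as.numeric(cx), cy = as.numeric(cy),
         w = as.numeric(w), h = as.numeric(h),
         angle_deg = as.numeric(angle_deg)),
    class = "rotated_box"))
}

#' Canonicalise a rotated box
#'
#' Folds negative side lengths to positive and reduces the angle to
#' \[-90, 90) in 90-degree steps, swapping width and height at each step so
#' the represented point set is unchanged. Idempotent.
#'
#' @param box A `rotated_box` (or a bare list with the same fields).
#' @return An equivalent `rotated_box` with `w, h > 0` and
#'   `angle_deg` in \[-90, 90).
#' @export
normalize_box <- function(box) {
  w <- abs(box$w); h <- abs(box$h)
  if (w == 0 || h == 0) {
    stop("invalid geometry: degenerate box (w or h is zero)", call. = FALSE)
  }
  a <- box$angle_deg
  while (a >= 90) { a <- a - 90; tmp <- w; w <- h; h <- tmp }
  while (a < -90) { a <- a + 90; tmp <- w; w <- h; h <- tmp }
  structure(list(cx = box$cx, cy = box$cy, w = w, h = h, angle_deg = a),
            class = "rotated_box")
}

#' @export
print.rotated_box <- function(x, ...) {
  cat(sprintf("<rotated_box centre=(%.6g, %.6g) w=%.6g h=%.6g angle=%.6g deg>\n",
              x$cx, x$cy, x$w, x$h, x$angle_deg))
  invisible(x)
}

#' Corner coordinates of a rotated box
#'
#' @param box A `rotated_box`.
#' @return A 4x2 matrix of corner coordinates in counter-clockwise order.
#' @export
box_corners <- function(box) {
  th <- box$angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  half <- rbind(c(-box$w, -box$h), c(box$w, -box$h),
                c(box$w, box$h), c(-box$w, box$h)) / 2
  sweep(half %*% t(R), 2, c(box$cx, box$cy), `+`)
}

# Shoelace area of a polygon given as an n x 2 matrix (absolute value).
polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman: clip convex polygon `subject` against the half-plane
# on the inner side of the directed edge a -> b of a counter-clockwise
# convex clip polygon.
clip_edge <- function(subject, a, b) {
  n <- nrow(subject)
  if (is.null(n) || n == 0) return(subject)
  ex <- b[1] - a[1]; ey <- b[2] - a[2]
  # signed cross product; >= 0 means inside for CCW polygons
  side <- ex * (subject[, 2] - a[2]) - ey * (subject[, 1] - a[1])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- side[i]; cj <- side[j]
    if (ci >= 0) out <- rbind(out, subject[i, ])
    if ((ci > 0 && cj < 0) || (ci < 0 && cj > 0)) {
      t <- ci / (ci - cj)
      out <- rbind(out, subject[i, ] + t * (subject[j, ] - subject[i, ]))
    }
  }
  out
}

# Intersection polygon of two convex polygons (both CCW-oriented).
convex_intersection <- function(p, q) {
  out <- p
  nq <- nrow(q)
  for (i in seq_len(nq)) {
    j <- if (i == nq) 1L else i + 1L
    out <- clip_edge(out, q[i, ], q[j, ])
    if (nrow(out) == 0) break
  }
  out
}

# Ensure counter-clockwise orientation (positive signed area) of a polygon.
ccw <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  s <- sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
  if (s < 0) p[rev(seq_len(n)), , drop = FALSE] else p
}

#' Intersection-over-union of two rotated boxes
#'
#' Exact IoU of two rotated rectangles computed by Sutherland-Hodgman
#' clipping of one quadrilateral against the other and the shoelace area
#' formula. Symmetric; 1 for identical point sets; 0 for disjoint interiors.
#'
#' @param a,b `rotated_box` objects.
#' @return IoU in \[0, 1\].
#' @export
rotated_iou <- function(a, b) {
  a <- normalize_box(a); b <- normalize_box(b)
  pa <- ccw(box_corners(a)); pb <- ccw(box_corners(b))
  inter <- polygon_area(convex_intersection(pa, pb))
  area_a <- a$w * a$h; area_b <- b$w * b$h
  union <- area_a + area_b - inter
  if (union <= 0) return(0)
  min(1, max(0, inter / union))
}

#' Average precision for rotated-box detections
#'
#' Per-class average precision and mean average precision (mAP) for a set of
#' frame-indexed predictions against ground-truth boxes. Matching is greedy:
#' within each class, predictions are visited in descending confidence
#' (ties broken by input order) and matched to the unmatched ground-truth box
#' of the same frame with the highest IoU at or above `iou_thresh`. AP uses
#' all-point precision-recall interpolation (area under the precision
#' envelope). Classes absent from `truths` are excluded from the mean and
#' reported as `NA` with a warning.
#'
#' @param preds Data frame with columns `structure`, `confidence`,
#'   `frame_index`, and a list-column `box` of `rotated_box` objects (or a
#'   list of detections as produced by [detection()] paired with frames).
#' @param truths Data frame with columns `structure`, `frame_index` and
#'   list-column `box`.
#' @param iou_thresh IoU threshold in (0, 1); default 0.5.
#' @return A list with `ap` (named numeric per class) and `map`.
#' @export
average_precision <- function(preds, truths, iou_thresh = 0.5) {
  stopifnot(iou_thresh > 0, iou_thresh < 1)
  classes <- unique(as.character(truths$structure))
  pred_classes <- unique(as.character(preds$structure))
  ghost <- setdiff(pred_classes, classes)
  if (length(ghost) > 0) {
    warning("predictions for classes with no ground truth excluded from mAP: ",
            paste(ghost, collapse = ", "), call. = FALSE)
  }
  ap <- vapply(classes, function(cl) {
    t_idx <- which(truths$structure == cl)
    p_idx <- which(preds$structure == cl)
    n_pos <- length(t_idx)
    if (length(p_idx) == 0) return(0)
    ord <- p_idx[order(-preds$confidence[p_idx])] # stable: ties keep input order
    matched <- rep(FALSE, n_pos)
    tp <- fp <- numeric(length(ord))
    for (k in seq_along(ord)) {
      i <- ord[k]
      cand <- which(!matched & truths$frame_index[t_idx] == preds$frame_index[i])
      best <- 0; best_j <- 0L
      for (j in cand) {
        iou <- rotated_iou(preds$box[[i]], truths$box[[t_idx[j]]])
        if (iou >= iou_thresh && iou > best) { best <- iou; best_j <- j }
      }
      if (best_j > 0L) { matched[best_j] <- TRUE; tp[k] <- 1 } else fp[k] <- 1
    }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(fp)
    recall <- cum_tp / n_pos
    precision <- cum_tp / (cum_tp + cum_fp)
    # precision envelope (running max from the right), then area under PR
    env <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * env)
  }, numeric(1))
  list(ap = ap, map = if (length(ap) > 0) mean(ap) else NA_real_)
}
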