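#' Score one frame from its detections
#'
#' Frame score = sum over retained detections of anatomical base score times
#' detector confidence. Detections below `detector_conf_floor` are ignored;
#' an empty frame scores 0.
#'
#' @param frame A [frame_detections()].
#' @param config A [scoring_config()].
#' @return Nonnegative numeric score.
#' @export
score_frame <- function(frame, config) {
  dets <- retained_detections(frame, config)
  if (length(dets) == 0) return(0)
  sum(vapply(dets, function(d) {
    if (!d$structure %in% names(config$base_scores)) {
      stop("configuration error: structure '", d$structure,
           "' has no base score", call. = FALSE)
    }
    config$base_scores[[d$structure]] * d$confidence
  }, numeric(1)))
}

retained_detections <- function(frame, config) {
  Filter(function(d) d$confidence >= config$detector_conf_floor,
         frame$detections)
}

empty_queue <- function() {
  data.frame(frame_index = integer(0), score = numeric(0),
             contributing = I(list()))
}

#' Build per-view candidate queues
#'
#' A frame enters the candidate queue of view V when V belongs to the
#' stream's plane, every required structure of V is detected at confidence
#' at or above V's `min_confidence`, and no forbidden structure of V is
#' present. A frame may enter several queues; queue entries carry the frame
#' score and the retained detections that produced it.
#'
#' @param stream A [sweep_stream()].
#' @param config A [scoring_config()].
#' @return Named list, view label to a data frame with columns
#'   `frame_index`, `score` and list-column `contributing`
#'   (each element a data frame of structure/confidence pairs).
#' @export
assign_candidates <- function(stream, config) {
  views <- intersect(names(config$criteria),
                     canonical_view_order(stream$plane))
  queues <- stats::setNames(rep(list(empty_queue()), length(views)), views)
  for (frame in stream$frames) {
    dets <- retained_detections(frame, config)
    if (length(dets) == 0) next
    labs <- vapply(dets, `[[`, character(1), "structure")
    confs <- vapply(dets, `[[`, numeric(1), "confidence")
    sc <- NULL
    for (v in views) {
      cr <- config$criteria[[v]]
      req_ok <- all(vapply(cr$required, function(s) {
        any(labs == s & confs >= cr$min_confidence)
      }, logical(1)))
      if (!req_ok || any(labs %in% cr$forbidden)) next
      if (is.null(sc)) sc <- score_frame(frame, config)
      queues[[v]] <- rbind(queues[[v]], data.frame(
        frame_index = frame$frame_index, score = sc,
        contributing = I(list(data.frame(structure = labs,
                                         confidence = confs)))))
    }
  }
  queues
}

# Min-max normalize candidate (frame_index, score) pairs to [0,1]^2 over the
# whole stream (all queues jointly), then run DBSCAN per view.
cluster_candidates <- function(queues, config) {
  all_f <- unlist(lapply(queues, function(q) q$frame_index))
  all_s <- unlist(lapply(queues, function(q) q$score))
  norm <- function(x, lo, hi) if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
  lapply(queues, function(q) {
    if (nrow(q) == 0) return(integer(0))
    pts <- cbind(norm(q$frame_index, min(all_f), max(all_f)),
                 norm(q$score, min(all_s), max(all_s)))
    dbscan(pts, eps = config$dbscan_eps,
           min_samples = config$dbscan_min_samples)
  })
}

# Per-view cluster table: label, total score, centroid frame; primary first.
cluster_table <- function(queue, labels) {
  keep <- labels > 0
  if (!any(keep)) {
    return(data.frame(label = integer(0), total = numeric(0),
                      centroid = numeric(0)))
  }
  tot <- tapply(queue$score[keep], labels[keep], sum)
  cen <- tapply(queue$frame_index[keep], labels[keep], mean)
  out <- data.frame(label = as.integer(names(tot)),
                    total = as.numeric(tot), centroid = as.numeric(cen))
  out[order(-out$total, out$label), , drop = FALSE]
}

#' Infer the sweep direction from candidate clusters
#'
#' Each view's candidates, embedded as (frame index, score) min-max
#' normalized over the stream, are clustered with DBSCAN; the
#' highest-total-score cluster of each view defines that view's centroid
#' frame. The direction is `forward` when the centroids follow the
#' anatomical sweep order (coronal: AHV, TVV, BV; sagittal: LPSV, MSV,
#' RPSV), `reverse` when they follow the exact reverse, and `unknown`
#' otherwise or when fewer than two views have a cluster.
#'
#' @param queues Candidate queues from [assign_candidates()].
#' @param config A [scoring_config()].
#' @param labels Optional precomputed cluster labels
#'   (from the same queues); computed when omitted.
#' @return `"forward"`, `"reverse"` or `"unknown"`.
#' @export
infer_scan_direction <- function(queues, config, labels = NULL) {
  if (is.null(labels)) labels <- cluster_candidates(queues, config)
  cents <- c()
  for (v in names(queues)) {
    tab <- cluster_table(queues[[v]], labels[[v]])
    if (nrow(tab) > 0) cents[v] <- tab$centroid[1]
  }
  if (length(cents) < 2) return("unknown")
  plane <- view_plane(names(cents)[1])
  ord <- intersect(canonical_view_order(plane), names(cents))
  seq_c <- cents[ord]
  if (all(diff(seq_c) > 0)) return("forward")
  if (all(diff(seq_c) < 0)) return("reverse")
  "unknown"
}

#' Filter candidate queues by cluster membership and sweep order
#'
#' Candidates labelled noise by DBSCAN are dropped with reason `"noise"`.
#' When the direction is known, views are visited in the direction's
#' anatomical order while keeping the last accepted primary-cluster
#' centroid; any cluster whose centroid falls behind it is dropped whole
#' with reason `"order"`. An unknown direction disables order filtering
#' only. Every dropped candidate is recorded.
#'
#' @param queues Candidate queues from [assign_candidates()].
#' @param labels Cluster labels from the internal clustering (one integer
#'   vector per view, 0 = noise).
#' @param direction `"forward"`, `"reverse"` or `"unknown"`.
#' @return List with `queues` (surviving candidates per view) and `dropped`
#'   (data frame with columns `view`, `frame_index`, `score`, `reason`).
#' @export
filter_candidates <- function(queues, labels, direction) {
  dropped <- data.frame(view = character(0), frame_index = integer(0),
                        score = numeric(0), reason = character(0))
  drop_rows <- function(v, q, idx, reason) {
    if (length(idx) == 0) return(invisible())
    dropped <<- rbind(dropped, data.frame(
      view = v, frame_index = q$frame_index[idx], score = q$score[idx],
      reason = reason))
  }
  out <- queues
  keep_labels <- labels
  for (v in names(queues)) {
    q <- queues[[v]]
    lb <- labels[[v]]
    noise <- which(lb == 0)
    drop_rows(v, q, noise, "noise")
    keep <- lb > 0
    out[[v]] <- q[keep, , drop = FALSE]
    keep_labels[[v]] <- lb[keep]
  }
  if (direction != "unknown" && length(out) > 0) {
    plane <- view_plane(names(out)[1])
    ord <- intersect(canonical_view_order(plane), names(out))
    if (direction == "reverse") ord <- rev(ord)
    last <- -Inf
    for (v in ord) {
      q <- out[[v]]
      lb <- keep_labels[[v]]
      tab <- cluster_table(q, lb)
      if (nrow(tab) == 0) next
      ok <- tab$label[tab$centroid >= last]
      bad <- tab$label[tab$centroid < last]
      if (length(bad) > 0) {
        idx <- which(lb %in% bad)
        drop_rows(v, q, idx, "order")
        out[[v]] <- q[-idx, , drop = FALSE]
        keep_labels[[v]] <- lb[-idx]
      }
      if (length(ok) > 0) {
        # advance to the best surviving cluster's centroid
        last <- tab$centroid[match(ok[1], tab$label)]
      }
    }
  }
  rownames(dropped) <- NULL
  list(queues = out, dropped = dropped)
}

#' Select the standard-view frame per queue
#'
#' Per view the maximum-score surviving candidate is selected; score ties
#' are broken toward the smallest frame index; an empty queue yields an
#' absent view (`NA`).
#'
#' @param queues Post-filter candidate queues.
#' @param direction Inferred direction, stored on the result.
#' @param dropped Drop audit table from [filter_candidates()].
#' @return An `extraction_result`: list with `selected` (named integer over
#'   all six views, `NA` = absent), `direction`, `queues` and `dropped`.
#' @export
select_standard_views <- function(queues, direction = "unknown",
                                  dropped = NULL) {
  selected <- stats::setNames(rep(NA_integer_, length(view_labels())),
                              view_labels())
  for (v in names(queues)) {
    q <- queues[[v]]
    if (nrow(q) == 0) next
    best <- order(-q$score, q$frame_index)[1]
    selected[v] <- q$frame_index[best]
  }
  if (is.null(dropped)) {
    dropped <- data.frame(view = character(0), frame_index = integer(0),
                          score = numeric(0), reason = character(0))
  }
  structure(list(selected = selected, direction = direction,
                 queues = queues, dropped = dropped),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  sel <- x$selected[!is.na(x$selected)]
  cat(sprintf("<extraction_result direction=%s views=%d/%d dropped=%d>\n",
              x$direction, length(sel), length(x$selected), nrow(x$dropped)))
  if (length(sel) > 0) {
    cat(paste(sprintf("  %s: frame %d", names(sel), sel), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Extract standard views from a sweep stream
#'
#' Full extraction stage: score frames, build per-view candidate queues,
#' cluster candidates, infer the sweep direction, filter noise and
#' out-of-order clusters, and select the highest-score candidate per view.
#' Deterministic for a fixed stream and configuration.
#'
#' @param stream A [sweep_stream()].
#' @param config A [scoring_config()]; defaults to
#'   [default_scoring_config()].
#' @return An `extraction_result` (see [select_standard_views()]). Views of
#'   the other plane are always absent.
#' @examples
#' sim <- simulate_sweep(sweep_spec(plane = "coronal", seed = 7))
#' extract_views(sim$stream)
#' @export
extract_views <- function(stream, config = default_scoring_config()) {
  queues <- assign_candidates(stream, config)
  labels <- cluster_candidates(queues, config)
  direction <- infer_scan_direction(queues, config, labels)
  flt <- filter_candidates(queues, labels, direction)
  select_standard_views(flt$queues, direction, flt$dropped)
}
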