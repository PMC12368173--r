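#' Read a sweep detection stream from JSON Lines
#'
#' The stream dialect is one JSON object per line: a header record
#' `{"plane": "coronal", "meta": {...}}` followed by frame records
#' `{"frame": 0, "detections": [{"label": "...", "conf": 0.9,
#' "box": [cx, cy, w, h, angle]}, ...]}`. Validation is strict; parse
#' errors name the offending line.
#'
#' @param path Path to a `.jsonl` file.
#' @return A [sweep_stream()].
#' @export
read_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty stream file: ", path, call. = FALSE)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) stop("parse error at line ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  header <- parse_line(1)
  if (is.null(header$plane)) {
    stop("parse error at line 1: header record must carry 'plane'",
         call. = FALSE)
  }
  frames <- lapply(seq_along(lines)[-1], function(i) {
    rec <- parse_line(i)
    if (is.null(rec$frame)) {
      stop("parse error at line ", i, ": missing 'frame'", call. = FALSE)
    }
    dets <- lapply(seq_along(rec$detections), function(k) {
      d <- rec$detections[[k]]
      if (is.null(d$label) || is.null(d$conf) || is.null(d$box)) {
        stop("parse error at line ", i, ", detection ", k,
             ": need 'label', 'conf' and 'box'", call. = FALSE)
      }
      b <- unlist(d$box)
      if (length(b) != 5) {
        stop("parse error at line ", i, ", detection ", k,
             ": box must have 5 numbers", call. = FALSE)
      }
      detection(d$label, d$conf, rotated_box(b[1], b[2], b[3], b[4], b[5]))
    })
    frame_detections(rec$frame, dets)
  })
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (length(idx) > 1 && any(diff(idx) <= 0)) {
    bad <- which(diff(idx) <= 0)[1] + 2L # +1 for header, +1 for second frame
    stop("parse error at line ", bad,
         ": frame indices must be strictly increasing", call. = FALSE)
  }
  meta <- if (is.null(header$meta)) list() else header$meta
  sweep_stream(header$plane, frames, meta)
}

#' Write a sweep detection stream as JSON Lines
#'
#' Inverse of [read_stream()]; `read_stream(write_stream(s, f))`
#' round-trips.
#'
#' @param stream A [sweep_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  header <- jsonlite::toJSON(list(plane = stream$plane, meta = stream$meta),
                             auto_unbox = TRUE, digits = NA)
  body <- vapply(stream$frames, function(f) {
    dets <- lapply(f$detections, function(d) {
      list(label = d$structure, conf = d$confidence,
           box = c(d$box$cx, d$box$cy, d$box$w, d$box$h, d$box$angle_deg))
    })
    jsonlite::toJSON(list(frame = f$frame_index, detections = dets),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read per-image and per-case prediction tables
#'
#' `images_path` is a CSV with columns `case_id`, `view` and the six
#' condition-probability columns ([condition_labels()]); `cases_path` is a
#' CSV with columns `case_id` and `binary_severe_prob`.
#'
#' @param images_path,cases_path CSV paths.
#' @return Named list, case id to [case_input()].
#' @export
read_case_predictions <- function(images_path, cases_path) {
  imgs <- utils::read.csv(images_path, stringsAsFactors = FALSE)
  cases <- utils::read.csv(cases_path, stringsAsFactors = FALSE)
  need <- c("case_id", "view", condition_labels())
  miss <- setdiff(need, names(imgs))
  if (length(miss) > 0) {
    stop("image prediction table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(c("case_id", "binary_severe_prob") %in% names(cases))) {
    stop("case table needs columns case_id and binary_severe_prob",
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(cases)), function(i) {
    id <- cases$case_id[i]
    rows <- imgs[imgs$case_id == id, , drop = FALSE]
    if (nrow(rows) == 0) stop("no images for case ", id, call. = FALSE)
    images <- lapply(seq_len(nrow(rows)), function(j) {
      probs <- as.numeric(rows[j, condition_labels()])
      image_prediction(stats::setNames(probs, condition_labels()),
                       view = rows$view[j])
    })
    case_input(images, cases$binary_severe_prob[i])
  })
  stats::setNames(out, cases$case_id)
}

#' Write per-image and per-case prediction tables
#'
#' @param cases Named list of [case_input()]s (names = case ids).
#' @param images_path,cases_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_case_predictions <- function(cases, images_path, cases_path) {
  img_rows <- do.call(rbind, lapply(names(cases), function(id) {
    do.call(rbind, lapply(cases[[id]]$images, function(im) {
      cbind(data.frame(case_id = id, view = im$view),
            as.data.frame(as.list(im$probs)))
    }))
  }))
  case_rows <- data.frame(
    case_id = names(cases),
    binary_severe_prob = vapply(cases, `[[`, numeric(1),
                                "binary_severe_prob"))
  utils::write.csv(img_rows, images_path, row.names = FALSE)
  utils::write.csv(case_rows, cases_path, row.names = FALSE)
  invisible(c(images_path, cases_path))
}

#' Run configuration
#'
#' All tunables of the pipeline in one validated object. Unknown keys are
#' rejected by name on load.
#'
#' @param tau Probability threshold for both diagnostic heads; default 0.5.
#' @param detector_conf_floor,dbscan_eps,dbscan_min_samples Extraction
#'   knobs, see [scoring_config()].
#' @param min_views Minimum number of extracted standard views for a case
#'   to be diagnosable; default 3.
#' @param ci_level Confidence level for reports; default 0.95.
#' @param bootstrap_reps Bootstrap replicates; default 2000.
#' @param seed Default seed; default 1.
#' @param report_digits Rounding applied in rendered reports only;
#'   default 3.
#' @param base_scores,criteria Optional overrides of the default scoring
#'   configuration (same shapes as in [scoring_config()]).
#' @return An object of class `run_config`; `$scoring` holds the derived
#'   [scoring_config()].
#' @export
run_config <- function(tau = 0.5, detector_conf_floor = 0.5,
                       dbscan_eps = 0.1, dbscan_min_samples = 3,
                       min_views = 3, ci_level = 0.95,
                       bootstrap_reps = 2000, seed = 1, report_digits = 3,
                       base_scores = NULL, criteria = NULL) {
  stopifnot(tau > 0, tau < 1, min_views >= 1, ci_level > 0, ci_level < 1,
            bootstrap_reps >= 1, report_digits >= 0)
  def <- default_scoring_config()
  scoring <- scoring_config(
    base_scores = if (is.null(base_scores)) def$base_scores else
      unlist(base_scores),
    criteria = if (is.null(criteria)) def$criteria else criteria,
    detector_conf_floor = detector_conf_floor, dbscan_eps = dbscan_eps,
    dbscan_min_samples = dbscan_min_samples)
  structure(list(tau = tau, min_views = as.integer(min_views),
                 ci_level = ci_level,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 report_digits = as.integer(report_digits),
                 scoring = scoring),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Run the full screening pipeline for one case
#'
#' Extracts standard views from the case's coronal and sagittal streams,
#' checks diagnosability (at least `min_views` extracted views), and when
#' per-image predictions are supplied produces the ensemble severity
#' verdict. The report is a plain list serialisable to JSON.
#'
#' @param streams Named list of [sweep_stream()]s (or file paths), names
#'   `"coronal"` / `"sagittal"`.
#' @param predictions Optional [case_input()] carrying the case's image
#'   predictions and binary severity probability.
#' @param config A [run_config()].
#' @return A report list with elements `extraction` (per plane: selected
#'   views, direction, queue sizes, dropped counts), `n_views`,
#'   `diagnosable` and, when predictions are given and the case is
#'   diagnosable, `verdict`.
#' @export
run_pipeline <- function(streams, predictions = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  extraction <- list()
  selected_all <- c()
  for (plane in names(streams)) {
    s <- streams[[plane]]
    if (is.character(s)) s <- read_stream(s)
    res <- extract_views(s, config$scoring)
    sel <- res$selected[!is.na(res$selected)]
    selected_all <- c(selected_all, sel)
    extraction[[plane]] <- list(
      selected = as.list(sel), direction = res$direction,
      queue_sizes = vapply(res$queues, nrow, integer(1)),
      n_dropped = nrow(res$dropped),
      dropped = res$dropped)
  }
  n_views <- length(selected_all)
  diagnosable <- n_views >= config$min_views
  report <- list(extraction = extraction, n_views = n_views,
                 diagnosable = diagnosable)
  if (!diagnosable) {
    report$note <- sprintf(
      "not diagnosable: only %d standard view(s) extracted (minimum %d)",
      n_views, config$min_views)
  } else if (!is.null(predictions)) {
    dec <- ensemble_decision(predictions, tau = config$tau)
    report$verdict <- list(severe = dec$severe,
                           binary_severe = dec$binary_severe,
                           multilabel_severe = dec$multilabel_severe,
                           abnormal_count = dec$abnormal_count,
                           rationale = dec$rationale)
  }
  report
}

#' Write a report (any plain list) as JSON
#'
#' @param report List to serialise.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
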