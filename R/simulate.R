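#' Specification of a synthetic sweep video
#'
#' Describes the detection stream of an idealised fontanelle sweep: as the
#' probe crosses each standard plane, the confidences of that plane's
#' defining structures rise and fall following a Gaussian bump centred at
#' the planted frame. Spurious detections, confidence jitter and dropout
#' emulate detector noise.
#'
#' @param plane `"coronal"` or `"sagittal"`.
#' @param n_frames Number of frames in the sweep; default 120 (a few
#'   seconds of video at typical frame rates).
#' @param direction `"forward"` or `"reverse"` (anatomical sweep order or
#'   its reverse).
#' @param peaks Named integer vector, view label to planted frame of that
#'   standard view; defaults to evenly spaced peaks at 25/50/75% of the
#'   sweep, ordered per `direction`. Must be ordered consistently with
#'   `direction`.
#' @param profile_width Standard deviation of the Gaussian confidence bump,
#'   in frames; default 8, i.e. each standard plane stays visible for
#'   roughly 30 frames (about a second of video) as the probe crosses it.
#' @param conf_peak Peak detector confidence at the planted frame; default
#'   0.9.
#' @param fp_rate Expected spurious detections per frame (Poisson);
#'   default 0.2.
#' @param dropout_prob Probability that any true detection is dropped;
#'   default 0.1.
#' @param conf_jitter_sd Gaussian jitter of confidences; default 0.05.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(plane = "coronal", n_frames = 120,
                       direction = c("forward", "reverse"), peaks = NULL,
                       profile_width = 8, conf_peak = 0.9, fp_rate = 0.2,
                       dropout_prob = 0.1, conf_jitter_sd = 0.05, seed = 1) {
  plane <- match.arg(plane, c("coronal", "sagittal"))
  direction <- match.arg(direction)
  stopifnot(n_frames >= 10, profile_width > 0,
            conf_peak >= 0, conf_peak <= 1, fp_rate >= 0,
            dropout_prob >= 0, dropout_prob <= 1, conf_jitter_sd >= 0)
  ord <- canonical_view_order(plane)
  if (is.null(peaks)) {
    pos <- round(n_frames * c(0.25, 0.5, 0.75))
    if (direction == "reverse") pos <- rev(pos)
    peaks <- stats::setNames(as.integer(pos), ord)
  }
  stopifnot(setequal(names(peaks), ord), all(peaks >= 0),
            all(peaks < n_frames))
  seq_p <- peaks[ord]
  ok <- if (direction == "forward") all(diff(seq_p) > 0) else
    all(diff(seq_p) < 0)
  if (!ok) {
    stop("peaks must be ordered consistently with the direction",
         call. = FALSE)
  }
  structure(list(plane = plane, n_frames = as.integer(n_frames),
                 direction = direction, peaks = peaks,
                 profile_width = profile_width, conf_peak = conf_peak,
                 fp_rate = fp_rate, dropout_prob = dropout_prob,
                 conf_jitter_sd = conf_jitter_sd, seed = as.integer(seed)),
            class = "sweep_spec")
}

random_box <- function() {
  rotated_box(cx = stats::runif(1, 100, 500), cy = stats::runif(1, 100, 400),
              w = stats::runif(1, 20, 80), h = stats::runif(1, 20, 80),
              angle_deg = stats::runif(1, -90, 90))
}

#' Simulate a sweep detection stream with known ground truth
#'
#' For every view of the spec's plane and every structure required by that
#' view, per-frame confidence follows
#' `conf_peak * exp(-(t - peak)^2 / (2 * profile_width^2))` plus Gaussian
#' jitter, clipped to \[0, 1\]; detections are dropped with probability
#' `dropout_prob` and spurious detections (uniform structure from the
#' vocabulary, uniform confidence and box) are added at rate `fp_rate` per
#' frame. Detections with confidence below 0.05, the emission floor of the
#' emulated detector, are not emitted.
#'
#' @param spec A [sweep_spec()].
#' @param config A [scoring_config()] supplying the per-view required
#'   structures and the vocabulary; default [default_scoring_config()].
#' @return List with `stream` (a [sweep_stream()]) and `truth`
#'   (list with `peaks` and `direction`).
#' @export
simulate_sweep <- function(spec, config = default_scoring_config()) {
  stopifnot(inherits(spec, "sweep_spec"))
  vocab <- structure_vocabulary(config)
  views <- canonical_view_order(spec$plane)
  with_seed(spec$seed, {
    frames <- lapply(seq_len(spec$n_frames) - 1L, function(t) {
      dets <- list()
      for (v in views) {
        peak <- spec$peaks[[v]]
        bump <- spec$conf_peak *
          exp(-(t - peak)^2 / (2 * spec$profile_width^2))
        for (s in config$criteria[[v]]$required) {
          if (stats::runif(1) < spec$dropout_prob) next
          conf <- bump + stats::rnorm(1, 0, spec$conf_jitter_sd)
          conf <- min(1, max(0, conf))
          if (conf < 0.05) next
          dets[[length(dets) + 1L]] <- detection(s, conf, random_box())
        }
      }
      n_fp <- stats::rpois(1, spec$fp_rate)
      for (k in seq_len(n_fp)) {
        # detector false positives are predominantly low-confidence
        conf_fp <- stats::rbeta(1, 1.5, 5)
        if (conf_fp < 0.05) next
        dets[[length(dets) + 1L]] <- detection(
          sample(vocab, 1), conf_fp, random_box())
      }
      frame_detections(t, dets)
    })
    list(stream = sweep_stream(spec$plane, frames,
                               meta = list(seed = spec$seed)),
         truth = list(peaks = spec$peaks, direction = spec$direction))
  })
}

default_condition_prevalence <- function() {
  c(normal = 0.55, IVH_I = 0.08, IVH_II = 0.07, ependymal_cyst = 0.07,
    minor_ventricular_dilation = 0.06, IVH_III = 0.06, IVH_IV = 0.04,
    hydrocephalus = 0.03, PVL = 0.04)
}

# Mean per-image probability of each condition label, per ground-truth
# condition, on images where the lesion is visible. Severe-defining labels
# sit high (0.85+), mild/absent labels low, matching a well-trained
# classifier on clean views.
default_label_profiles <- function() {
  base <- stats::setNames(rep(0.05, 6), condition_labels())
  prof <- list()
  prof$normal <- replace(base, "normal", 0.9)
  prof$IVH_I <- replace(replace(base, "IVH", 0.85), "normal", 0.15)
  prof$IVH_II <- prof$IVH_I
  prof$IVH_III <- replace(replace(base, "IVH", 0.85),
                          "ventricular_dilation", 0.85)
  prof$IVH_IV <- replace(replace(base, "IVH", 0.9),
                         "ventricular_dilation", 0.85)
  prof$ependymal_cyst <- replace(replace(base, "ependymal_cyst", 0.85),
                                 "normal", 0.15)
  prof$minor_ventricular_dilation <-
    replace(replace(base, "ventricular_dilation", 0.85), "normal", 0.15)
  prof$hydrocephalus <- replace(replace(base, "hydrocephalus", 0.85),
                                "ventricular_dilation", 0.6)
  prof$PVL <- replace(base, "PVL", 0.85)
  prof
}

condition_findings <- function(condition) {
  if (condition == "normal") character(0) else condition
}

#' Specification of a synthetic diagnostic cohort
#'
#' @param n_cases Number of cases; default 200.
#' @param prevalence Named probability vector over ground-truth conditions
#'   (`normal`, `IVH_I` ... `IVH_IV`, `ependymal_cyst`,
#'   `minor_ventricular_dilation`, `hydrocephalus`, `PVL`); must sum to 1.
#'   The default mirrors a screening population dominated by normal and
#'   mild findings with a severe rate of 0.17.
#' @param profiles Per-condition mean image probabilities; default
#'   well-separated profiles (severe-defining labels at mean >= 0.85,
#'   absent labels at 0.05).
#' @param noise_sd Gaussian noise added to every image probability;
#'   default 0.05.
#' @param views_range Integer range of standard views per case; default
#'   4 to 6.
#' @param binary_means Mean binary-head severity probability for severe and
#'   non-severe cases; default `c(severe = 0.85, mild = 0.15)`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 200,
                        prevalence = default_condition_prevalence(),
                        profiles = default_label_profiles(),
                        noise_sd = 0.05, views_range = c(4, 6),
                        binary_means = c(severe = 0.85, mild = 0.15),
                        seed = 1) {
  stopifnot(n_cases >= 1, abs(sum(prevalence) - 1) < 1e-8,
            all(prevalence >= 0), noise_sd >= 0,
            length(views_range) == 2, views_range[1] >= 1,
            views_range[2] >= views_range[1],
            all(names(prevalence) %in% names(profiles)))
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 profiles = profiles, noise_sd = noise_sd,
                 views_range = as.integer(views_range),
                 binary_means = binary_means, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a diagnostic cohort with known ground truth
#'
#' Each case draws a ground-truth condition from the prevalence vector and
#' 4-6 standard-view images. For abnormal conditions the lesion is visible
#' on at least two images (lesion profile); the remaining images follow the
#' normal profile. All image probabilities get Gaussian noise and are
#' clipped to \[0, 1\]; the binary-head probability is drawn around the
#' severity-dependent mean. Deterministic per seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of cases, each a list with `input` (a [case_input()]),
#'   `condition` (a [case_condition()]) and `label` (0/1 via
#'   [papile_case_label()]).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  conds <- names(spec$prevalence)
  clip01 <- function(x) pmin(1, pmax(0, x))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_cases), function(i) {
      cond_name <- sample(conds, 1, prob = spec$prevalence)
      cond <- case_condition(condition_findings(cond_name))
      label <- papile_case_label(cond)
      n_views <- sample(seq(spec$views_range[1], spec$views_range[2]), 1)
      views <- sample(view_labels(), n_views)
      n_lesion <- if (cond_name == "normal") 0 else
        sample(seq(min(2, n_views), n_views), 1)
      lesion_on <- seq_len(n_views) %in% sample(n_views, n_lesion)
      images <- lapply(seq_len(n_views), function(j) {
        prof <- if (lesion_on[j]) spec$profiles[[cond_name]] else
          spec$profiles$normal
        probs <- clip01(prof + stats::rnorm(length(prof), 0, spec$noise_sd))
        image_prediction(stats::setNames(probs, names(prof)),
                         view = views[j])
      })
      mu <- if (label == 1) spec$binary_means[["severe"]] else
        spec$binary_means[["mild"]]
      bp <- clip01(mu + stats::rnorm(1, 0, spec$noise_sd))
      list(input = case_input(images, bp), condition = cond, label = label)
    })
  })
}
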