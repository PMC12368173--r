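test_that("score_frame sums base score times confidence over retained detections", {
  cfg <- toy_config(detector_conf_floor = 0.3)
  expect_equal(score_frame(make_frame(0), cfg), 0)
  fr <- make_frame(1, c("A", "B"), c(0.9, 0.5))
  expect_equal(score_frame(fr, cfg), 2 * 0.9 + 1 * 0.5)
  # below the floor the detection is ignored entirely
  fr2 <- make_frame(1, c("A", "B"), c(0.9, 0.2))
  expect_equal(score_frame(fr2, cfg), 1.8)
  # unknown structure is a configuration error naming the structure
  fr3 <- make_frame(2, "mystery", 0.9)
  expect_error(score_frame(fr3, cfg), "mystery")
})

test_that("score_frame matches a brute-force oracle on random frames", {
  cfg <- toy_config(detector_conf_floor = 0.4)
  set.seed(21)
  for (i in 1:100) {
    k <- sample(0:6, 1)
    labs <- sample(c("A", "B", "C"), k, replace = TRUE)
    confs <- runif(k)
    fr <- make_frame(i, labs, confs)
    want <- 0
    for (j in seq_len(k)) {
      if (confs[j] >= 0.4) {
        want <- want + cfg$base_scores[[labs[j]]] * confs[j]
      }
    }
    expect_equal(score_frame(fr, cfg), want)
  }
})

test_that("assign_candidates enforces plane, required and forbidden criteria", {
  cfg <- default_scoring_config()
  ahv_frame <- make_frame(5, c("anterior_horn_left", "anterior_horn_right"),
                          c(0.9, 0.9))
  cor <- sweep_stream("coronal", list(ahv_frame))
  q <- assign_candidates(cor, cfg)
  expect_equal(q$AHV$frame_index, 5L)
  expect_equal(nrow(q$TVV), 0)

  # the same detections in a sagittal stream reach no coronal queue
  sag <- sweep_stream("sagittal", list(ahv_frame))
  qs <- assign_candidates(sag, cfg)
  expect_true(all(vapply(qs, nrow, integer(1)) == 0))
  expect_false("AHV" %in% names(qs))

  # missing one required structure keeps the frame out
  half <- sweep_stream("coronal",
                       list(make_frame(5, "anterior_horn_left", 0.9)))
  expect_equal(nrow(assign_candidates(half, cfg)$AHV), 0)

  # a forbidden structure vetoes the frame
  cfg_f <- default_scoring_config()
  cfg_f$criteria$AHV$forbidden <- "third_ventricle"
  veto <- sweep_stream("coronal", list(
    make_frame(5, c("anterior_horn_left", "anterior_horn_right",
                    "third_ventricle"), c(0.9, 0.9, 0.8))))
  expect_equal(nrow(assign_candidates(veto, cfg_f)$AHV), 0)
  # ... and that frame still reaches the TVV queue
  expect_equal(assign_candidates(veto, cfg_f)$TVV$frame_index, 5L)
})

# small deterministic queues: three tight clusters at chosen frame centres
planted_queues <- function(centres, n_each = 4, score = 3) {
  views <- names(centres)
  qs <- lapply(views, function(v) {
    f <- centres[[v]] + seq_len(n_each) - 1L
    data.frame(frame_index = as.integer(f),
               score = rep(score, n_each),
               contributing = I(rep(list(NULL), n_each)))
  })
  stats::setNames(qs, views)
}

test_that("infer_scan_direction reads the cluster centroid ordering", {
  cfg <- default_scoring_config(dbscan_eps = 0.2)
  fwd <- planted_queues(c(AHV = 20L, TVV = 50L, BV = 80L))
  expect_equal(infer_scan_direction(fwd, cfg), "forward")
  rev <- planted_queues(c(AHV = 80L, TVV = 50L, BV = 20L))
  expect_equal(infer_scan_direction(rev, cfg), "reverse")
  mixed <- planted_queues(c(AHV = 50L, TVV = 20L, BV = 80L))
  expect_equal(infer_scan_direction(mixed, cfg), "unknown")
  empty <- lapply(fwd, function(q) q[0, ])
  expect_equal(infer_scan_direction(empty, cfg), "unknown")
  one <- fwd["AHV"]
  expect_equal(infer_scan_direction(one, cfg), "unknown")
})

test_that("filter_candidates drops noise and order-violating clusters with reasons", {
  cfg <- default_scoring_config(dbscan_eps = 0.15)
  qs <- planted_queues(c(AHV = 20L, TVV = 50L, BV = 80L))
  labels <- cusweep:::cluster_candidates(qs, cfg)
  flt <- filter_candidates(qs, labels, "forward")
  expect_equal(nrow(flt$dropped), 0)
  expect_equal(flt$queues, qs)

  # spurious lone high-score candidate far from its view's cluster -> noise
  qs2 <- qs
  qs2$AHV <- rbind(qs2$AHV, data.frame(frame_index = 300L, score = 9,
                                       contributing = I(list(NULL))))
  labels2 <- cusweep:::cluster_candidates(qs2, cfg)
  flt2 <- filter_candidates(qs2, labels2, "forward")
  expect_true(any(flt2$dropped$frame_index == 300 &
                    flt2$dropped$reason == "noise"))
  expect_false(300 %in% flt2$queues$AHV$frame_index)

  # BV cluster planted before AHV in a forward sweep -> dropped as "order"
  qs3 <- planted_queues(c(AHV = 40L, TVV = 60L, BV = 10L))
  labels3 <- cusweep:::cluster_candidates(qs3, cfg)
  flt3 <- filter_candidates(qs3, labels3, "forward")
  expect_true(all(flt3$dropped$view == "BV"))
  expect_true(all(flt3$dropped$reason == "order"))
  expect_equal(nrow(flt3$queues$BV), 0)
  expect_equal(nrow(flt3$queues$AHV), 4)

  # no silent loss: dropped + surviving = assigned
  n_assigned <- sum(vapply(qs3, nrow, integer(1)))
  n_left <- sum(vapply(flt3$queues, nrow, integer(1)))
  expect_equal(n_left + nrow(flt3$dropped), n_assigned)
})

test_that("select_standard_views takes the argmax with earliest-frame tie-break", {
  q <- data.frame(frame_index = c(5L, 9L, 14L), score = c(1.2, 3.4, 2.0),
                  contributing = I(rep(list(NULL), 3)))
  res <- select_standard_views(list(AHV = q))
  expect_equal(unname(res$selected["AHV"]), 9L)
  expect_true(all(is.na(res$selected[setdiff(view_labels(), "AHV")])))

  tie <- data.frame(frame_index = c(11L, 7L), score = c(2, 2),
                    contributing = I(rep(list(NULL), 2)))
  expect_equal(unname(select_standard_views(list(TVV = tie))$selected["TVV"]),
               7L)

  none <- select_standard_views(list(BV = q[0, ]))
  expect_true(is.na(none$selected["BV"]))
})

test_that("extract_views is deterministic and honest about empty streams", {
  empty <- sweep_stream("coronal",
                        lapply(0:19, function(i) frame_detections(i)))
  res <- extract_views(empty)
  expect_true(all(is.na(res$selected)))
  expect_equal(res$direction, "unknown")

  sim <- simulate_sweep(sweep_spec(plane = "sagittal", seed = 12))
  r1 <- extract_views(sim$stream)
  r2 <- extract_views(sim$stream)
  expect_identical(r1, r2)
})

test_that("selected frame dominates every surviving candidate of its view", {
  for (s in 1:5) {
    sim <- simulate_sweep(sweep_spec(
      plane = if (s %% 2) "coronal" else "sagittal", seed = s))
    res <- extract_views(sim$stream)
    for (v in names(res$queues)) {
      q <- res$queues[[v]]
      if (nrow(q) == 0) next
      sel <- res$selected[[v]]
      expect_gte(q$score[q$frame_index == sel], max(q$score) - 1e-12)
    }
  }
})

test_that("uniform scaling of base scores changes neither selection nor direction", {
  sim <- simulate_sweep(sweep_spec(plane = "coronal", seed = 31))
  cfg <- default_scoring_config()
  base <- extract_views(sim$stream, cfg)
  for (c_mult in c(0.25, 3)) {
    cfg2 <- cfg
    cfg2$base_scores <- cfg$base_scores * c_mult
    scaled <- extract_views(sim$stream, cfg2)
    expect_identical(scaled$selected, base$selected)
    expect_identical(scaled$direction, base$direction)
  }
})
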