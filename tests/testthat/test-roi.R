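test_that("default ROI layout gives five disjoint in-bounds rectangles", {
  cfg <- phantom_config()
  tmpl <- face_template(cfg)
  rois <- default_roi_set(tmpl, cfg$eye_centers)
  expect_named(rois, c("forehead", "nose", "mouth", "left_cheek",
                       "right_cheek"))
  pix <- lapply(rois, function(r) {
    expand.grid(x = r[["x0"]]:(r[["x1"]] - 1), y = r[["y0"]]:(r[["y1"]] - 1))
  })
  for (r in rois) {
    expect_true(r[["x0"]] >= 0 && r[["y0"]] >= 0)
    expect_true(r[["x1"]] <= 320 && r[["y1"]] <= 240)
    expect_true(r[["x1"]] > r[["x0"]] && r[["y1"]] > r[["y0"]])
  }
  all_pix <- do.call(rbind, pix)
  expect_equal(nrow(all_pix), nrow(unique(all_pix)))  # pairwise disjoint
})

test_that("ROI layout is equivariant with the eye pair", {
  cfg <- phantom_config()
  tmpl <- face_template(cfg)
  rois <- default_roi_set(tmpl, cfg$eye_centers)
  shifted <- default_roi_set(tmpl, cfg$eye_centers +
                               matrix(c(10, 0, 10, 0), 2, 2, byrow = TRUE))
  for (nm in names(rois)) {
    expect_equal(shifted[[nm]][c("x0", "x1")] - rois[[nm]][c("x0", "x1")],
                 c(x0 = 10, x1 = 10))
    expect_equal(shifted[[nm]][c("y0", "y1")], rois[[nm]][c("y0", "y1")])
  }
  # doubling the inter-ocular distance doubles widths/heights (within rounding)
  mid <- colMeans(cfg$eye_centers)
  wide_eyes <- sweep(sweep(cfg$eye_centers, 2, mid), 1:2, 2, "*")
  wide_eyes <- sweep(wide_eyes, 2, mid, "+")
  wide <- thermoface:::default_roi_geometry(wide_eyes, 320, 240)
  for (nm in names(rois)) {
    w1 <- rois[[nm]][["x1"]] - rois[[nm]][["x0"]]
    w2 <- wide[[nm]][["x1"]] - wide[[nm]][["x0"]]
    expect_lt(abs(w2 - 2 * w1), 2)
  }
  # eyes near the frame edge push ROIs out of bounds -> error
  edge_eyes <- matrix(c(20, 96, 76, 96), 2, 2, byrow = TRUE)
  expect_error(default_roi_set(tmpl, edge_eyes), "outside")
})

test_that("ROI series have one mean per frame and respect constants", {
  cfg <- phantom_config()
  rois <- default_roi_set(face_template(cfg), cfg$eye_centers)
  const <- thermal_sequence(replicate(5, matrix(30, 240, 320),
                                      simplify = FALSE), fps = 2)
  series <- extract_roi_series(const, rois)
  expect_length(series, 5)
  for (s in series) expect_equal(s, rep(30, 5))
})

test_that("ROI sets round-trip through JSON", {
  cfg <- phantom_config()
  rois <- default_roi_set(face_template(cfg), cfg$eye_centers)
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_set(rois, path)
  back <- read_roi_set(path)
  for (nm in names(rois)) expect_equal(back[[nm]], rois[[nm]])
  expect_error(read_roi_set({
    p <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(forehead = 1:4), p)
    p
  }), "exactly")
})

test_that("feature vectors have 48 entries and are changes, not absolutes", {
  sched <- build_default_schedule()
  n <- total_frames(sched)
  for (e in emotion_levels())
    expect_length(build_features(rep(33, n), sched, e), 48)
  # constant series -> all-zero features under baseline subtraction
  expect_equal(build_features(rep(33, n), sched, "HVLA"), rep(0, 48))
  # adding a constant to the series leaves features unchanged
  withr::with_seed(1, series <- 33 + cumsum(rnorm(n, 0, 0.01)))
  expect_equal(build_features(series + 5, sched, "LVHA"),
               build_features(series, sched, "LVHA"), tolerance = 1e-12)
  # but not with baseline subtraction off
  expect_equal(build_features(series + 5, sched, "LVHA", baseline = "none") -
                 build_features(series, sched, "LVHA", baseline = "none"),
               rep(5, 48))
  expect_error(build_features(rep(33, 10), sched, "HVLA"), "length")
})

test_that("per-segment baselining removes linear drift almost entirely", {
  sched <- build_default_schedule()
  n <- total_frames(sched)
  drift <- 0.1 * (seq_len(n) - 1) / 2 / 60   # 0.1 degC/min at 2 fps
  f <- build_features(33 + drift, sched, "HVLA")
  expect_lt(max(abs(f)), 0.02)  # residual within-window drift only
})

test_that("cohort blocks have aligned labels and the planted gap lands in its cell", {
  sched <- build_default_schedule()
  coh <- simulate_cohort_series(signal_recovery_config(), sched,
                                n_moderate = 18, n_marked = 17, seed = 2)
  blocks <- cohort_feature_matrix(coh, sched)
  expect_length(blocks, 20)
  for (b in blocks) {
    expect_equal(dim(b$values), c(35, 48))
    expect_equal(as.vector(table(b$labels)), c(18, 17))
  }
  gap <- vapply(blocks, function(b) {
    d <- colMeans(b$values[b$labels == "marked", , drop = FALSE]) -
      colMeans(b$values[b$labels == "moderate", , drop = FALSE])
    sqrt(mean(d^2))
  }, numeric(1))
  expect_equal(names(which.max(gap)), "forehead.LVHA")
})

test_that("single-subject cohorts give 1 x 48 matrices", {
  sched <- build_default_schedule()
  coh <- simulate_cohort_series(phantom_config(), sched,
                                n_moderate = 1, n_marked = 1, seed = 1)
  blocks <- cohort_feature_matrix(coh[1], sched)
  expect_equal(dim(blocks[[1]]$values), c(1, 48))
})

test_that("subject order permutes rows and labels together", {
  sched <- short_schedule()
  coh <- simulate_cohort_series(phantom_config(), sched, 3, 3, seed = 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  blocks <- cohort_feature_matrix(coh, sched)
  blocks_p <- cohort_feature_matrix(coh[perm], sched)
  for (key in names(blocks)) {
    expect_equal(blocks_p[[key]]$values, blocks[[key]]$values[perm, ])
    expect_equal(as.character(blocks_p[[key]]$labels),
                 as.character(blocks[[key]]$labels)[perm])
  }
})

test_that("registration is a no-op for jitter-free phantoms", {
  cfg <- quiet_config()
  sched <- thermoface:::new_schedule(
    data.frame(emotion = "HVLA", start_s = 0, duration_s = 3,
               image_count = 1L), fps = 2, image_duration_s = 3)
  sub <- generate_subject(cfg, sched, "moderate", seed = 4)  # 6 frames
  fixed <- build_fixed_image(sub$sequence)
  rois <- default_roi_set(fixed)
  raw <- extract_roi_series(sub$sequence, rois)
  reg <- register_sequence(sub$sequence, fast_ga(seed = 6), fixed = fixed)
  reg_series <- extract_roi_series(reg$sequence, rois)
  # features are linear in the series, so series agreement implies
  # feature agreement
  for (nm in names(raw))
    expect_lt(max(abs(reg_series[[nm]] - raw[[nm]])), 0.01)
})
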