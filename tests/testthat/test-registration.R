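test_that("binocular centers of planted eye disks are recovered within 1 px", {
  cfg <- phantom_config()
  tmpl <- face_template(cfg)
  eyes <- locate_binocular_centers(tmpl)
  # centroid of a planted uniform disk is its center, analytically
  expect_lt(max(abs(eyes - cfg$eye_centers)), 1)
  expect_lt(eyes["left", "x"], eyes["right", "x"])
  # symmetric eyes: midpoint on the planted midline column
  expect_equal(mean(eyes[, "x"]), mean(cfg$eye_centers[, 1]), tolerance = 1)
})

test_that("localization fails cleanly without two eye regions", {
  expect_error(locate_binocular_centers(matrix(30, 240, 320)),
               "localization failed")
  cfg <- phantom_config()
  one_eye <- face_template(cfg)
  # fill in the right eye
  ec <- cfg$eye_centers[2, ]
  x <- matrix(rep(0:319, each = 240), 240, 320)
  y <- matrix(rep(0:239, times = 320), 240, 320)
  one_eye[(x - ec[1])^2 + (y - ec[2])^2 <= cfg$eye_radius^2] <- cfg$face_base
  expect_error(locate_binocular_centers(one_eye), "expected exactly 2")
})

test_that("fixed image leaves canonical frames unchanged and restores shifts", {
  cfg <- phantom_config()
  tmpl <- face_template(cfg)
  seq1 <- thermal_sequence(list(tmpl), fps = 2)
  fixed <- build_fixed_image(seq1)
  expect_identical(fixed$frame, tmpl)   # already at the canonical midpoint
  expect_false(fixed$flipped)
  # shift the face +5 px in x: apply_affine with tx = -5 (pull convention)
  shifted <- apply_affine(tmpl, affine_params(tx = -5), fill = cfg$ambient)
  fixed2 <- build_fixed_image(thermal_sequence(list(shifted), fps = 2))
  mid <- colMeans(fixed2$eyes)
  expect_equal(unname(mid["x"]), 160, tolerance = 0.2)
  expect_equal(unname(mid["y"]), 96, tolerance = 0.2)
})

test_that("mirrored frames are flipped back using the lateral asymmetry", {
  cfg <- phantom_config()
  tmpl <- face_template(cfg)
  mirrored <- tmpl[, ncol(tmpl):1]
  fixed <- build_fixed_image(thermal_sequence(list(mirrored), fps = 2))
  expect_true(fixed$flipped)
  expect_equal(unname(fixed$eyes[, "x"]), cfg$eye_centers[, 1],
               tolerance = 0.5)
  never <- build_fixed_image(thermal_sequence(list(mirrored), fps = 2),
                             flip = "never")
  expect_false(never$flipped)
})

test_that("self-registration returns identity and registration is deterministic", {
  f <- blob_frame(48)
  cfg <- fast_ga(seed = 3, stage1_bounds = c(tx = 6, ty = 6, theta = 5))
  fit <- ga_affine_register(f, f, cfg)
  expect_lt(abs(fit$params$tx), 0.3)
  expect_lt(abs(fit$params$ty), 0.3)
  expect_lt(abs(fit$params$theta), 0.3)
  expect_gt(fit$fitness, -0.02)   # near the theoretical maximum (0)
  fit2 <- ga_affine_register(f, f, cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$trace, fit2$trace)
})

test_that("best fitness is non-decreasing within each GA stage (elitism)", {
  f <- blob_frame(48)
  mov <- apply_affine(f, affine_params(tx = 2, ty = 1, theta = 3), fill = 27)
  fit <- ga_affine_register(mov, f, fast_ga(seed = 9))
  expect_false(is.unsorted(fit$trace$stage1))
  expect_false(is.unsorted(fit$trace$stage2))
})

test_that("registering unrelated frames terminates and returns parameters", {
  withr::with_seed(4, {
    a <- matrix(27 + abs(rnorm(32 * 32)), 32, 32)
    b <- matrix(27 + abs(rnorm(32 * 32)), 32, 32)
  })
  fit <- ga_affine_register(a, b, fast_ga(seed = 2, generations = 10))
  expect_s3_class(fit$params, "affine_params")
  expect_length(fit$trace$stage2, 10)
})

test_that("degenerate (contrast-free) fixed images are rejected", {
  flat <- matrix(27, 32, 32)
  flat[10:20, 10:20] <- 30   # mask exists but is constant
  expect_error(ga_affine_register(flat, flat, fast_ga()), "degenerate")
})

test_that("a planted transform is recovered as its inverse", {
  cfg <- phantom_config()
  tmpl <- face_template(cfg)
  p <- affine_params(tx = 3, ty = -2, theta = 2)
  mov <- apply_affine(tmpl, p, fill = cfg$ambient)
  fit <- ga_affine_register(mov, tmpl, ga_config(seed = 21))
  inv <- affine_invert(p)
  expect_lt(abs(fit$params$tx - inv$tx), 0.5)
  expect_lt(abs(fit$params$ty - inv$ty), 0.5)
  expect_lt(abs(fit$params$theta - inv$theta), 0.5)
})

test_that("GA matches exhaustive integer-translation search on tiny frames", {
  f <- blob_frame(16)
  grid_mad <- function(mov, fix, tx, ty) {
    w <- apply_affine(mov, affine_params(tx = tx, ty = ty), fill = 27)
    msk <- face_mask(fix)
    mean(abs(w[msk] - fix[msk]))
  }
  for (shift in list(c(2, 1), c(-3, 2), c(0, -2))) {
    mov <- apply_affine(f, affine_params(tx = shift[1], ty = shift[2]),
                        fill = 27)
    # oracle: exhaustive search over integer translations
    grid <- expand.grid(tx = -4:4, ty = -4:4)
    grid$mad <- mapply(function(tx, ty) grid_mad(mov, f, tx, ty),
                       grid$tx, grid$ty)
    best <- grid[which.min(grid$mad), ]
    fit <- ga_affine_register(mov, f,
      fast_ga(seed = 7, stage1_bounds = c(tx = 4, ty = 4, theta = 1),
              stage2_bounds = c(tx = 1, ty = 1, theta = 0.5, sx = 0.01,
                                sy = 0.01, shear = 0.01)))
    expect_equal(round(fit$params$tx), best$tx)
    expect_equal(round(fit$params$ty), best$ty)
  }
})

test_that("sequence registration reduces overlap error on jittered phantoms", {
  cfg <- phantom_config(noise_sd = 0.02)
  sched <- thermoface:::new_schedule(
    data.frame(emotion = "REST", start_s = 0, duration_s = 3,
               image_count = 0L), fps = 2, image_duration_s = 3)
  sub <- generate_subject(cfg, sched, "moderate", seed = 13)  # 6 frames
  reg <- register_sequence(sub$sequence, fast_ga(seed = 5))
  expect_equal(nrow(reg$result), 6)
  expect_lt(mean(reg$result$err_after), mean(reg$result$err_before))
  expect_length(reg$sequence$frames, 6)
})

test_that("jitter-free sequences register near the identity", {
  cfg <- quiet_config()
  sched <- thermoface:::new_schedule(
    data.frame(emotion = "REST", start_s = 0, duration_s = 2,
               image_count = 0L), fps = 2, image_duration_s = 3)
  sub <- generate_subject(cfg, sched, "moderate", seed = 2)
  reg <- register_sequence(sub$sequence, fast_ga(seed = 8))
  expect_true(all(abs(reg$result$tx) < 0.5))
  expect_true(all(abs(reg$result$ty) < 0.5))
  expect_true(all(abs(reg$result$theta) < 0.5))
})
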