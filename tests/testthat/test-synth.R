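test_that("neutral template is a valid, fixed face layout", {
  f <- neutral_template()
  expect_s3_class(f, "landmark_frame")
  expect_identical(f$points, neutral_template()$points)
  u <- default_unit_map()
  ctr <- function(unit) colMeans(f$points[u[[unit]] + 1L, , drop = FALSE])
  # image convention: y grows downward; subject's left is at larger x
  expect_gt(ctr("LE")["x"], ctr("RE")["x"])
  expect_lt(ctr("LEB")["y"], ctr("LE")["y"])   # brows above eyes
  expect_lt(ctr("RE")["y"], ctr("M")["y"])     # eyes above mouth
  expect_lt(ctr("N")["y"], ctr("M")["y"])      # nose above mouth
  expect_gt(ctr("LJ")["y"], ctr("M")["y"])     # chin below mouth
})

test_that("emotion displacements act only inside the emotion's AU regions", {
  u <- default_unit_map()
  reg <- emotion_registry()
  aus <- au_registry()
  for (emo in names(reg)) {
    d <- emotion_displacement(emo, intensity = 1, displacement_scale = 1)
    expect_identical(dim(d), c(68L, 2L))
    region <- sort(unique(unlist(lapply(reg[[emo]], function(code)
      unlist(u[unlist(aus[[as.character(code)]])])))))
    outside <- setdiff(0:67, region)
    expect_true(all(d[outside + 1L, ] == 0), label = emo)
    expect_gt(sum(abs(d)), 0)
    expect_equal(emotion_displacement(emo, intensity = 0), d * 0)
    expect_equal(emotion_displacement(emo, 0.5, 10), d * 5)
  }
  # all pairs of emotions produce distinct fields
  fields <- lapply(names(reg), emotion_displacement)
  for (a in seq_along(fields)) for (b in seq_along(fields)) {
    if (a < b) expect_false(isTRUE(all.equal(fields[[a]], fields[[b]])))
  }
  expect_error(emotion_displacement("Bliss"), "unknown emotion")
})

test_that("Happy displaces mouth corners but not jaw-only landmarks", {
  d <- emotion_displacement("Happy", 1, 10)
  corners <- c(48, 54) + 1L
  expect_true(all(rowSums(abs(d[corners, ])) > 0))
  expect_true(d[49, 2] < 0)                     # corner moves up (y down)
  jaw_only <- setdiff(0:16, default_unit_map()$LJ)
  expect_true(all(d[jaw_only + 1L, ] == 0))
})

test_that("intensity ramp peaks strictly at the mid frame", {
  for (n in c(1L, 2L, 3L, 7L, 12L, 13L, 30L)) {
    r <- intensity_ramp(n)
    expect_length(r, n)
    expect_true(all(r >= 0 & r <= 1))
    expect_identical(which.max(r), as.integer(mid_positions(n)))
    expect_equal(max(r), 1)
    if (n >= 2) expect_identical(sum(r == 1), 1L)  # strict apex
  }
})

test_that("generator produces the configured counts, deterministically", {
  cfg <- synth_config(n_subjects = 4L, videos_per_class = 2L,
                      frames_per_video = 12L,
                      classes = c("Happy", "Anger", "Surprise"), seed = 5L)
  ds <- generate_synthetic(cfg)
  expect_identical(nrow(ds$manifest), 24L)        # 4 x 3 x 2 videos
  expect_identical(nrow(ds$table), 288L)          # 24 x 12 frames
  expect_setequal(unique(ds$table$label), cfg$classes)
  expect_identical(length(unique(ds$table$subject_id)), 4L)
  ds2 <- generate_synthetic(cfg)
  expect_identical(ds$table, ds2$table)
  ds3 <- generate_synthetic(synth_config(n_subjects = 4L, videos_per_class = 2L,
                                         frames_per_video = 12L,
                                         classes = cfg$classes, seed = 6L))
  expect_false(identical(ds$table, ds3$table))
})

test_that("the mid frame carries the maximum displacement in every noise-free video", {
  cfg <- synth_config(n_subjects = 2L, videos_per_class = 1L,
                      frames_per_video = 11L, noise_sd = 0, seed = 9L)
  ds <- generate_synthetic(cfg)
  for (v in table_to_videos(ds$table)) {
    onset <- v$frames[[1]]$points
    dev <- vapply(v$frames, function(f) sum((f$points - onset)^2), numeric(1))
    expect_identical(which.max(dev), as.integer(mid_positions(length(v$frames))),
                     label = v$video_id)
  }
})

test_that("noise-free, strongly displaced classes are perfectly recoverable", {
  cfg <- synth_config(n_subjects = 4L, videos_per_class = 1L,
                      frames_per_video = 6L, noise_sd = 0,
                      displacement_scale = 10, seed = 11L)
  ds <- generate_synthetic(cfg)
  rep <- run_pipeline(ds$table, scheme = "mid", graph = "facs")
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$f1, 1)
})
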