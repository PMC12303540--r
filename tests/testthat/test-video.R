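test_that("joint angles match their geometric constructions", {
  expect_equal(joint_angle(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_equal(joint_angle(c(0, 0), c(0, 1), c(1, 1)), 90)
  expect_equal(joint_angle(c(1, 0), c(0, 0), c(cos(pi / 3), sin(pi / 3))), 60)
  expect_error(joint_angle(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("joint angles are invariant to translation, scaling and rotation", {
  set.seed(6)
  for (i in 1:20) {
    a <- runif(2); b <- runif(2); c <- runif(2)
    base <- joint_angle(a, b, c)
    shift <- runif(2, -5, 5)
    expect_equal(joint_angle(a + shift, b + shift, c + shift), base,
                 tolerance = 1e-9)
    k <- runif(1, 0.1, 10)
    expect_equal(joint_angle(a * k, b * k, c * k), base, tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(joint_angle(as.numeric(R %*% a), as.numeric(R %*% b),
                             as.numeric(R %*% c)), base, tolerance = 1e-9)
  }
})

test_that("segment reference angles behave on canonical segments", {
  expect_equal(segment_reference_angle(c(0, 0), c(0, 1), "vertical"), 0)
  expect_equal(segment_reference_angle(c(0, 0), c(1, 1), "vertical"), 45)
  expect_equal(segment_reference_angle(c(0, 0), c(1, 0), "horizontal",
                                       travel_sign = 1), 0)
  expect_equal(segment_reference_angle(c(0, 0), c(1, 0), "horizontal",
                                       travel_sign = -1), 180)
  expect_error(segment_reference_angle(c(1, 1), c(1, 1), "vertical"),
               "coincident")
})

test_that("OpenPose JSON writing and parsing round-trip a sequence", {
  seq <- simulate_keypoints(posture_sim_params(seed = 8, keypoint_noise_sd = 1,
                                               walk_distance = 2))
  dir <- withr::local_tempdir()
  write_openpose_json(seq, dir)
  back <- parse_openpose_json(dir, fps = seq$fps,
                              image_height = seq$image_height)
  expect_equal(dim(back$frames), dim(seq$frames))
  expect_equal(back$frames, seq$frames, tolerance = 1e-12)
})

test_that("empty and malformed frame files follow the contract", {
  dir <- withr::local_tempdir()
  writeLines('{"people": []}', file.path(dir, "a_000000000000_keypoints.json"))
  seq <- parse_openpose_json(dir)
  expect_true(all(seq$frames[1, , 3] == 0))

  writeLines('{"people": [{"pose_keypoints_2d": [1,2,3]}]}',
             file.path(dir, "a_000000000001_keypoints.json"))
  expect_error(parse_openpose_json(dir), "25 keypoint triplets")

  writeLines('{"people": [', file.path(dir, "a_000000000001_keypoints.json"))
  err <- tryCatch(parse_openpose_json(dir), error = function(e) e)
  expect_match(conditionMessage(err), "keypoints.json")
})

test_that("multi-person frames keep the largest bounding box", {
  small <- as.numeric(t(cbind(matrix(5, 25, 2), 0.9)))
  big_m <- cbind(matrix(runif(50, 0, 500), 25, 2), 0.9)
  big <- as.numeric(t(big_m))
  dir <- withr::local_tempdir()
  jsonlite::write_json(
    list(people = list(list(pose_keypoints_2d = small),
                       list(pose_keypoints_2d = big))),
    file.path(dir, "b_000000000000_keypoints.json"),
    auto_unbox = TRUE, digits = NA)
  seq <- parse_openpose_json(dir)
  expect_equal(seq$frames[1, , 1], big_m[, 1], tolerance = 1e-9)
})

test_that("confidence filtering keeps clean frames and rejects hopeless clips", {
  seq <- simulate_keypoints(posture_sim_params(seed = 10))
  f <- filter_frames(seq)
  expect_equal(attr(f, "retained_fraction"), 1)

  seq$frames[, , 3] <- 0
  expect_error(filter_frames(seq), "insufficient frames")
})

test_that("spatiotemporal parameters recover the generator's gait", {
  res <- vapply(1:10, function(s) {
    p <- posture_sim_params(step_length = 0.65, cadence = 1.7,
                            keypoint_noise_sd = 2, seed = s)
    st <- spatiotemporal_params(simulate_keypoints(p))
    c(st$step_length, st$cadence, st$scale, st$step_speed,
      st$step_length * st$cadence)
  }, numeric(5))
  expect_equal(mean(res[1, ]), 0.65, tolerance = 0.05 / 0.65)
  expect_equal(mean(res[2, ]), 1.7, tolerance = 0.05)
  expect_equal(mean(res[3, ]), 1 / 320, tolerance = 0.01 / 320 * 320)
  # the definitional identity holds exactly
  expect_equal(res[4, ], res[5, ], tolerance = 1e-9)
})

test_that("lowering the head pitch lowers head_to_ground by the same amount", {
  base <- mean(vapply(1:6, function(s) {
    p <- posture_sim_params(head_pitch_offset = 2, keypoint_noise_sd = 2,
                            seed = 500 + s)
    extract_posture_features(simulate_keypoints(p))$head_to_ground_mean
  }, numeric(1)))
  lowered <- mean(vapply(1:6, function(s) {
    p <- posture_sim_params(head_pitch_offset = 8, keypoint_noise_sd = 2,
                            seed = 600 + s)
    extract_posture_features(simulate_keypoints(p))$head_to_ground_mean
  }, numeric(1)))
  expect_equal(base - lowered, 6, tolerance = 1)
})

test_that("angle means match generator ground truth within 2 degrees at 3 px noise", {
  errs <- vapply(1:20, function(s) {
    delta <- runif(1, 0, 12)
    calf <- runif(1, 12, 24)
    p <- posture_sim_params(head_pitch_offset = delta, calf_mean = calf,
                            calf_range = 8, keypoint_noise_sd = 3,
                            seed = 700 + s)
    pf <- extract_posture_features(simulate_keypoints(p))
    max(abs(pf$head_to_ground_mean - (135 - delta)),
        abs(pf$calf_to_vertical_mean - (180 - calf)))
  }, numeric(1))
  expect_lt(mean(errs), 2)
})

test_that("posture features expose means, variances and QC fields", {
  pf <- extract_posture_features(simulate_keypoints(posture_sim_params(seed = 12)))
  expect_true(all(c("knee_mean", "knee_var", "head_to_body_mean",
                    "head_to_ground_mean", "calf_to_vertical_mean",
                    "step_length", "step_speed",
                    "retained_frame_fraction") %in% names(pf)))
  expect_gte(pf$knee_var, 0)
  expect_true(pf$retained_frame_fraction >= 0 && pf$retained_frame_fraction <= 1)
  expect_true(pf$knee_mean >= 0 && pf$knee_mean <= 180)
})
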