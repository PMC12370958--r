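# rotating-pose builder: anus fixed, chest circles at rate deg/frame
rotating_pose <- function(n, rate_deg) {
  co <- base_coords(n)
  ang <- (0:(n - 1)) * rate_deg * pi / 180
  co[, "anus", "x"] <- 0; co[, "anus", "y"] <- 0
  co[, "chest", "x"] <- cos(ang); co[, "chest", "y"] <- sin(ang)
  pose_sequence(co)
}

test_that("turning detection integrates constant rotation exactly", {
  seq <- rotating_pose(30, 3)
  ev <- detect_turning(seq)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1L)
  # oracle: total heading change = 29 intervals x 3 deg
  expect_equal(ev$turning_angle, 87, tolerance = 1e-6)
  expect_equal(ev$turning_velocity, 90, tolerance = 1e-6)

  # right turn mirrors
  ev2 <- detect_turning(rotating_pose(30, -3))
  expect_equal(ev2$direction, -1L)
  expect_equal(ev2$turning_angle, 87, tolerance = 1e-6)

  # constant heading: no events
  expect_equal(nrow(detect_turning(make_pose(40))), 0)
})

test_that("abrupt 180-degree flips are suppressed as noise", {
  co <- base_coords(40)
  co[, "anus", c("x", "y")] <- 0
  co[, "chest", "x"] <- c(rep(1, 20), rep(-1, 20))
  co[, "chest", "y"] <- 0
  ev <- detect_turning(pose_sequence(co))
  expect_equal(nrow(ev), 0)
})

test_that("turning direction flips under reflection, angle is rotation invariant", {
  seq <- rotating_pose(40, 4)
  ev <- detect_turning(seq)
  # world-frame rotation leaves the event unchanged
  ang <- 1.1
  rot <- diag(3); rot[1:2, 1:2] <- cbind(c(cos(ang), sin(ang)),
                                         c(-sin(ang), cos(ang)))
  s2 <- seq; s2$coords <- rigid_transform(seq$coords, rot = rot)
  ev2 <- detect_turning(s2)
  expect_equal(ev2$turning_angle, ev$turning_angle, tolerance = 1e-6)
  expect_equal(ev2$direction, ev$direction)
  # reflection (y -> -y) flips the direction
  s3 <- seq; s3$coords[, , "y"] <- -s3$coords[, , "y"]
  ev3 <- detect_turning(s3)
  expect_equal(ev3$direction, -ev$direction)
  expect_equal(ev3$turning_angle, ev$turning_angle, tolerance = 1e-6)
})

test_that("rearing features follow the finite-difference oracle", {
  n <- 59
  co <- base_coords(n)
  z <- c(seq(0, 3, length.out = 30), seq(3, 0, length.out = 30)[-1])
  co[, "chest", "z"] <- z
  seq <- pose_sequence(co)
  ann <- data.frame(start_frame = 0, peak_frame = 29, end_frame = 58)
  rf <- rearing_features(seq, ann)
  expect_length(rf, 11)
  expect_equal(rf[["up_displacement"]], 3)
  expect_equal(rf[["down_displacement"]], 3)
  expect_equal(rf[["up_duration"]], 29 / 30)
  # mean ascending velocity: 3 cm over 29 intervals at 30 Hz
  expect_equal(rf[["up_vz_mean"]], (3 / 29) * 30, tolerance = 1e-9)
  expect_equal(rf[["down_vz_mean"]], -(3 / 29) * 30, tolerance = 1e-9)

  # flat chest: all zero
  rf0 <- rearing_features(make_pose(59), ann)
  expect_true(all(abs(rf0) < 1e-12 | names(rf0) %in%
                    c("up_duration", "down_duration", "total_duration")))
  expect_error(rearing_features(seq, data.frame(start_frame = 0,
                                                peak_frame = 60,
                                                end_frame = 58)), "peak")
})

test_that("strides span consecutive strikes and exclude rearing overlaps", {
  # swing flags F T T F F T T F -> swings [1,3) and [5,7), strikes 3 and 7
  ann <- data.frame(kind = "swing", foot = "r_foot",
                    start_frame = c(1, 5), peak_frame = NA,
                    end_frame = c(3, 7))
  st <- detect_strides(ann)
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start_frame, st$end_frame), c(3, 7))
  expect_equal(st$swing_start, 5)

  # a single swing yields no strides
  expect_equal(nrow(detect_strides(ann[1, ])), 0)

  # overlap with a rearing event removes the stride
  ann2 <- rbind(ann, data.frame(kind = "rearing", foot = NA,
                                start_frame = 4, peak_frame = 5,
                                end_frame = 6))
  expect_equal(nrow(detect_strides(ann2)), 0)
})

test_that("gait features have 28 descriptors with sane bounds", {
  s <- generate_session(preset("control"), duration = 120, fs = 30, seed = 31)
  gt <- gait_feature_table(s$pose, s$truth$annotations)
  expect_equal(length(attr(gt, "feature_cols")), 28)
  expect_gt(nrow(gt), 4)
  expect_true(all(gt$duty_factor >= 0 & gt$duty_factor <= 1))
  expect_true(all(gt$stride_duration > 0))
  expect_true(all(gt$regularity >= 0 & gt$regularity <= 1))
  # stride duration tracks the oscillator period (cadence = speed/3, so
  # period = 3/speed); allow one frame of slack as phase jitter shifts
  # individual crossings
  v0 <- s$truth$draws$bout_speeds
  periods <- 1 / pmin(5, pmax(1, v0 / 3))
  expect_lt(abs(stats::median(gt$stride_duration) - stats::median(periods)),
            2 / 30)
})

test_that("stride boundaries equal the ground-truth oscillator strikes", {
  s <- generate_session(preset("control"), duration = 90, fs = 30, seed = 33)
  ann <- s$truth$annotations
  st <- detect_strides(ann)
  for (ft in unique(st$foot)) {
    swings <- ann[ann$kind == "swing" & ann$foot == ft, ]
    swings <- swings[order(swings$start_frame), ]
    strikes <- swings$end_frame
    rr <- ann[ann$kind == "rearing", ]
    keep <- rep(TRUE, length(strikes) - 1)
    for (i in seq_len(length(strikes) - 1)) {
      if (nrow(rr) && any(strikes[i] < rr$end_frame &
                          rr$start_frame < strikes[i + 1])) keep[i] <- FALSE
    }
    got <- st[st$foot == ft, ]
    expect_equal(got$start_frame, strikes[-length(strikes)][keep])
    expect_equal(got$end_frame, strikes[-1][keep])
  }
})

test_that("axial bending angle reproduces the dot-product geometry", {
  n <- 320
  co <- base_coords(n)
  co[, "r_foot", c("x", "y")] <- 0; co[, "l_foot", c("x", "y")] <- 0
  co[, "nose", "x"] <- 1; co[, "nose", "y"] <- 0
  co[, "anus", "x"] <- -1; co[, "anus", "y"] <- 0
  r <- axial_bending_clips(pose_sequence(co))
  expect_equal(r$theta, rep(180, n), tolerance = 1e-9)
  expect_equal(nrow(r$clips), 0)    # no frame below 75 degrees

  co[, "nose", "y"] <- 1; co[, "anus", "y"] <- 1
  r90 <- axial_bending_clips(pose_sequence(co))
  expect_equal(r90$theta, rep(90, n), tolerance = 1e-9)

  # sustained 60-degree bend yields clips with that mean angle
  co[, "nose", c("x", "y")] <- matrix(c(1, 0), n, 2, byrow = TRUE)
  co[, "anus", c("x", "y")] <- matrix(c(cos(pi / 3), sin(pi / 3)), n, 2,
                                      byrow = TRUE)
  r60 <- axial_bending_clips(pose_sequence(co))
  expect_equal(r60$theta[1], 60, tolerance = 1e-9)
  expect_gte(nrow(r60$clips), 1)
  expect_equal(r60$clips$mean_theta, rep(60, nrow(r60$clips)),
               tolerance = 1e-9)

  # clip count is monotone nonincreasing in the flag threshold
  s <- generate_session(preset("pd_severe"), 120, 30, 41)
  n65 <- nrow(axial_bending_clips(s$pose, thresh = 65)$clips)
  n75 <- nrow(axial_bending_clips(s$pose, thresh = 75)$clips)
  n85 <- nrow(axial_bending_clips(s$pose, thresh = 85)$clips)
  expect_lte(n65, n75); expect_lte(n75, n85)
})

test_that("foot placement percentages follow body-frame geometry", {
  n <- 50
  co <- base_coords(n)
  co[, "anus", c("x", "y")] <- 0
  co[, "chest", "x"] <- 1; co[, "chest", "y"] <- 0
  # both feet strictly ahead of the anus
  co[, "r_foot", "x"] <- 0.5; co[, "l_foot", "x"] <- 0.5
  expect_equal(feet_placement_stats(pose_sequence(co))$pct_behind, 0)
  # mirrored about the anus: half behind
  co[, "r_foot", "x"] <- 0.5; co[, "l_foot", "x"] <- -0.5
  expect_equal(feet_placement_stats(pose_sequence(co))$pct_behind, 50)
  # severe PD cohort trails more than control
  ct <- generate_session(preset("control"), 200, 30, 51)
  pd <- generate_session(preset("pd_severe"), 200, 30, 52)
  expect_gt(feet_placement_stats(pd$pose)$pct_behind,
            feet_placement_stats(ct$pose)$pct_behind)
})
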