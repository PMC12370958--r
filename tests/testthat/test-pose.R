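test_that("pose files round-trip losslessly and validate their schema", {
  seq <- make_pose(100)
  seq$coords[, , ] <- seq$coords[, , ] + stats::rnorm(length(seq$coords), 0, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose(seq, path)
  back <- read_pose(path)
  expect_equal(back$n_frames, 100)
  expect_equal(ncol(pdpose:::pose_flat(back)), 27)
  expect_lt(max(abs(back$coords - seq$coords)), 1e-6)

  # empty sequence: header-only file, re-readable
  empty <- pose_sequence(array(numeric(0), dim = c(0, 9, 3)))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_pose(empty, p2)
  expect_equal(read_pose(p2)$n_frames, 0)
})

test_that("malformed pose tables are rejected with informative errors", {
  seq <- make_pose(50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose(seq, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  tab$chest_z <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, p2, row.names = FALSE)
  expect_error(read_pose(p2), "chest_z")

  tab2 <- utils::read.csv(path, check.names = FALSE)
  tab2$frame[10] <- 100L
  utils::write.csv(tab2, p2, row.names = FALSE)
  expect_error(read_pose(p2), "non-monotone")
})

test_that("short NA gaps are linearly interpolated, long gaps rejected", {
  seq <- make_pose(20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose(seq, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  tab$chest_z[6:8] <- NA            # 3-frame gap between frames 5 and 9
  tab$chest_z[5] <- 1; tab$chest_z[9] <- 5
  utils::write.csv(tab, path, row.names = FALSE)
  back <- read_pose(path)
  expect_equal(back$coords[6:8, "chest", "z"], c(2, 3, 4))

  tab$chest_z[6:11] <- NA           # 6-frame gap exceeds the limit
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_pose(path), "exceeds")
})

test_that("segment vectors follow the endpoint map and are translation invariant", {
  co <- base_coords(5)
  seq <- pose_sequence(co)
  sv <- segment_vectors(seq)
  expect_equal(dim(sv), c(5, 8, 3))
  expect_equal(sv[1, "h_body", ],
               co[1, "anus", ] - co[1, "chest", ], ignore_attr = TRUE)
  # all nodes at the origin -> zero vectors
  z <- pose_sequence(array(0, dim = c(3, 9, 3)))
  expect_true(all(segment_vectors(z) == 0))
  # rigid translation leaves segment vectors unchanged
  seq2 <- pose_sequence(rigid_transform(co, rot = diag(3), shift = c(5, 5, 5)))
  expect_equal(segment_vectors(seq2), sv, tolerance = 1e-12)
})

test_that("body frame maps world xy to anus-origin heading coordinates", {
  co <- base_coords(3)
  co[, "anus", c("x", "y")] <- 0
  co[, "chest", "x"] <- 0; co[, "chest", "y"] <- 1
  seq <- pose_sequence(co)
  bf <- body_frame(seq, 0)
  expect_false(bf$degenerate)
  expect_equal(as.numeric(to_body_frame(bf, c(0, -0.5))), c(-0.5, 0))
  expect_equal(as.numeric(to_body_frame(bf, c(0, 0))), c(0, 0))

  # whole-body rotation leaves body-frame coordinates unchanged
  ang <- pi / 2
  rot <- diag(3); rot[1:2, 1:2] <- cbind(c(cos(ang), sin(ang)),
                                         c(-sin(ang), cos(ang)))
  seq2 <- pose_sequence(rigid_transform(co, rot = rot))
  p1 <- to_body_frame(body_frame(seq, 1), co[2, "r_foot", c("x", "y")])
  p2 <- to_body_frame(body_frame(seq2, 1),
                      seq2$coords[2, "r_foot", c("x", "y")])
  expect_equal(p1, p2, tolerance = 1e-9)

  # coincident anus/chest in xy is flagged degenerate
  co[, "chest", c("x", "y")] <- 0
  expect_true(body_frame(pose_sequence(co), 0)$degenerate)
})

test_that("inter-node distances are invariant to random rigid transforms", {
  set.seed(11)
  co <- base_coords(4)
  co[, , ] <- co[, , ] + stats::rnorm(length(co))
  d0 <- sqrt(rowSums((co[, "r_hand", ] - co[, "l_hand", ])^2))
  for (i in 1:5) {
    co2 <- rigid_transform(co, shift = stats::rnorm(3, 0, 10))
    d1 <- sqrt(rowSums((co2[, "r_hand", ] - co2[, "l_hand", ])^2))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("annotation tables are validated", {
  ann <- data.frame(kind = "rearing", foot = NA, start_frame = 10,
                    peak_frame = 5, end_frame = 20)
  expect_error(pdpose:::validate_annotations(ann), "peak")
  ann2 <- data.frame(kind = "swing", foot = NA, start_frame = 1,
                     peak_frame = NA, end_frame = 5)
  expect_error(pdpose:::validate_annotations(ann2), "foot")
  ok <- data.frame(kind = "swing", foot = "r_foot", start_frame = 1,
                   peak_frame = NA, end_frame = 5)
  expect_silent(pdpose:::validate_annotations(ok, n_frames = 10))
  expect_error(pdpose:::validate_annotations(ok, n_frames = 4), "outside")
})
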