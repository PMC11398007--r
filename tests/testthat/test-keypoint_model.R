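test_that("joint roster is a 25-entry bijection", {
  nm <- joint_names()
  expect_length(nm, 25)
  expect_equal(anyDuplicated(nm), 0)
  expect_equal(joint_id(joint_name(0:24)), 0:24)
  expect_error(joint_id("kneecap"), class = "gait_validation_error")
  expect_error(joint_name(25), class = "gait_validation_error")
})

test_that("constructor validates timestamps, quality and completeness", {
  s <- make_series(3)
  df <- as.data.frame(s)[, c("t", "joint", "x", "y", "quality")]
  # colliding timestamps (two frames collapse onto one)
  bad <- df
  bad$t[bad$t == max(bad$t)] <- 1 / 60
  expect_error(keypoint_series(bad), class = "gait_validation_error")
  # quality out of range
  bad <- df; bad$quality[1] <- 1.5
  expect_error(keypoint_series(bad), class = "gait_validation_error")
  # non-finite coordinates need quality 0
  bad <- df; bad$x[3] <- NA
  expect_error(keypoint_series(bad), class = "gait_validation_error")
  bad$quality[3] <- 0
  expect_s3_class(keypoint_series(bad), "keypoint_series")
  # duplicated joint within a frame
  bad <- df; bad$joint[1:2] <- "nose"
  expect_error(keypoint_series(bad), class = "gait_validation_error")
})

test_that("jsonl and csv round trips are lossless to 1e-6 px", {
  s <- make_series(100, seed = 4)
  # plant one missing keypoint
  s$quality[77] <- 0
  s$x[77] <- NA_real_
  s$y[77] <- NA_real_
  for (dialect in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_keypoint_series(s, path, dialect = dialect)
    r <- read_keypoint_series(path, dialect = dialect)
    expect_equal(n_frames(r), 100)
    ok <- s$quality > 0
    expect_lt(max(abs(r$x[ok] - s$x[ok])), 1e-6 + 1e-12)
    expect_lt(max(abs(r$y[ok] - s$y[ok])), 1e-6 + 1e-12)
    expect_lt(max(abs(r$t - s$t)), 1e-6 + 1e-12)
    expect_equal(r$joint, s$joint)
    # missing sentinel preserved
    expect_equal(r$quality[77], 0)
    expect_true(is.na(r$x[77]))
  }
})

test_that("a 2-frame jsonl fixture parses to 2 frames x 25 keypoints", {
  s <- make_series(2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_keypoint_series(s, path, "jsonl")
  expect_length(readLines(path), 2)
  r <- read_keypoint_series(path, "jsonl")
  expect_equal(n_frames(r), 2)
  expect_equal(nrow(r), 50)
})

test_that("empty series round trips through both dialects", {
  s <- make_series(0)
  for (dialect in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_keypoint_series(s, path, dialect = dialect)
    r <- read_keypoint_series(path, dialect = dialect)
    expect_equal(n_frames(r), 0)
  }
  # csv keeps its header even when empty
  path <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_series(s, path, "csv")
  expect_match(readLines(path)[1], "t,joint,x,y,quality")
})

test_that("malformed files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,joint,x,y", "0,nose,1,2"), path)  # missing quality
  expect_error(read_keypoint_series(path, "csv"),
               class = "gait_format_error")

  path2 <- withr::local_tempfile(fileext = ".jsonl")
  s <- make_series(3)
  write_keypoint_series(s, path2, "jsonl")
  lines <- readLines(path2)
  lines[2] <- substr(lines[2], 1, 40)  # truncated JSON on line 2
  writeLines(lines, path2)
  expect_error(read_keypoint_series(path2, "jsonl"), "line 2",
               class = "gait_format_error")

  # unknown joint name
  df <- as.data.frame(make_series(2))[, c("t", "joint", "x", "y", "quality")]
  df$joint[1] <- "tail"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path3, row.names = FALSE)
  expect_error(read_keypoint_series(path3, "csv"),
               class = "gait_validation_error")

  # non-monotone timestamps in the file
  s3 <- make_series(3)
  path4 <- withr::local_tempfile(fileext = ".jsonl")
  write_keypoint_series(s3, path4, "jsonl")
  lines <- readLines(path4)
  writeLines(lines[c(1, 3, 2)], path4)
  expect_error(read_keypoint_series(path4, "jsonl"),
               class = "gait_validation_error")
})

test_that("fill_missing interpolates short gaps linearly and tags them", {
  s <- make_series(8)
  # plant a 2-frame gap in l_knee x: frames 3,4 between known values
  col <- which(s$joint == "l_knee")
  s$x[col[3:4]] <- NA; s$y[col[3:4]] <- NA; s$quality[col[3:4]] <- 0
  s$x[col[2]] <- 10; s$x[col[5]] <- 16
  filled <- fill_missing(s, max_gap_frames = 3)
  fc <- which(filled$joint == "l_knee")
  expect_equal(filled$x[fc[3:4]], c(12, 14))
  expect_true(all(filled$interpolated[fc[3:4]]))
  expect_gt(min(filled$quality[fc[3:4]]), 0)
})

test_that("gaps longer than max_gap_frames stay missing", {
  s <- make_series(10)
  col <- which(s$joint == "r_ankle")
  gap <- 3:6  # 4-frame gap
  s$x[col[gap]] <- NA; s$y[col[gap]] <- NA; s$quality[col[gap]] <- 0
  filled <- fill_missing(s, max_gap_frames = 3)
  fc <- which(filled$joint == "r_ankle")
  expect_true(all(filled$quality[fc[gap]] == 0))
  expect_true(all(is.na(filled$x[fc[gap]])))
})

test_that("fill_missing is the identity on complete series and never
          touches observed keypoints", {
  s <- make_series(12, seed = 7)
  expect_identical(fill_missing(s, 3), s)
  for (seed in 1:3) {
    set.seed(seed)
    s2 <- make_series(20, seed = seed)
    drop <- sample(nrow(s2), 30)
    s2$quality[drop] <- 0
    s2$x[drop] <- NA; s2$y[drop] <- NA
    filled <- fill_missing(s2, 3)
    obs <- s2$quality > 0
    expect_identical(filled$x[obs], s2$x[obs])
    expect_identical(filled$y[obs], s2$y[obs])
    expect_identical(filled$quality[obs], s2$quality[obs])
  }
})
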