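test_that("weighted spike values follow the threshold-sum closed form", {
  # brute-force oracle: sum the thresholds cleared by the intensity change
  eps <- c(1, 2, 4, 8, 16, 32)
  oracle <- function(p_diff) sum(eps[eps <= p_diff]) / sum(eps)
  for (p in c(0, 3, 5, 7, 15, 31, 32, 200)) {
    prev <- matrix(0, 3, 3)
    curr <- prev
    curr[2, 2] <- p
    ws <- weighted_spike_frame(prev, curr)
    expect_equal(ws$wspike[2, 2], oracle(p))
  }
  # saturation: P_diff >= 32 clears every threshold, spikes at any theta
  prev <- matrix(0, 2, 2)
  curr <- matrix(40, 2, 2)
  ws <- weighted_spike_frame(prev, curr,
                             encoder_params(binarize_theta = 1))
  expect_equal(ws$wspike, matrix(1, 2, 2))
  expect_equal(ws$spikes, matrix(1L, 2, 2))
})

test_that("static scenes produce no spikes and errors are informative", {
  fr <- matrix(runif(100, 0, 255), 10, 10)
  ws <- weighted_spike_frame(fr, fr)
  expect_equal(sum(ws$wspike), 0)
  expect_equal(sum(ws$spikes), 0)
  expect_error(weighted_spike_frame(fr, matrix(0, 5, 5)),
               class = "dar_argument_error")
  expect_error(weighted_spike_frame(array(0, c(2, 2, 3)), fr),
               regexp = "grayscale")
})

test_that("encoding yields T-1 ordered frames and is one-sided in time", {
  frames <- array(0, dim = c(8, 8, 5))
  frames[3, 3, 3] <- 100  # single brightening then darkening event
  sv <- encode_video(frames)
  expect_equal(dim(sv$frames)[3], 4)
  # brightening edge spikes at transition 2->3 only; the darkening 3->4
  # transition is invisible to the signed rule
  expect_equal(sv$frames[3, 3, 2], 1L)
  expect_equal(sv$frames[3, 3, 3], 0L)

  # played backwards, the same scene spikes at the mirrored transition:
  # forward and reverse encodings differ
  rev_frames <- frames[, , 5:1]
  sv_rev <- encode_video(rev_frames)
  expect_false(identical(sv$frames, sv_rev$frames[, , 4:1]))

  expect_error(encode_video(frames[, , 1, drop = FALSE]),
               class = "dar_argument_error")
})

test_that("moving-edge spikes stay within the object's dilated footprint", {
  # 10x10 bright square translating 1 px/frame over a uniform background
  frames <- array(20, dim = c(40, 60, 6))
  for (t in 1:6) frames[16:25, (20 + t):(29 + t), t] <- 150
  sv <- encode_video(frames)
  for (t in 1:5) {
    act <- which(sv$frames[, , t] == 1, arr.ind = TRUE)
    expect_gt(nrow(act), 0)
    expect_true(all(act[, 1] >= 15 & act[, 1] <= 26))
    expect_true(all(act[, 2] >= 20 + t & act[, 2] <= 30 + t + 1))
  }
})

test_that("centre of gravity averages active pixels and defaults to the image centre", {
  fr <- matrix(0L, 30, 50)
  expect_equal(unname(center_of_gravity(fr)), c(26, 16))  # empty -> centre

  fr[20, 10] <- 1L
  expect_equal(unname(center_of_gravity(fr)), c(10, 20))

  fr2 <- matrix(0L, 30, 50)
  fr2[1, 1] <- 1L
  fr2[11, 11] <- 1L
  expect_equal(unname(center_of_gravity(fr2)), c(6, 6))

  # ring of active pixels centred at (25, 15): direct averaging oracle
  fr3 <- matrix(0L, 30, 50)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  xs <- round(25 + 8 * cos(th)); ys <- round(15 + 8 * sin(th))
  fr3[cbind(ys, xs)] <- 1L
  idx <- which(fr3 == 1, arr.ind = TRUE)
  expect_equal(unname(center_of_gravity(fr3)),
               c(round(mean(idx[, 2])), round(mean(idx[, 1]))))
  expect_equal(unname(center_of_gravity(fr3)), c(25, 15))
})

test_that("CRLTB scans are bb-sized, CoG-centred and stride-shifted", {
  params <- encoder_params(bb_size = 11, stride = 3)
  frames <- array(0, dim = c(40, 60, 4))
  for (t in 1:4) frames[18:22, (25 + t):(29 + t), t] <- 200
  sv <- encode_video(frames, params)
  ss <- extract_scans(sv, params)
  expect_setequal(names(ss$scans), c("C", "R", "L", "T", "B"))
  for (key in names(ss$scans)) {
    expect_equal(dim(ss$scans[[key]])[1:2], c(11, 11))
  }
  # default stride is half the centre-to-edge distance of the 41-box
  expect_equal(encoder_params()$stride, 10)
  expect_equal(encoder_params()$stride, (41 - 1) / 2 / 2)

  # activity well inside the C window: shifted scans see subsets of C's
  # active pixels at shifted coordinates
  t <- 2
  g <- ss$cog_track[t, ]
  c_act <- sum(ss$scans$C[, , t])
  expect_gt(c_act, 0)
  for (key in c("R", "L", "T", "B")) {
    expect_lte(sum(ss$scans[[key]][, , t]), c_act)
  }
  # R scan at offset +stride: content equals C content shifted by stride
  shift <- params$stride
  expect_equal(ss$scans$R[, 1:(11 - shift), t],
               ss$scans$C[, (1 + shift):11, t])
})

test_that("empty videos give centre-fixated all-zero scans", {
  sv <- encode_video(array(7, dim = c(30, 30, 5)))
  ss <- extract_scans(sv, encoder_params(bb_size = 11, stride = 3))
  expect_equal(sum(vapply(ss$scans, sum, 0)), 0)
  expect_true(all(ss$cog_track[, "x_g"] == 16))
  expect_true(all(ss$cog_track[, "y_g"] == 16))
})

test_that("translation of the scene shifts the CoG but not the C-scan content", {
  params <- encoder_params(bb_size = 11, stride = 3)
  base <- array(0, dim = c(50, 70, 3))
  base[20:24, 30:34, 2] <- 120
  base[20:24, 31:35, 3] <- 120
  shifted <- array(0, dim = c(50, 70, 3))
  shifted[26:30, 37:41, 2] <- 120   # same scene moved by (+7, +6)
  shifted[26:30, 38:42, 3] <- 120
  ss1 <- extract_scans(encode_video(base, params), params)
  ss2 <- extract_scans(encode_video(shifted, params), params)
  expect_equal(ss2$cog_track[, "x_g"] - ss1$cog_track[, "x_g"], c(7, 7))
  expect_equal(ss2$cog_track[, "y_g"] - ss1$cog_track[, "y_g"], c(6, 6))
  expect_identical(ss1$scans$C, ss2$scans$C)
})

test_that("deletion rules match a brute-force application on a constructed fixture", {
  params <- encoder_params(bb_size = 5, stride = 1,
                           min_active_frac = 0.08, max_active_frac = 0.75)
  h <- 10; w <- 10
  # construct 10 spike frames directly with known active counts
  sv <- structure(list(frames = array(0L, dim = c(h, w, 10))),
                  class = "spike_video")
  counts <- c(0, 5, 99, 20, 30, 12, 80, 25, 8, 16)
  withr::with_seed(99, {
    for (t in 1:10) {
      sv$frames[, , t][sample.int(h * w, counts[t])] <- 1L
    }
  })
  ss <- extract_scans(sv, params)
  filtered <- delete_bad_frames(ss, sv, params)

  # brute force, rule by rule
  frac <- counts / (h * w)
  bad1 <- which(frac < 0.08 | frac > 0.75)
  keep1 <- setdiff(1:10, bad1)
  c_counts <- apply(ss$scans$C, 3, sum)
  mean_c <- mean(c_counts[keep1])
  expect_equal(filtered$deleted_frames$C, bad1)
  for (key in c("R", "L", "T", "B")) {
    s_counts <- apply(ss$scans[[key]], 3, sum)
    bad2 <- keep1[abs(c_counts[keep1] - s_counts[keep1]) > mean_c]
    expect_equal(filtered$deleted_frames[[key]], sort(union(bad1, bad2)))
    expect_equal(dim(filtered$scans[[key]])[3], 10 - length(union(bad1, bad2)))
  }
  # rule 2 never removes additional frames from the C stream
  expect_equal(dim(filtered$scans$C)[3], length(keep1))
})

test_that("whole-frame flashes and empty frames are deleted by the activity bounds", {
  params <- encoder_params(bb_size = 5, stride = 1)
  sv <- structure(list(frames = array(0L, dim = c(10, 10, 3))),
                  class = "spike_video")
  sv$frames[, , 2][1:80] <- 1L   # 80 % active: flash
  ss <- extract_scans(sv, params)
  filtered <- delete_bad_frames(ss, sv, params)
  # frame 2 trips the 75 % bound; frames 1 and 3 are empty (< 8 %)
  expect_equal(filtered$deleted_frames$C, 1:3)
  expect_equal(dim(filtered$scans$C)[3], 0)
})

test_that("scan inputs flatten to X x T binary matrices", {
  params <- encoder_params(bb_size = 11, stride = 3, min_active_frac = 0)
  frames <- array(0, dim = c(30, 30, 4))
  frames[10:12, 10:12, 2] <- 90
  frames[14:16, 14:16, 3] <- 90
  ss <- video_to_scans(frames, params)
  inp <- scan_input(ss, "C")
  expect_equal(nrow(inp), 121)
  expect_true(all(inp %in% c(0L, 1L)))
})
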