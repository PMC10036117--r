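spec_l <- build_maze("landmark", 1.70)

# hand-built trial: a pose stream following given waypoints at given speed,
# starting inside the departure circle of `start_arm`
manual_trial <- function(spec, start_arm, waypoints, speed = 1,
                         pause = 0, phase = "test", hz = 30) {
  dep <- arm_end(spec, start_arm)
  start <- dep - arm_axis(spec, start_arm) * 0.29
  pts <- rbind(start, waypoints)
  seg <- diff(pts)
  len <- sum(sqrt(rowSums(seg^2)))
  dt <- 1 / hz
  t_walk <- seq(0, len / speed, by = dt)
  st <- t_walk * speed
  xy <- ymazenav:::resample_polyline(pts, st)
  if (pause > 0) {
    n_p <- round(pause * hz)
    xy <- rbind(matrix(rep(start, n_p), ncol = 2, byrow = TRUE), xy)
  }
  tt <- (seq_len(nrow(xy)) - 1) * dt
  structure(list(phase = phase, start_arm = start_arm, height = 1.70,
                 pose = data.frame(t = tt, x = xy[, 1], y = xy[, 2],
                                   yaw = 0),
                 gaze = NULL, end_event = "stopped_at_endpoint",
                 truth = NULL),
            class = "trial_record")
}

test_that("segmentation splits at the departure-circle exit", {
  # stationary 10 s then a walk out: orientation recovers the pause
  tr <- manual_trial(spec_l, "B", arm_end(spec_l, "C"), pause = 10)
  seg <- segment_trial(tr, spec_l)
  expect_equal(diff(seg$orientation), 10, tolerance = 1.5 / 30)
  expect_equal(seg$navigation[2], max(tr$pose$t))

  # an agent that never moves: whole trial is orientation
  still <- manual_trial(spec_l, "B", arm_end(spec_l, "B") -
                          arm_axis(spec_l, "B") * 0.29, pause = 2)
  seg2 <- segment_trial(still, spec_l)
  expect_null(seg2$navigation)
  expect_true(is.na(seg2$exit_index))

  # starting outside the circle is a protocol violation
  bad <- manual_trial(spec_l, "B", arm_end(spec_l, "C"))
  bad$pose$x <- bad$pose$x + 1
  expect_error(segment_trial(bad, spec_l), "departure circle")

  # simulator ground truth: latent pause recovered within a sample or two
  set.seed(9)
  for (i in 1:5) {
    p <- agent_profile("young", "allocentric_map",
                       orientation_pause = c(2 + i, 0.5))
    trs <- simulate_trial(spec_l, p, "B", "test")
    segs <- segment_trial(trs, spec_l)
    expect_equal(diff(segs$orientation), trs$truth$pause, tolerance = 2 / 30)
  }
})

test_that("metrics match hand-computed values on straight and zig-zag paths", {
  # straight 2 m at 1 m/s into the goal arm (from just outside C's endpoint)
  tr <- manual_trial(spec_l, "B", arm_end(spec_l, "C"), speed = 1, pause = 3)
  m <- compute_metrics(tr, spec_l, subject_height = 2)
  seg_len <- sum(sqrt(rowSums(diff(rbind(
    arm_end(spec_l, "B") - arm_axis(spec_l, "B") * 0.29,
    arm_end(spec_l, "C")))^2)))
  # navigation runs from the departure-circle exit (0.01 m past the start
  # point, which sits 0.29 m inside the circle) to the first endpoint-disk
  # entry (0.4 m before C's end)
  expect_equal(m$traveled_distance, seg_len - 0.01 - 0.4, tolerance = 0.05)
  expect_equal(m$average_speed, 1, tolerance = 0.02)
  expect_equal(m$normalized_speed, 0.5, tolerance = 0.01)
  expect_equal(m$escape_latency,
               m$orientation_duration + m$navigation_duration)
  expect_equal(m$first_endpoint, "C")
  expect_false(m$incomplete)

  # zig-zag polyline: traveled distance equals the hand-summed length
  z1 <- c(0.1, 0.5); z2 <- c(-0.1, 0.9); z3 <- c(0.1, 1.3)
  wp <- rbind(z1, z2, z3, arm_end(spec_l, "C"))
  trz <- manual_trial(spec_l, "B", wp, speed = 0.8)
  mz <- compute_metrics(trz, spec_l, subject_height = 1.7)
  start <- arm_end(spec_l, "B") - arm_axis(spec_l, "B") * 0.29
  poly <- rbind(start, wp)
  hand <- sum(sqrt(rowSums(diff(poly)^2)))
  expect_equal(mz$traveled_distance, hand - 0.01 - 0.4, tolerance = 0.06)

  # a trial that never leaves the start is flagged, not zeroed
  still <- manual_trial(spec_l, "B", arm_end(spec_l, "B") -
                          arm_axis(spec_l, "B") * 0.29, pause = 1)
  ms <- compute_metrics(still, spec_l, 1.7)
  expect_true(ms$incomplete)
  expect_true(is.na(ms$traveled_distance))
})

test_that("first endpoint follows the 0.4 m disk rule", {
  # B -> center -> C
  tr <- manual_trial(spec_l, "B", arm_end(spec_l, "C"))
  expect_equal(first_endpoint(tr, spec_l), "C")
  # grazing within 0.39 m of A's center then on to C still counts as A
  graze <- arm_end(spec_l, "A") - arm_axis(spec_l, "A") * 0.39
  tr2 <- manual_trial(spec_l, "B", rbind(graze, c(0, 0), arm_end(spec_l, "C")))
  expect_equal(first_endpoint(tr2, spec_l), "A")
  # stationary trial: none
  still <- manual_trial(spec_l, "B", arm_end(spec_l, "B") -
                          arm_axis(spec_l, "B") * 0.29, pause = 1)
  expect_equal(first_endpoint(still, spec_l), "none")
})

test_that("learning success requires reaching C without entering arm B", {
  direct <- manual_trial(spec_l, "A", arm_end(spec_l, "C"), phase = "learning")
  expect_true(learning_success(direct, spec_l))
  # partway into B and back: failure
  into_B <- arm_axis(spec_l, "B") * 1.2
  detour <- manual_trial(spec_l, "A", rbind(into_B, c(0, 0), arm_end(spec_l, "C")),
                         phase = "learning")
  expect_false(learning_success(detour, spec_l))
  # re-entering the start arm A is allowed by the stated rule
  back_A <- arm_axis(spec_l, "A") * 1.2
  wander <- manual_trial(spec_l, "A", rbind(c(0, 0), back_A, c(0, 0),
                                            arm_end(spec_l, "C")),
                         phase = "learning")
  expect_true(learning_success(wander, spec_l))
  expect_error(learning_success(manual_trial(spec_l, "B", arm_end(spec_l, "C")),
                                spec_l), "learning")
})

test_that("trials-to-criterion agrees with a brute-force scan oracle", {
  expect_equal(trials_to_criterion(rep(TRUE, 4)), 4L)
  expect_equal(trials_to_criterion(c(TRUE, FALSE, rep(TRUE, 4))), 6L)
  expect_equal(trials_to_criterion(c(FALSE, FALSE, FALSE, rep(TRUE, 4))), 7L)
  expect_warning(trials_to_criterion(c(TRUE, TRUE, TRUE)), "never met")

  # oracle: first index i such that flags[i-3..i] are all TRUE
  oracle <- function(flags) {
    for (i in 4:length(flags)) {
      if (all(flags[(i - 3):i])) return(i)
    }
    NA_integer_
  }
  for (len in 4:7) {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), len))
    for (r in seq_len(nrow(grid))) {
      flags <- unlist(grid[r, ])
      if (!all(flags[(len - 3):len])) next
      expect_identical(trials_to_criterion(flags), oracle(flags))
    }
  }
})

test_that("probe-trial and subject-level strategy classification", {
  allo <- manual_trial(spec_l, "B", arm_end(spec_l, "C"))
  ego <- manual_trial(spec_l, "B", arm_end(spec_l, "A"))
  expect_equal(classify_probe_trial(allo, spec_l), "allocentric")
  expect_equal(classify_probe_trial(ego, spec_l), "egocentric")
  # returns to its own start arm: unclassifiable
  back <- manual_trial(spec_l, "B", rbind(c(0, 0), arm_end(spec_l, "B")))
  expect_equal(classify_probe_trial(back, spec_l), "unclassifiable")
  expect_error(classify_probe_trial(manual_trial(spec_l, "A", arm_end(spec_l, "C")),
                                    spec_l), "B-start")

  expect_equal(subject_strategy(c("allocentric", "allocentric", "egocentric")),
               "allocentric")
  expect_equal(subject_strategy(c("allocentric", "egocentric", "egocentric")),
               "egocentric")
  expect_equal(subject_strategy(rep("allocentric", 3)), "allocentric")
  expect_equal(subject_strategy(c("unclassifiable", "unclassifiable",
                                  "allocentric")), "unclassifiable")
  expect_equal(subject_strategy(c("unclassifiable", "egocentric",
                                  "egocentric")), "egocentric")
  expect_error(subject_strategy(c("allocentric", "egocentric")), "three")
})

test_that("strategy recovery is exact on simulated cohorts", {
  prof <- list(
    young = list(landmark = list(
      list(profile = agent_profile("young", "allocentric_map",
                                   p_allocentric_choice = 1), weight = 1))),
    older = list(landmark = list(
      list(profile = agent_profile("older", "egocentric",
                                   p_allocentric_choice = 0), weight = 1))))
  cfg <- sim_config(data.frame(age_group = c("young", "older"),
                               condition = "landmark", n = 4L,
                               stringsAsFactors = FALSE),
                    profiles = prof, seed = 77L, streams = "pose")
  co <- simulate_cohort(cfg)
  met <- cohort_metrics(co)
  ct <- cohort_table(met)
  merged <- merge(ct, co$subjects[, c("subject_id", "strategy")],
                  by = "subject_id", suffixes = c("", "_truth"))
  expect_equal(nrow(merged), 8L)
  expect_equal(merged$strategy,
               ifelse(merged$strategy_truth == "egocentric",
                      "egocentric", "allocentric"))
  # additivity of escape latency on every complete trial
  done <- met[!met$incomplete, ]
  expect_equal(done$escape_latency,
               done$orientation_duration + done$navigation_duration,
               tolerance = 1e-10)
})

test_that("sketch scoring checks shape, order (up to rotation), placement, goal", {
  perfect <- list(shape = "Y",
                  landmarks = c("star", "square", "circle"),
                  order = spec_l$landmarks$label[order(spec_l$landmarks$azimuth)],
                  placement = rep("between", 3),
                  goal_facing = "square")
  s <- score_sketch(perfect, spec_l)
  expect_true(all(unlist(s)))

  # all rotations of the true cyclic order are correct; both mirrored
  # orders (enumerated) are not
  true_ccw <- as.character(perfect$order)
  for (k in 0:2) {
    rot <- true_ccw[(0:2 + k) %% 3 + 1]
    sk <- perfect; sk$order <- rot
    expect_true(score_sketch(sk, spec_l)$order_correct)
    mir <- rev(rot)
    skm <- perfect; skm$order <- mir
    expect_false(score_sketch(skm, spec_l)$order_correct)
  }

  at_ends <- perfect; at_ends$placement <- c("between", "end", "between")
  expect_false(score_sketch(at_ends, spec_l)$placement_correct)

  wrong_goal <- perfect; wrong_goal$goal_facing <- "circle"
  expect_false(score_sketch(wrong_goal, spec_l)$goal_correct)

  wrong_shape <- perfect; wrong_shape$shape <- "T"
  expect_false(score_sketch(wrong_shape, spec_l)$shape_correct)

  expect_error(score_sketch(list(shape = "Y"), spec_l), "malformed")
  expect_error(score_sketch(perfect, build_maze("geometry", 1.7)), "landmark")
})
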