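# Seeded agent-based simulator: cohorts of navigating agents with known
# ground-truth strategy profiles, emitting 30 Hz head-pose and 120 Hz
# binocular gaze streams with the statistical structure the analysis assumes
# (group-dependent allocentric choice probabilities, state-dependent gaze
# elevation, 22-27% gaze missingness, walking-speed/pause variability).

POSE_HZ <- 30
GAZE_HZ <- 120

#' Define an agent profile
#'
#' An agent profile holds the latent parameters of one simulated navigator:
#' its strategy type (egocentric; allocentric map-based; allocentric
#' view-matching, which re-fixates the circle landmark at the junction and
#' dwells there), the per-trial probability of an allocentric probe response,
#' a learning error rate, locomotion parameters, state-dependent gaze
#' elevation distributions, and the gaze missingness rate.
#'
#' @param age_group `"children"`, `"young"` or `"older"`.
#' @param strategy `"egocentric"`, `"allocentric_map"` or
#'   `"allocentric_viewmatch"`.
#' @param p_allocentric_choice Per-probe-trial probability of choosing the
#'   goal arm C from start B.
#' @param learning_error_rate Probability that a learning trial fails (the
#'   agent detours into arm B before the goal).
#' @param walk_speed `c(mean, sd)` walking speed, m/s.
#' @param orientation_pause `c(mean, sd)` initial stationary pause, s.
#' @param center_dwell_extra Extra junction dwell (s) inserted by
#'   view-matching agents on probe trials.
#' @param gaze_state_elevations Named list with `c(mean, sd)` gaze elevation
#'   (degrees) for the states `orient_sky`, `orient_floor`, `navigate_walls`.
#' @param missing_rate Per-gaze-sample probability of a missing (invalid)
#'   sample; typical empirical rates are 0.22-0.27.
#' @param missing_mode `"iid"` (independent Bernoulli per sample) or
#'   `"burst"` (two-state Markov run-length model with the same stationary
#'   rate, emulating blink bursts).
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(age_group = c("young", "children", "older"),
                          strategy = c("allocentric_map", "egocentric",
                                       "allocentric_viewmatch"),
                          p_allocentric_choice = 0.9,
                          learning_error_rate = 0.1,
                          walk_speed = c(0.75, 0.12),
                          orientation_pause = c(3, 1),
                          center_dwell_extra = 8,
                          gaze_state_elevations = list(
                            orient_sky = c(28, 7),
                            orient_floor = c(-22, 7),
                            navigate_walls = c(-4, 6)),
                          missing_rate = 0.25,
                          missing_mode = c("iid", "burst")) {
  age_group <- match.arg(age_group)
  strategy <- match.arg(strategy)
  missing_mode <- match.arg(missing_mode)
  stopifnot(p_allocentric_choice >= 0, p_allocentric_choice <= 1,
            learning_error_rate >= 0, learning_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            walk_speed[1] > 0, orientation_pause[1] > 0)
  structure(list(
    age_group = age_group, strategy = strategy,
    p_allocentric_choice = p_allocentric_choice,
    learning_error_rate = learning_error_rate,
    walk_speed = walk_speed, orientation_pause = orientation_pause,
    center_dwell_extra = center_dwell_extra,
    gaze_state_elevations = gaze_state_elevations,
    missing_rate = missing_rate, missing_mode = missing_mode
  ), class = "agent_profile")
}

#' Default per-cell profile mixtures
#'
#' Returns, for each age group by condition cell, a list of agent profiles
#' with mixture weights. The defaults were chosen to reproduce the
#' qualitative structure this pipeline is designed to detect: young adults
#' are mostly allocentric in both conditions; children and older adults are
#' mostly egocentric with landmarks but mostly allocentric with the
#' anisotropic geometry; a share of older allocentric agents view-match
#' (junction dwell + circle re-fixation); missingness is 22% for young
#' adults, 27% for older, 25% for children. They are package defaults, not
#' measured quantities.
#'
#' @return Nested list: `profiles[[age_group]][[condition]]` is a list of
#'   `list(profile =, weight =)` entries with weights summing to 1.
#' @export
default_profiles <- function() {
  mix <- function(...) {
    xs <- list(...)
    w <- vapply(xs, `[[`, 0, "weight")
    stopifnot(abs(sum(w) - 1) < 1e-9)
    xs
  }
  ego <- function(ag, mr, speed, pause) {
    agent_profile(ag, "egocentric", p_allocentric_choice = 0.1,
                  learning_error_rate = 0.12, walk_speed = speed,
                  orientation_pause = pause, missing_rate = mr)
  }
  allo <- function(ag, mr, speed, pause, strat = "allocentric_map") {
    agent_profile(ag, strat, p_allocentric_choice = 0.92,
                  learning_error_rate = 0.08, walk_speed = speed,
                  orientation_pause = pause, missing_rate = mr)
  }
  ch_s <- c(0.80, 0.15); ch_p <- c(2.8, 0.9)
  yo_s <- c(0.85, 0.15); yo_p <- c(2.2, 0.7)
  ol_s <- c(0.60, 0.12); ol_p <- c(4.0, 1.3)
  list(
    children = list(
      landmark = mix(list(profile = ego("children", 0.25, ch_s, ch_p), weight = 0.65),
                     list(profile = allo("children", 0.25, ch_s, ch_p), weight = 0.35)),
      geometry = mix(list(profile = ego("children", 0.25, ch_s, ch_p), weight = 0.15),
                     list(profile = allo("children", 0.25, ch_s, ch_p), weight = 0.85))),
    young = list(
      landmark = mix(list(profile = ego("young", 0.22, yo_s, yo_p), weight = 0.10),
                     list(profile = allo("young", 0.22, yo_s, yo_p), weight = 0.90)),
      geometry = mix(list(profile = ego("young", 0.22, yo_s, yo_p), weight = 0.02),
                     list(profile = allo("young", 0.22, yo_s, yo_p), weight = 0.98))),
    older = list(
      landmark = mix(list(profile = ego("older", 0.27, ol_s, ol_p), weight = 0.65),
                     list(profile = allo("older", 0.27, ol_s, ol_p), weight = 0.15),
                     list(profile = allo("older", 0.27, ol_s, ol_p,
                                         "allocentric_viewmatch"), weight = 0.20)),
      geometry = mix(list(profile = ego("older", 0.27, ol_s, ol_p), weight = 0.15),
                     list(profile = allo("older", 0.27, ol_s, ol_p), weight = 0.75),
                     list(profile = allo("older", 0.27, ol_s, ol_p,
                                         "allocentric_viewmatch"), weight = 0.10)))
  )
}

#' Simulation configuration
#'
#' @param group_sizes Data frame with columns `age_group`, `condition`, `n`
#'   (subjects per cell).
#' @param profiles Profile mixtures as returned by [default_profiles()].
#' @param seed Integer seed; the whole cohort is deterministic given the seed.
#' @param test_sequence Start arms of the test phase; the protocol's
#'   predefined sequence is B, A, A, B, A, B.
#' @param streams `"full"` (pose + gaze), `"pose"` (trajectories only) or
#'   `"none"` (latent choices only; fast path for large replicate studies).
#' @param height_dist Named list mapping age group to `c(mean, sd)` subject
#'   height in meters.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(group_sizes,
                       profiles = default_profiles(),
                       seed = 1L,
                       test_sequence = c("B", "A", "A", "B", "A", "B"),
                       streams = c("full", "pose", "none"),
                       height_dist = list(children = c(1.45, 0.07),
                                          young = c(1.72, 0.09),
                                          older = c(1.67, 0.09))) {
  streams <- match.arg(streams)
  stopifnot(is.data.frame(group_sizes),
            all(c("age_group", "condition", "n") %in% names(group_sizes)),
            all(group_sizes$n >= 0),
            all(group_sizes$age_group %in% c("children", "young", "older")),
            all(group_sizes$condition %in% c("landmark", "geometry")),
            all(test_sequence %in% c("A", "B", "C")))
  if (sum(group_sizes$n) == 0) stop("empty group sizes")
  structure(list(group_sizes = group_sizes, profiles = profiles,
                 seed = as.integer(seed), test_sequence = test_sequence,
                 pose_hz = POSE_HZ, gaze_hz = GAZE_HZ,
                 streams = streams, height_dist = height_dist),
            class = "sim_config")
}

# sample points of a polyline at constant speed; returns positions at the
# requested arc-length stations
resample_polyline <- function(pts, stations) {
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  stations <- pmin(stations, total)
  i <- findInterval(stations, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(pts) - 1L)
  frac <- (stations - cum[i]) / pmax(len[i], 1e-12)
  pts[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
}

# rounded corner through the junction: blend the incoming and outgoing axes
# with a quadratic Bezier anchored 0.25 m from the center
corner_arc <- function(p_in, corner, p_out, n = 8) {
  tt <- seq(0, 1, length.out = n)
  b <- outer((1 - tt)^2, p_in) + outer(2 * tt * (1 - tt), corner) +
    outer(tt^2, p_out)
  b[, , drop = TRUE]
}

# waypoint polyline from one arm end region to another through the junction
route_points <- function(spec, from_arm, to_arm, via = NULL) {
  r_in <- 0.25
  # start just inside the rim of the 0.3 m departure circle, on the center
  # side, so locomotion onset and departure-circle exit coincide to within a
  # sample or two
  p0 <- arm_end(spec, from_arm) - arm_axis(spec, from_arm) * 0.29
  legs <- list(c(from_arm, to_arm))
  if (!is.null(via)) legs <- list(c(from_arm, via), c(via, to_arm))
  pts <- matrix(p0, ncol = 2)
  cur <- from_arm
  for (leg in legs) {
    a <- leg[1]; b <- leg[2]
    pa <- arm_axis(spec, a) * r_in
    pb <- arm_axis(spec, b) * r_in
    depth <- if (!is.null(via) && b == via) {
      m <- spec$arm_mouth[[b]]
      m + 0.45 * (spec$corridor_length - m)   # partway into the detour arm
    } else {
      spec$corridor_length - 0.15             # inside the endpoint disk
    }
    arc <- corner_arc(pa, c(0, 0), pb)
    pts <- rbind(pts, arc, matrix(arm_axis(spec, b) * depth, ncol = 2))
    cur <- b
  }
  pts
}

smooth_jitter <- function(n, sd = 0.01, win = 15L) {
  raw <- matrix(stats::rnorm(2 * (n + 2 * win)), ncol = 2)
  sm <- apply(raw, 2, function(v) {
    f <- stats::filter(v, rep(1 / win, win), sides = 2)
    f[(win + 1):(win + n)]
  })
  sm <- matrix(sm, ncol = 2)
  sm * sd / (1 / sqrt(win))   # restore unit variance, then scale
}

sample_trunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, lower)
}

#' Simulate one trial
#'
#' Generates one trial's head-pose (30 Hz) and binocular gaze (120 Hz)
#' streams for an agent with the given profile. The trajectory is an initial
#' stationary orientation pause at the departure position (facing the maze
#' center), followed by constant-speed locomotion with Gaussian lateral
#' jitter along a rounded-corner route to the chosen endpoint. Learning
#' trials run from arm A to the goal C, with a detour into arm B at the
#' profile's learning error rate; probe trials from B go to C with
#' probability `p_allocentric_choice`, otherwise to A; view-matching agents
#' insert an extra junction dwell during probe trials, re-fixating the circle
#' landmark sector. Gaze is generated by a state machine: during the
#' orientation pause the agent either fixates the sky sector of the landmark
#' facing the start arm (allocentric agents, landmark condition) or looks
#' down toward the junction floor; during navigation it looks at the walls
#' ahead. Each gaze sample is dropped (marked invalid in both eyes) with the
#' profile's missing rate.
#'
#' @param spec A `maze_spec`.
#' @param profile An `agent_profile`.
#' @param start_arm `"A"`, `"B"` or `"C"`.
#' @param phase `"learning"` or `"test"`.
#' @param streams `"full"`, `"pose"` or `"none"`.
#' @return An object of class `trial_record`: a list with `phase`,
#'   `start_arm`, `pose` (data frame `t, x, y, yaw`), `gaze` (data frame
#'   `t, lx, ly, lz, rx, ry, rz, valid_l, valid_r`, directions in the head
#'   frame), `end_event`, and a `truth` list of latent labels (chosen arm,
#'   pause duration, speed, gaze state means).
#' @export
simulate_trial <- function(spec, profile, start_arm, phase = c("test", "learning"),
                           streams = "full") {
  phase <- match.arg(phase)
  stopifnot(inherits(spec, "maze_spec"), inherits(profile, "agent_profile"))

  # --- latent choices -------------------------------------------------------
  via <- NULL
  if (phase == "learning") {
    failed <- stats::runif(1) < profile$learning_error_rate
    dest <- spec$goal_arm
    if (failed) via <- "B"
    choice_allocentric <- NA
  } else {
    if (start_arm == "B") {
      choice_allocentric <- stats::runif(1) < profile$p_allocentric_choice
      dest <- if (choice_allocentric) spec$goal_arm else "A"
    } else {
      choice_allocentric <- NA   # control start: both strategies converge on C
      dest <- spec$goal_arm
    }
  }
  pause <- sample_trunc_norm(1, profile$orientation_pause[1],
                             profile$orientation_pause[2], 0.5)
  speed <- sample_trunc_norm(1, profile$walk_speed[1], profile$walk_speed[2], 0.2)
  dwell <- 0
  if (phase == "test" && profile$strategy == "allocentric_viewmatch") {
    dwell <- sample_trunc_norm(1, profile$center_dwell_extra,
                               profile$center_dwell_extra / 4, 1)
  }
  truth <- list(phase = phase, start_arm = start_arm, dest_arm = dest,
                learning_failed = if (phase == "learning") !is.null(via) else NA,
                choice_allocentric = choice_allocentric,
                pause = pause, speed = speed, center_dwell = dwell,
                strategy = profile$strategy)
  if (streams == "none") {
    return(structure(list(phase = phase, start_arm = start_arm, pose = NULL,
                          gaze = NULL, end_event = "stopped_at_endpoint",
                          truth = truth), class = "trial_record"))
  }

  # --- trajectory -----------------------------------------------------------
  dt <- 1 / POSE_HZ
  route <- route_points(spec, start_arm, dest, via)
  seglen <- sqrt(rowSums(diff(route)^2))
  path_len <- sum(seglen)
  walk_T <- path_len / speed
  # junction dwell splits the walk where the route passes nearest the center
  cum <- c(0, cumsum(seglen))
  d_center <- sqrt(rowSums(route^2))
  s_center <- cum[which.min(d_center)]
  tail_T <- if (phase == "test") 5.4 else 0.3  # endpoint stop / goal entry
  total_T <- pause + walk_T + dwell + tail_T
  t_pose <- seq(0, total_T, by = dt)
  # arc-length station of each pose sample
  t_rel <- t_pose - pause
  st <- numeric(length(t_pose))
  before_dwell <- t_rel <= s_center / speed
  st[before_dwell] <- pmax(0, t_rel[before_dwell]) * speed
  after <- !before_dwell
  st[after] <- pmin(path_len, s_center + pmax(0, t_rel[after] - s_center / speed - dwell) * speed)
  xy_clean <- resample_polyline(route, st)
  # smooth (low-frequency) head sway: i.i.d. jitter at 30 Hz would read as
  # spurious locomotion, so white noise is moving-average filtered over 1 s
  # and rescaled
  xy <- xy_clean + smooth_jitter(nrow(xy_clean), sd = 0.005, win = 30L)
  # keep the pre-departure samples inside the 0.3 m departure circle
  dep <- arm_end(spec, start_arm)
  pre <- st <= 0
  if (any(pre)) {
    off <- sweep(xy[pre, , drop = FALSE], 2, dep)
    r <- sqrt(rowSums(off^2))
    too_far <- r > 0.295
    if (any(too_far)) {
      off[too_far, ] <- off[too_far, , drop = FALSE] * (0.295 / r[too_far])
      xy[pre, ] <- sweep(off, 2, dep, `+`)
    }
  }
  # heading: direction of motion (from the jitter-free path) while walking;
  # facing the maze center while stationary
  head_vec <- rbind(diff(xy_clean), c(NA, NA))
  yaw <- atan2(head_vec[, 2], head_vec[, 1]) / DEG
  still <- c(diff(st) < 1e-9, TRUE)
  face_center <- atan2(-xy_clean[, 2], -xy_clean[, 1]) / DEG
  yaw[still | !is.finite(yaw)] <- face_center[still | !is.finite(yaw)]
  pose <- data.frame(t = t_pose, x = xy[, 1], y = xy[, 2], yaw = yaw)

  end_event <- if (phase == "learning") "goal_reached" else "stopped_at_endpoint"
  rec <- list(phase = phase, start_arm = start_arm, pose = pose, gaze = NULL,
              end_event = end_event, truth = truth)

  # --- gaze -----------------------------------------------------------------
  if (streams == "full") {
    t_gaze <- seq(0, total_T, by = 1 / GAZE_HZ)
    n <- length(t_gaze)
    elev_par <- profile$gaze_state_elevations
    orient_state <- if (profile$strategy != "egocentric" &&
                        spec$condition == "landmark") "orient_sky" else "orient_floor"
    state <- rep("navigate_walls", n)
    state[t_gaze < pause] <- orient_state
    dwell_win <- t_gaze >= pause + s_center / speed &
      t_gaze < pause + s_center / speed + dwell
    if (dwell > 0) state[dwell_win] <- "viewmatch_sky"

    # target azimuth per state (world frame)
    yaw_g <- approx_angle(pose$t, pose$yaw, t_gaze)
    az <- yaw_g                                       # navigate: look ahead
    if (orient_state == "orient_sky") {
      lm <- spec$landmarks[spec$landmarks$facing_arm == start_arm, ]
      az[state == "orient_sky"] <- lm$azimuth
    }
    if (any(state == "viewmatch_sky")) {
      circ <- spec$landmarks[spec$landmarks$label == "circle", ]
      az[state == "viewmatch_sky"] <- if (nrow(circ)) circ$azimuth else yaw_g[state == "viewmatch_sky"]
    }
    elev <- numeric(n)
    for (s in unique(state)) {
      par_name <- if (s == "viewmatch_sky") "orient_sky" else s
      p <- elev_par[[par_name]]
      elev[state == s] <- stats::rnorm(sum(state == s), p[1], p[2])
    }
    elev <- pmin(85, pmax(-85, elev))
    az <- az + stats::rnorm(n, 0, 4)
    # world direction -> head frame (rotate by -yaw about z)
    cw <- cos(az * DEG) * cos(elev * DEG)
    sw <- sin(az * DEG) * cos(elev * DEG)
    zz <- sin(elev * DEG)
    cy <- cos(-yaw_g * DEG); sy <- sin(-yaw_g * DEG)
    hx <- cw * cy - sw * sy
    hy <- cw * sy + sw * cy
    eye_noise <- function() matrix(stats::rnorm(3 * n, 0, 0.008), ncol = 3)
    mk_eye <- function() {
      d <- cbind(hx, hy, zz) + eye_noise()
      d / sqrt(rowSums(d^2))
    }
    dl <- mk_eye(); dr <- mk_eye()
    miss <- missing_mask(n, profile$missing_rate, profile$missing_mode)
    one_eye <- stats::runif(n) < 0.04   # one-eye dropouts on valid samples
    lose_left <- stats::runif(n) < 0.5
    valid_l <- !miss & !(one_eye & lose_left)
    valid_r <- !miss & !(one_eye & !lose_left)
    rec$gaze <- data.frame(t = t_gaze,
                           lx = dl[, 1], ly = dl[, 2], lz = dl[, 3],
                           rx = dr[, 1], ry = dr[, 2], rz = dr[, 3],
                           valid_l = valid_l, valid_r = valid_r)
    rec$truth$orient_state <- orient_state
  }
  structure(rec, class = "trial_record")
}

# interpolate an angle series (degrees) along the shortest arc
approx_angle <- function(t, a, tout) {
  ca <- stats::approx(t, cos(a * DEG), tout, rule = 2)$y
  sa <- stats::approx(t, sin(a * DEG), tout, rule = 2)$y
  atan2(sa, ca) / DEG
}

missing_mask <- function(n, rate, mode) {
  if (rate <= 0) return(rep(FALSE, n))
  if (mode == "iid") return(stats::runif(n) < rate)
  # two-state Markov chain with mean burst length 8 samples and stationary
  # probability `rate` of being in the missing state
  mean_burst <- 8
  p_exit <- 1 / mean_burst
  p_enter <- rate * p_exit / (1 - rate)
  m <- logical(n)
  cur <- stats::runif(1) < rate
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    m[i] <- cur
    cur <- if (cur) u[i] >= p_exit else u[i] < p_enter
  }
  m
}

#' Simulate a cohort
#'
#' For every subject: learning trials from arm A until four consecutive
#' successes, then the six-trial test sequence (default B, A, A, B, A, B).
#' Each subject's height is drawn from its age group's distribution and the
#' maze walls are sized to that height. The output is deterministic given
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @return An object of class `ymaze_cohort`: list with `trials` (named list
#'   of `trial_record`s), `subjects` (one row per subject: id, age group,
#'   condition, height, latent strategy and choice probability), `truth`
#'   (one row per trial with every latent label), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  trials_by_subject <- list()
  subjects <- list()
  truth <- list()
  truth_fields <- c("phase", "start_arm", "dest_arm", "learning_failed",
                    "choice_allocentric", "pause", "speed", "strategy")
  truth_row <- function(id, key, tr) {
    c(list(subject_id = id, trial_id = key), tr$truth[truth_fields])
  }
  sid <- 0L
  for (k in seq_len(nrow(config$group_sizes))) {
    ag <- config$group_sizes$age_group[k]
    cond <- config$group_sizes$condition[k]
    n <- config$group_sizes$n[k]
    mixture <- config$profiles[[ag]][[cond]]
    w <- vapply(mixture, `[[`, 0, "weight")
    for (s in seq_len(n)) {
      sid <- sid + 1L
      id <- sprintf("S%04d", sid)
      height <- max(1.0, stats::rnorm(1, config$height_dist[[ag]][1],
                                      config$height_dist[[ag]][2]))
      spec <- build_maze(cond, height)
      profile <- mixture[[sample.int(length(mixture), 1, prob = w)]]$profile
      subjects[[id]] <- list(
        subject_id = id, age_group = ag, condition = cond, height = height,
        strategy = profile$strategy,
        p_allocentric_choice = profile$p_allocentric_choice,
        missing_rate = profile$missing_rate)
      # learning to criterion (4 consecutive successes; error rate forced to
      # zero after 26 trials so the protocol guarantee holds)
      subj_trials <- list()
      subj_truth <- list()
      consec <- 0L; ti <- 0L
      while (consec < 4L) {
        ti <- ti + 1L
        pr <- profile
        if (ti > 26L) pr$learning_error_rate <- 0
        tr <- simulate_trial(spec, pr, "A", "learning", streams = config$streams)
        consec <- if (isTRUE(tr$truth$learning_failed)) 0L else consec + 1L
        key <- sprintf("%s_L%02d", id, ti)
        tr$subject_id <- id; tr$trial_id <- key
        tr$age_group <- ag; tr$condition <- cond; tr$height <- height
        subj_trials[[key]] <- tr
        subj_truth[[key]] <- truth_row(id, key, tr)
      }
      for (ti in seq_along(config$test_sequence)) {
        sa <- config$test_sequence[ti]
        tr <- simulate_trial(spec, profile, sa, "test", streams = config$streams)
        key <- sprintf("%s_T%02d", id, ti)
        tr$subject_id <- id; tr$trial_id <- key
        tr$age_group <- ag; tr$condition <- cond; tr$height <- height
        subj_trials[[key]] <- tr
        subj_truth[[key]] <- truth_row(id, key, tr)
      }
      trials_by_subject[[id]] <- subj_trials
      truth[[id]] <- subj_truth
    }
  }
  trials <- do.call(c, unname(trials_by_subject))
  truth <- do.call(c, unname(truth))
  bind_rows_fast <- function(rows) {
    if (!length(rows)) return(NULL)
    fields <- names(rows[[1]])
    out <- lapply(fields, function(f) unlist(lapply(rows, `[[`, f),
                                             use.names = FALSE))
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  structure(list(trials = trials,
                 subjects = bind_rows_fast(subjects),
                 truth = bind_rows_fast(truth),
                 config = config),
            class = "ymaze_cohort")
}

#' @export
print.ymaze_cohort <- function(x, ...) {
  cat("Simulated Y-maze cohort: ", nrow(x$subjects), " subjects, ",
      length(x$trials), " trials (seed ", x$config$seed, ")\n", sep = "")
  print(table(x$subjects$age_group, x$subjects$condition))
  invisible(x)
}
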