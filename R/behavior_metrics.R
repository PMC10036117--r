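# Trial segmentation, the seven navigation variables, learning-criterion
# logic, probe-trial strategy classification and map-sketch scoring.

#' Segment a trial into orientation and navigation periods
#'
#' The orientation period runs from stimulus onset until the subject exits a
#' 0.3 m circle around the departure position (the start arm's end); the
#' navigation period runs from that sample to the end of the trial. If the
#' subject never exits, the whole trial is orientation and the navigation
#' interval is empty.
#'
#' @param trial A `trial_record` with a non-empty pose stream starting inside
#'   the departure circle.
#' @param spec A `maze_spec`.
#' @return List with `orientation = c(t_start, t_exit)`,
#'   `navigation = c(t_exit, t_end)` or `NULL` when the subject never moves,
#'   and `exit_index` (row of the first sample outside the circle, `NA` if
#'   none).
#' @export
segment_trial <- function(trial, spec) {
  stopifnot(inherits(trial, "trial_record"), inherits(spec, "maze_spec"))
  pose <- trial$pose
  if (is.null(pose) || nrow(pose) == 0) stop("empty pose stream")
  dep <- arm_end(spec, trial$start_arm)
  r <- sqrt((pose$x - dep[1])^2 + (pose$y - dep[2])^2)
  if (r[1] > spec$departure_radius) {
    stop("trial starts outside the departure circle (r = ",
         signif(r[1], 3), " m)")
  }
  out <- which(r > spec$departure_radius)
  if (!length(out)) {
    return(list(orientation = range(pose$t), navigation = NULL,
                exit_index = NA_integer_))
  }
  i <- out[1]
  list(orientation = c(pose$t[1], pose$t[i]),
       navigation = c(pose$t[i], pose$t[nrow(pose)]),
       exit_index = i)
}

# first entry into an endpoint disk, scanning from `from_idx` but ignoring
# the initial contiguous occupancy of the start arm's own endpoint disk (the
# departure position sits inside it); re-entering the start disk later counts
endpoint_entry <- function(pose, spec, start_arm, from_idx,
                           arms = names(spec$arm_azimuths)) {
  pose <- pose[from_idx:nrow(pose), , drop = FALSE]
  se <- arm_end(spec, start_arm)
  in_start <- (pose$x - se[1])^2 + (pose$y - se[2])^2 <= spec$endpoint_radius^2
  scan_from <- if (in_start[1]) {
    out <- which(!in_start)
    if (!length(out)) return(list(arm = "none", idx = NA_integer_))
    out[1]
  } else 1L
  best_idx <- Inf; best_arm <- "none"
  for (a in arms) {
    e <- arm_end(spec, a)
    inside <- which((pose$x - e[1])^2 + (pose$y - e[2])^2 <=
                      spec$endpoint_radius^2)
    inside <- inside[inside >= scan_from]
    if (length(inside) && inside[1] < best_idx) {
      best_idx <- inside[1]
      best_arm <- a
    }
  }
  list(arm = best_arm,
       idx = if (is.finite(best_idx)) from_idx + best_idx - 1L else NA_integer_)
}

#' First endpoint disk entered
#'
#' The label of the first 0.4 m endpoint disk the trajectory enters after
#' leaving the start arm's own endpoint area (the departure position lies
#' within it; returning to it later does count as an entry).
#'
#' @param trial A `trial_record`.
#' @param spec A `maze_spec`.
#' @return `"A"`, `"B"`, `"C"`, or `"none"` if no disk is ever entered.
#' @export
first_endpoint <- function(trial, spec) {
  seg <- segment_trial(trial, spec)
  if (is.na(seg$exit_index)) return("none")
  endpoint_entry(trial$pose, spec, trial$start_arm, seg$exit_index)$arm
}

#' Compute the navigation variables of one trial
#'
#' Returns the standard per-trial navigation measures: orientation and
#' navigation durations, escape latency (their sum), traveled distance (sum
#' of successive positional displacements over the navigation interval),
#' average speed, normalized speed (speed divided by subject height, to
#' compare adults with children), and time spent in the central area (the
#' junction plus the inner third of each arm).
#'
#' The navigation interval ends at the first entry into the goal zone
#' (learning trials) or the first endpoint disk entered (test trials); if
#' neither is reached it ends with the trial and the metrics row is flagged
#' `incomplete`.
#'
#' @param trial A `trial_record`.
#' @param spec A `maze_spec`.
#' @param subject_height Height in meters (defaults to the height recorded on
#'   the trial).
#' @param position_filter Optional low-pass filter width (odd integer,
#'   samples) applied to positions before differencing, since head sway
#'   inflates path length; `NULL` (default) uses raw positions.
#' @return A one-row data frame of class `trial_metrics`.
#' @export
compute_metrics <- function(trial, spec, subject_height = trial$height,
                            position_filter = NULL) {
  seg <- segment_trial(trial, spec)
  pose <- trial$pose
  if (!is.null(position_filter)) {
    k <- rep(1 / position_filter, position_filter)
    sm <- function(v) {
      f <- stats::filter(v, k, sides = 2)
      f[is.na(f)] <- v[is.na(f)]
      as.numeric(f)
    }
    pose$x <- sm(pose$x); pose$y <- sm(pose$y)
  }
  orientation_duration <- diff(seg$orientation)
  dt <- stats::median(diff(pose$t))
  if (is.na(seg$exit_index)) {
    res <- data.frame(
      orientation_duration = orientation_duration, navigation_duration = NA_real_,
      escape_latency = NA_real_, traveled_distance = NA_real_,
      average_speed = NA_real_, normalized_speed = NA_real_,
      time_in_central_area = 0, first_endpoint = "none",
      incomplete = TRUE, stringsAsFactors = FALSE)
    class(res) <- c("trial_metrics", class(res))
    return(res)
  }
  # end of navigation: first goal entry (learning) / first endpoint (test)
  arms <- names(spec$arm_azimuths)
  target_arms <- if (trial$phase == "learning") spec$goal_arm else arms
  entry <- endpoint_entry(pose, spec, trial$start_arm, seg$exit_index,
                          arms = target_arms)
  fe <- entry$arm
  incomplete <- is.na(entry$idx)
  end_idx <- if (incomplete) nrow(pose) else entry$idx
  nav <- pose[seg$exit_index:end_idx, , drop = FALSE]
  navigation_duration <- nav$t[nrow(nav)] - nav$t[1]
  traveled <- sum(sqrt(diff(nav$x)^2 + diff(nav$y)^2))
  avg_speed <- if (navigation_duration > 0) traveled / navigation_duration else NA_real_
  zones <- point_zone(spec, cbind(pose$x, pose$y))
  central <- sum(zones == "central_area") * dt
  res <- data.frame(
    orientation_duration = orientation_duration,
    navigation_duration = navigation_duration,
    escape_latency = orientation_duration + navigation_duration,
    traveled_distance = traveled,
    average_speed = avg_speed,
    normalized_speed = avg_speed / subject_height,
    time_in_central_area = central,
    first_endpoint = fe,
    incomplete = incomplete,
    stringsAsFactors = FALSE)
  class(res) <- c("trial_metrics", class(res))
  res
}

#' Was a learning trial successful?
#'
#' A learning trial (start A) is successful if the goal zone is reached
#' without ever entering arm B (its corridor, endpoint or departure zone).
#' Re-entering the start arm A does not count as a failure.
#'
#' @param trial A learning-phase `trial_record` starting at arm A.
#' @param spec A `maze_spec`.
#' @return Logical.
#' @export
learning_success <- function(trial, spec) {
  if (trial$phase != "learning") stop("not a learning trial")
  zones <- point_zone(spec, cbind(trial$pose$x, trial$pose$y))
  entered_B <- any(zones %in% c("arm_B_corridor", "endpoint_B", "departure_B"))
  goal <- arm_end(spec, spec$goal_arm)
  reached <- any((trial$pose$x - goal[1])^2 + (trial$pose$y - goal[2])^2 <=
                   spec$goal_radius^2)
  reached && !entered_B
}

#' Trials to the learning criterion
#'
#' Index (1-based) of the trial completing the first run of four consecutive
#' successful learning trials.
#'
#' @param success_flags Ordered logical vector of per-trial success.
#' @return Integer count; `NA` with a warning if the criterion is never met.
#' @examples
#' trials_to_criterion(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))  # 6
#' @export
trials_to_criterion <- function(success_flags) {
  stopifnot(is.logical(success_flags))
  consec <- 0L
  for (i in seq_along(success_flags)) {
    consec <- if (success_flags[i]) consec + 1L else 0L
    if (consec == 4L) return(i)
  }
  warning("learning criterion (4 consecutive successes) never met")
  NA_integer_
}

#' Classify one probe trial
#'
#' Probe trials start from arm B, the arm not used during learning. Reaching
#' the goal arm C first is an allocentric (world-anchored) response; reaching
#' arm A first means the subject repeated the learned body turn (egocentric).
#' Trials that first return to B, or never enter an endpoint, are
#' unclassifiable.
#'
#' @param trial A test-phase `trial_record` starting at arm B.
#' @param spec A `maze_spec`.
#' @return `"allocentric"`, `"egocentric"` or `"unclassifiable"`.
#' @export
classify_probe_trial <- function(trial, spec) {
  if (trial$start_arm != "B") stop("probe classification requires a B-start trial")
  fe <- first_endpoint(trial, spec)
  switch(fe,
         C = "allocentric",
         A = "egocentric",
         "unclassifiable")
}

#' Subject-level strategy from the three probe trials
#'
#' A subject is allocentric with a majority (at least 2 of 3) of allocentric
#' probe responses, egocentric with a majority of egocentric responses, and
#' unclassifiable when unclassifiable trials prevent a majority either way.
#'
#' @param probe_labels Character vector of exactly three per-trial labels.
#' @return `"allocentric"`, `"egocentric"` or `"unclassifiable"`.
#' @export
subject_strategy <- function(probe_labels) {
  if (length(probe_labels) != 3L) {
    stop("exactly the three B-start probe labels are required")
  }
  stopifnot(all(probe_labels %in% c("allocentric", "egocentric", "unclassifiable")))
  n_allo <- sum(probe_labels == "allocentric")
  n_ego <- sum(probe_labels == "egocentric")
  if (n_allo >= 2) "allocentric" else if (n_ego >= 2) "egocentric" else "unclassifiable"
}

#' Score a map sketch
#'
#' Scores a structured record of a subject's top-view drawing of the maze
#' against the true layout: recognition of the maze shape and landmark set,
#' whether the cyclic order of the drawn landmarks matches the true order up
#' to rotation (a mirrored order is incorrect), whether all landmarks are
#' placed between the arms (not at arm ends), and whether the goal is drawn
#' in the correct arm relative to the landmark array.
#'
#' @param sketch Named list with `shape` (chosen shape label; truth `"Y"`),
#'   `landmarks` (character vector of chosen landmark labels),
#'   `order` (the three drawn labels in counter-clockwise order),
#'   `placement` (character vector, one of `"between"`/`"end"` per landmark),
#'   and `goal_facing` (label of the landmark drawn opposite/facing the goal
#'   arm).
#' @param spec A `maze_spec` in the landmark condition.
#' @return A one-row data frame with logical columns `shape_correct`,
#'   `landmarks_correct`, `order_correct`, `placement_correct`,
#'   `goal_correct`.
#' @export
score_sketch <- function(sketch, spec) {
  stopifnot(inherits(spec, "maze_spec"))
  if (spec$condition != "landmark") stop("sketch scoring requires the landmark condition")
  need <- c("shape", "landmarks", "order", "placement", "goal_facing")
  if (!all(need %in% names(sketch))) {
    stop("malformed sketch record; required fields: ", paste(need, collapse = ", "))
  }
  truth_labels <- spec$landmarks$label
  shape_correct <- identical(sketch$shape, "Y")
  landmarks_correct <- setequal(sketch$landmarks, truth_labels)
  # true counter-clockwise cyclic order from the landmark azimuths
  true_order <- spec$landmarks$label[order(spec$landmarks$azimuth)]
  order_correct <- FALSE
  if (length(sketch$order) == 3L && setequal(sketch$order, truth_labels)) {
    rotations <- lapply(0:2, function(k) true_order[(0:2 + k) %% 3 + 1])
    order_correct <- any(vapply(rotations, identical, TRUE, y = as.character(sketch$order)))
  }
  placement_correct <- length(sketch$placement) == 3L &&
    all(sketch$placement == "between")
  goal_landmark <- spec$landmarks$label[spec$landmarks$facing_arm == spec$goal_arm]
  goal_correct <- identical(as.character(sketch$goal_facing), goal_landmark)
  data.frame(shape_correct = shape_correct,
             landmarks_correct = landmarks_correct,
             order_correct = order_correct,
             placement_correct = placement_correct,
             goal_correct = goal_correct)
}

#' Per-trial metrics table for a cohort
#'
#' Runs [compute_metrics()] (plus success / strategy labelling) over every
#' trial of a simulated or imported cohort.
#'
#' @param cohort A `ymaze_cohort`.
#' @return Data frame, one row per trial, with subject metadata, the seven
#'   navigation variables, `success` (learning trials) and `strategy`
#'   (B-start probe trials).
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "ymaze_cohort"))
  specs <- list()
  rows <- lapply(cohort$trials, function(tr) {
    key <- paste(tr$condition, round(tr$height, 6))
    if (is.null(specs[[key]])) specs[[key]] <<- build_maze(tr$condition, tr$height)
    spec <- specs[[key]]
    m <- compute_metrics(tr, spec)
    m$subject_id <- tr$subject_id
    m$trial_id <- tr$trial_id
    m$age_group <- tr$age_group
    m$condition <- tr$condition
    m$phase <- tr$phase
    m$start_arm <- tr$start_arm
    m$success <- if (tr$phase == "learning") learning_success(tr, spec) else NA
    m$strategy <- if (tr$phase == "test" && tr$start_arm == "B") {
      classify_probe_trial(tr, spec)
    } else NA_character_
    m
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- "data.frame"
  out
}

#' Subject-level cohort table
#'
#' Aggregates per-trial metrics to one row per subject: age group, condition,
#' the majority strategy over the three B-start probes, the binary
#' majority-allocentric outcome, trials-to-criterion, and mean navigation
#' metrics.
#'
#' @param metrics Per-trial metrics table from [cohort_metrics()].
#' @param drop_unclassifiable Drop subjects whose strategy is unclassifiable
#'   (default `TRUE`, matching their exclusion from behavioral and gaze
#'   analyses; set `FALSE` to keep them, e.g. to pool them with the
#'   egocentric group for profiling analyses).
#' @return Data frame of class `cohort_table`, one row per subject, with
#'   `allocentric_majority` as 0/1.
#' @export
cohort_table <- function(metrics, drop_unclassifiable = TRUE) {
  subjects <- unique(metrics$subject_id)
  rows <- lapply(subjects, function(s) {
    m <- metrics[metrics$subject_id == s, ]
    probes <- m[m$phase == "test" & m$start_arm == "B", ]
    strat <- subject_strategy(probes$strategy)
    learning <- m[m$phase == "learning", ]
    data.frame(
      subject_id = s,
      age_group = m$age_group[1],
      condition = m$condition[1],
      strategy = strat,
      allocentric_majority = as.integer(strat == "allocentric"),
      trials_to_criterion = trials_to_criterion(learning$success),
      escape_latency = mean(learning$escape_latency[1:min(4, nrow(learning))], na.rm = TRUE),
      traveled_distance = mean(learning$traveled_distance[1:min(4, nrow(learning))], na.rm = TRUE),
      normalized_speed = mean(learning$normalized_speed[1:min(4, nrow(learning))], na.rm = TRUE),
      time_in_central_area = mean(probes$time_in_central_area, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (drop_unclassifiable) out <- out[out$strategy != "unclassifiable", ]
  class(out) <- c("cohort_table", class(out))
  out
}
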