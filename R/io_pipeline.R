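# On-disk trial format, strict YAML pipeline configuration, and the staged
# pipeline (simulate -> metrics -> gaze -> stats -> predict), each stage
# runnable independently on the previous stage's files.

TRIAL_COLS <- c("subject_id", "age_group", "condition", "height", "trial_id",
                "phase", "start_arm", "stream", "t",
                "x", "y", "yaw",
                "lx", "ly", "lz", "rx", "ry", "rz", "valid_l", "valid_r")

#' Write trial records to the long tabular trial format
#'
#' One row per stream sample: pose rows carry `x, y, yaw`; gaze rows carry
#' the two head-frame eye directions and validity flags. Units are SI
#' (meters, seconds) and degrees for angles; timestamps are strictly
#' increasing within each (trial, stream).
#'
#' @param cohort A `ymaze_cohort` (or plain list of `trial_record`s).
#' @param path Output file path.
#' @param format `"csv"` or `"parquet"` (parquet needs the arrow package).
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  trials <- if (inherits(cohort, "ymaze_cohort")) cohort$trials else cohort
  rows <- lapply(trials, function(tr) {
    if (is.null(tr$pose)) return(NULL)
    meta <- data.frame(subject_id = tr$subject_id, age_group = tr$age_group,
                       condition = tr$condition, height = tr$height,
                       trial_id = tr$trial_id, phase = tr$phase,
                       start_arm = tr$start_arm, stringsAsFactors = FALSE)
    pose <- cbind(meta, stream = "pose", tr$pose,
                  lx = NA_real_, ly = NA_real_, lz = NA_real_,
                  rx = NA_real_, ry = NA_real_, rz = NA_real_,
                  valid_l = NA, valid_r = NA)
    out <- pose[TRIAL_COLS]
    if (!is.null(tr$gaze)) {
      gaze <- cbind(meta, stream = "gaze", tr$gaze,
                    x = NA_real_, y = NA_real_, yaw = NA_real_)
      out <- rbind(out, gaze[TRIAL_COLS])
    }
    out
  })
  tab <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                          make.row.names = FALSE))
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the parquet backend requires the arrow package")
    }
    arrow::write_parquet(tab, path)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read trial records from the tabular trial format
#'
#' Validates the schema (required columns, known enum values, strictly
#' increasing timestamps per trial and stream; violations are reported with
#' their row numbers) and reassembles `trial_record` objects.
#'
#' @param path Input file.
#' @param format `"csv"` or `"parquet"`.
#' @return A `ymaze_cohort`-like list with `trials` and `subjects` (no
#'   ground-truth table). An empty file yields zero trials with a warning.
#' @export
read_trials <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the parquet backend requires the arrow package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(TRIAL_COLS, names(tab))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("empty trial table")
    return(structure(list(trials = list(), subjects = NULL, truth = NULL,
                          config = NULL), class = "ymaze_cohort"))
  }
  bad_phase <- which(!tab$phase %in% c("learning", "test"))
  if (length(bad_phase)) stop("unknown phase at row ", bad_phase[1])
  bad_arm <- which(!tab$start_arm %in% c("A", "B", "C"))
  if (length(bad_arm)) stop("unknown start_arm at row ", bad_arm[1])
  bad_cond <- which(!tab$condition %in% c("landmark", "geometry"))
  if (length(bad_cond)) stop("unknown condition at row ", bad_cond[1])
  bad_stream <- which(!tab$stream %in% c("pose", "gaze"))
  if (length(bad_stream)) stop("unknown stream at row ", bad_stream[1])
  key <- paste(tab$trial_id, tab$stream)
  dec <- which(c(FALSE, diff(tab$t) <= 0) & key == c("", key[-length(key)]))
  if (length(dec)) {
    stop("non-increasing timestamp at row ", dec[1],
         " (trial ", tab$trial_id[dec[1]], ", ", tab$stream[dec[1]], ")")
  }
  trials <- lapply(split(tab, tab$trial_id), function(d) {
    pose <- d[d$stream == "pose", c("t", "x", "y", "yaw")]
    gaze <- d[d$stream == "gaze",
              c("t", "lx", "ly", "lz", "rx", "ry", "rz", "valid_l", "valid_r")]
    gaze$valid_l <- as.logical(gaze$valid_l)
    gaze$valid_r <- as.logical(gaze$valid_r)
    structure(list(
      subject_id = d$subject_id[1], trial_id = d$trial_id[1],
      age_group = d$age_group[1], condition = d$condition[1],
      height = d$height[1], phase = d$phase[1], start_arm = d$start_arm[1],
      pose = `rownames<-`(pose, NULL),
      gaze = if (nrow(gaze)) `rownames<-`(gaze, NULL) else NULL,
      end_event = NA_character_, truth = NULL), class = "trial_record")
  })
  subj <- unique(tab[, c("subject_id", "age_group", "condition", "height")])
  structure(list(trials = trials,
                 subjects = `rownames<-`(subj, NULL),
                 truth = NULL, config = NULL),
            class = "ymaze_cohort")
}

PIPELINE_KEYS <- list(
  top = c("mode", "seed", "out_dir", "cohort", "gaze", "predict"),
  cohort = c("group_sizes", "streams", "test_sequence"),
  gaze = c("phases"),
  predict = c("scheme", "reps", "fraction"))

validate_config <- function(cfg) {
  check <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown config key", if (length(bad) > 1) "s", " in ", where,
           ": ", paste(bad, collapse = ", "))
    }
  }
  check(cfg, PIPELINE_KEYS$top, "top level")
  for (k in c("cohort", "gaze", "predict")) {
    if (!is.null(cfg[[k]])) check(cfg[[k]], PIPELINE_KEYS[[k]], k)
  }
  if (is.null(cfg$mode) || !cfg$mode %in% c("simulate", "analyze")) {
    stop("config requires mode: simulate or analyze")
  }
  if (is.null(cfg$seed)) stop("config requires an integer seed")
  invisible(cfg)
}

default_group_sizes <- function() {
  g <- expand.grid(condition = c("landmark", "geometry"),
                   age_group = c("children", "young", "older"),
                   stringsAsFactors = FALSE)
  g$n <- 12L
  g[, c("age_group", "condition", "n")]
}

#' Run the pipeline stages
#'
#' `run_pipeline()` executes simulate -> metrics -> gaze -> stats -> predict
#' from a strict YAML configuration and writes all outputs (CSV/JSON) plus a
#' run manifest (config hash, seed, package version) into the output
#' directory. Each stage is also exported separately and operates on the
#' previous stage's files, so stages can be re-run independently. Reruns
#' with the same configuration reproduce the simulation outputs exactly.
#'
#' @param config Path to a YAML configuration, or an equivalent named list.
#'   Keys: `mode` (`simulate` runs everything from the simulator; `analyze`
#'   expects `trials.csv` already in `out_dir`), `seed`, `out_dir`, and
#'   optional `cohort` (`group_sizes`: list of `{age_group, condition, n}`;
#'   `streams`; `test_sequence`), `gaze` (`phases`) and `predict`
#'   (`scheme`, `reps`, `fraction`) blocks. Unknown keys are rejected
#'   before any computation.
#' @param out_dir Overrides the configured output directory.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  out <- out_dir %||% cfg$out_dir %||% stop("no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (cfg$mode == "simulate") stage_simulate(cfg, out)
  stage_metrics(out)
  stage_gaze(out, phases = cfg$gaze$phases %||% "test")
  stage_stats(out)
  stage_predict(out, scheme = cfg$predict$scheme %||% "both",
                reps = cfg$predict$reps %||% 1000L,
                fraction = cfg$predict$fraction %||% 0.25)
  manifest <- list(
    package = "ymazenav",
    version = as.character(utils::packageVersion("ymazenav")),
    seed = cfg$seed,
    mode = cfg$mode,
    config_hash = if (is.character(config)) unname(tools::md5sum(config)) else NA,
    files = list.files(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' @rdname run_pipeline
#' @param cfg Parsed configuration list (simulate stage).
#' @export
stage_simulate <- function(cfg, out_dir) {
  gs <- if (!is.null(cfg$cohort$group_sizes)) {
    do.call(rbind, lapply(cfg$cohort$group_sizes, as.data.frame))
  } else {
    default_group_sizes()
  }
  sc <- sim_config(gs, seed = cfg$seed,
                   streams = cfg$cohort$streams %||% "full",
                   test_sequence = cfg$cohort$test_sequence %||%
                     c("B", "A", "A", "B", "A", "B"))
  cohort <- simulate_cohort(sc)
  write_trials(cohort, file.path(out_dir, "trials.csv"))
  utils::write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(cohort)
}

#' @rdname run_pipeline
#' @export
stage_metrics <- function(out_dir) {
  cohort <- read_trials(file.path(out_dir, "trials.csv"))
  metrics <- cohort_metrics(cohort)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  ct <- cohort_table(metrics)
  utils::write.csv(ct, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  invisible(metrics)
}

#' @rdname run_pipeline
#' @param phases Trial phases analyzed by the gaze stage.
#' @export
stage_gaze <- function(out_dir, phases = "test") {
  cohort <- read_trials(file.path(out_dir, "trials.csv"))
  has_gaze <- any(!vapply(cohort$trials, function(t) is.null(t$gaze), TRUE))
  if (!has_gaze) return(invisible(NULL))
  gz <- cohort_gaze(cohort, phases = phases)
  utils::write.csv(gz$dwell, file.path(out_dir, "dwell.csv"), row.names = FALSE)
  if (!is.null(gz$timecourses)) {
    utils::write.csv(gz$timecourses, file.path(out_dir, "timecourse.csv"),
                     row.names = FALSE)
  }
  # per-subject classifier features: mean orientation altitude over B-probes
  dw <- gz$dwell[gz$dwell$start_arm == "B" & !is.na(gz$dwell$orientation_altitude), ]
  if (nrow(dw)) {
    feats <- stats::aggregate(orientation_altitude ~ subject_id + age_group + condition,
                              data = dw, FUN = mean)
    utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  }
  invisible(gz)
}

#' @rdname run_pipeline
#' @export
stage_stats <- function(out_dir) {
  ct <- utils::read.csv(file.path(out_dir, "cohort.csv"), stringsAsFactors = FALSE)
  results <- list()
  fit <- fit_strategy_glm(ct)
  groups <- unique(ct$age_group)
  deltas <- list()
  if (all(c("landmark", "geometry") %in% ct$condition) && length(groups) > 1) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    deltas <- lapply(pairs, function(p) {
      sd <- second_difference(fit, p)
      data.frame(group_1 = p[1], group_2 = p[2], delta = sd$delta,
                 se = sd$se, p_value = sd$p_value, stringsAsFactors = FALSE)
    })
  }
  # pairwise Fisher tests of strategy by age within each condition
  fisher_rows <- list()
  for (cond in unique(ct$condition)) {
    sub <- ct[ct$condition == cond, ]
    for (p in utils::combn(unique(sub$age_group), 2, simplify = FALSE)) {
      t22 <- with(sub[sub$age_group %in% p, ],
                  table(factor(age_group, levels = p),
                        factor(allocentric_majority, levels = c(1, 0))))
      if (any(rowSums(t22) == 0) || any(colSums(t22) == 0)) next
      ft <- fisher_2x2(t22)
      fisher_rows[[paste(cond, p[1], p[2])]] <- data.frame(
        condition = cond, group_1 = p[1], group_2 = p[2],
        p_value = ft$p_value, odds_ratio = ft$odds_ratio,
        phi = ft$phi, cohens_w = ft$cohens_w, n = ft$n,
        stringsAsFactors = FALSE)
    }
  }
  report <- list(
    cell_probabilities = fit$cell_probabilities,
    second_differences = if (length(deltas)) do.call(rbind, deltas) else NULL,
    fisher = if (length(fisher_rows)) do.call(rbind, c(fisher_rows, make.row.names = FALSE)) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (!is.null(report$second_differences)) {
    utils::write.csv(report$second_differences,
                     file.path(out_dir, "second_differences.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

#' @rdname run_pipeline
#' @param scheme Validation scheme for the predict stage (`"holdout"`,
#'   `"loo"` or `"both"`).
#' @param reps,fraction Hold-out repetitions and held-out fraction.
#' @export
stage_predict <- function(out_dir, scheme = "both", reps = 1000L,
                          fraction = 0.25) {
  fpath <- file.path(out_dir, "features.csv")
  cpath <- file.path(out_dir, "cohort.csv")
  if (!file.exists(fpath)) return(invisible(NULL))
  feats <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  ct <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  d <- merge(feats, ct[, c("subject_id", "strategy")], by = "subject_id")
  # strategy prediction within the landmark condition only (the geometry
  # condition typically has too few egocentric subjects)
  d <- d[d$condition == "landmark" & d$strategy %in% c("allocentric", "egocentric"), ]
  out <- list()
  if (nrow(d) >= 6 && all(table(d$strategy) >= 3)) {
    if (scheme %in% c("holdout", "both")) {
      hv <- holdout_validate(d$orientation_altitude, d$strategy,
                             fraction = fraction, reps = reps)
      out$holdout <- list(overall_correct = hv$overall_correct,
                          class_correct = as.list(hv$class_correct),
                          p_value = hv$p_value, reps = hv$reps)
    }
    if (scheme %in% c("loo", "both")) {
      lv <- loo_validate(d$orientation_altitude, d$strategy)
      out$leave_one_out <- list(overall_correct = lv$overall_correct,
                                class_correct = as.list(lv$class_correct),
                                n = length(lv$fold_correct))
    }
  } else {
    out$note <- "too few classifiable landmark-condition subjects per class"
  }
  jsonlite::write_json(out, file.path(out_dir, "predict.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
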