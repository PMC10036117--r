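# Head/eye stream fusion, cyclopean gaze, per-sample surface labelling,
# dwell-time proportions, landmark-sector analysis, binned time courses,
# heatmaps and gaze-altitude features.

#' Combine left and right eye signals into a cyclopean gaze direction
#'
#' With both eyes valid, the cyclopean direction is the renormalized mean of
#' the two unit directions; with one valid eye, that eye's direction is used;
#' with neither, the sample is missing.
#'
#' @param left,right n-by-3 matrices of unit gaze directions.
#' @param valid_l,valid_r Logical vectors of per-sample validity.
#' @return List with `direction` (n-by-3 matrix, `NA` rows when missing) and
#'   `missing` (logical vector).
#' @export
cyclopean <- function(left, right, valid_l, valid_r) {
  if (is.null(dim(left))) left <- matrix(left, ncol = 3, byrow = TRUE)
  if (is.null(dim(right))) right <- matrix(right, ncol = 3, byrow = TRUE)
  n <- nrow(left)
  stopifnot(nrow(right) == n, length(valid_l) == n, length(valid_r) == n)
  d <- matrix(NA_real_, n, 3)
  both <- valid_l & valid_r
  if (any(both)) {
    m <- left[both, , drop = FALSE] + right[both, , drop = FALSE]
    d[both, ] <- m / sqrt(rowSums(m^2))
  }
  lo <- valid_l & !valid_r
  ro <- valid_r & !valid_l
  d[lo, ] <- left[lo, , drop = FALSE] / sqrt(rowSums(left[lo, , drop = FALSE]^2))
  d[ro, ] <- right[ro, , drop = FALSE] / sqrt(rowSums(right[ro, , drop = FALSE]^2))
  list(direction = d, missing = !(valid_l | valid_r))
}

#' Fuse head-pose and gaze streams into a world-frame gaze stream
#'
#' Interpolates the 30 Hz head stream to the 120 Hz gaze timestamps (linear
#' interpolation for position, shortest-arc spherical interpolation for the
#' heading angle), combines the two eyes into a cyclopean direction, and
#' rotates the head-frame gaze directions into the world frame. Gaze samples
#' outside the pose time range are dropped. The gaze origin is the
#' interpolated head position raised to eye height.
#'
#' @param pose Data frame `t, x, y, yaw` (yaw in degrees, world frame).
#' @param gaze Data frame `t, lx, ly, lz, rx, ry, rz, valid_l, valid_r`
#'   (head-frame unit directions).
#' @param eye_height Gaze origin height in meters.
#' @return Data frame: `t`, origin `ox, oy, oz`, world-frame direction
#'   `gx, gy, gz` (`NA` when missing), `missing`.
#' @export
fuse_streams <- function(pose, gaze, eye_height) {
  stopifnot(nrow(pose) > 0, nrow(gaze) > 0)
  if (is.unsorted(pose$t, strictly = TRUE) || is.unsorted(gaze$t, strictly = TRUE)) {
    stop("non-monotone timestamps")
  }
  keep <- gaze$t >= pose$t[1] & gaze$t <= pose$t[nrow(pose)]
  gaze <- gaze[keep, , drop = FALSE]
  tt <- gaze$t
  hx <- stats::approx(pose$t, pose$x, tt)$y
  hy <- stats::approx(pose$t, pose$y, tt)$y
  yaw <- approx_angle(pose$t, pose$yaw, tt)
  cyc <- cyclopean(as.matrix(gaze[, c("lx", "ly", "lz")]),
                   as.matrix(gaze[, c("rx", "ry", "rz")]),
                   gaze$valid_l, gaze$valid_r)
  d <- cyc$direction
  cy <- cos(yaw * DEG); sy <- sin(yaw * DEG)
  gx <- d[, 1] * cy - d[, 2] * sy
  gy <- d[, 1] * sy + d[, 2] * cy
  data.frame(t = tt, ox = hx, oy = hy, oz = eye_height,
             gx = gx, gy = gy, gz = d[, 3], missing = cyc$missing)
}

#' Label each gaze sample with the surface it falls on
#'
#' Casts each non-missing world-frame gaze ray against the maze with
#' [cast_gaze_ray()] and attaches the surface label (`wall`, `floor`, `sky`),
#' the landmark sky sector where applicable, and the gaze elevation relative
#' to eye level.
#'
#' @param fused Output of [fuse_streams()].
#' @param spec A `maze_spec`.
#' @return Data frame of class `labelled_gaze`: `t`, `surface` (with
#'   `missing`), `sector`, `elevation` (degrees, `NA` when missing), hit
#'   coordinates `x, y, z`.
#' @export
label_stream <- function(fused, spec) {
  n <- nrow(fused)
  surface <- rep("missing", n)
  sector <- rep(NA_character_, n)
  elev <- rep(NA_real_, n)
  x <- y <- z <- rep(NA_real_, n)
  ok <- !fused$missing
  if (any(ok)) {
    o <- cbind(fused$ox[ok], fused$oy[ok], fused$oz[ok])
    d <- cbind(fused$gx[ok], fused$gy[ok], fused$gz[ok])
    hit <- cast_gaze_ray(spec, o, d)
    surface[ok] <- hit$surface
    sector[ok] <- hit$sector
    x[ok] <- hit$x; y[ok] <- hit$y; z[ok] <- hit$z
    elev[ok] <- gaze_elevation(d)
  }
  out <- data.frame(t = fused$t, surface = surface, sector = sector,
                    elevation = elev, x = x, y = y, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("labelled_gaze", class(out))
  out
}

region_props <- function(surface, sector) {
  n_ok <- sum(surface != "missing")
  regions <- c("wall", "floor", "sky")
  props <- stats::setNames(vapply(regions, function(r) {
    if (n_ok == 0) NA_real_ else sum(surface == r) / n_ok
  }, 0), regions)
  sectors <- c("star", "square", "circle")
  sect <- stats::setNames(vapply(sectors, function(s) {
    if (n_ok == 0) NA_real_ else sum(surface == "sky" & !is.na(sector) & sector == s) / n_ok
  }, 0), sectors)
  list(proportions = props, sector_proportions = sect)
}

#' Gaze dwell-time summary of a trial
#'
#' Overall dwell proportions are the fractions of non-missing gaze time spent
#' on the walls, the floor and the sky region (missing samples are excluded
#' from the denominator, so the three sum to 1), plus the per-landmark sky
#' sector proportions (which sum to the sky proportion) and the missing
#' fraction. The binned time course maps the orientation period onto 15 and
#' the navigation period onto 35 equal-duration bins; each bin's value is the
#' dwell proportion within a sliding window (default 1 s) centered on the
#' bin midpoint and clipped at the period edges.
#'
#' @param labels A `labelled_gaze` stream.
#' @param segmentation Output of [segment_trial()].
#' @param window Sliding window width in seconds (default 1).
#' @param bins Integer vector `c(orientation_bins, navigation_bins)`,
#'   default `c(15, 35)`.
#' @return An object of class `dwell_summary`: list with `proportions`,
#'   `sector_proportions`, `missing_fraction`, and `timecourse` (long data
#'   frame: bin, period, region, fraction).
#' @export
dwell_summary <- function(labels, segmentation, window = 1, bins = c(15L, 35L)) {
  stopifnot(inherits(labels, "labelled_gaze"))
  n_ok <- sum(labels$surface != "missing")
  if (n_ok == 0) {
    warning("all gaze samples missing; proportions undefined")
  }
  overall <- region_props(labels$surface, labels$sector)
  missing_fraction <- mean(labels$surface == "missing")

  periods <- list(orientation = segmentation$orientation,
                  navigation = segmentation$navigation)
  tc <- list()
  bin_id <- 0L
  for (pi in seq_along(periods)) {
    pd <- periods[[pi]]
    nb <- bins[pi]
    if (is.null(pd) || diff(pd) <= 0) next
    mids <- pd[1] + (seq_len(nb) - 0.5) / nb * diff(pd)
    for (b in seq_len(nb)) {
      bin_id <- bin_id + 1L
      lo <- max(pd[1], mids[b] - window / 2)
      hi <- min(pd[2], mids[b] + window / 2)
      sel <- labels$t >= lo & labels$t <= hi
      pr <- region_props(labels$surface[sel], labels$sector[sel])
      tc[[bin_id]] <- data.frame(
        bin = bin_id, period = names(periods)[pi],
        region = names(pr$proportions),
        fraction = unname(pr$proportions),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(proportions = overall$proportions,
                 sector_proportions = overall$sector_proportions,
                 missing_fraction = missing_fraction,
                 timecourse = if (length(tc)) do.call(rbind, tc) else NULL),
            class = "dwell_summary")
}

#' @export
print.dwell_summary <- function(x, ...) {
  cat("Gaze dwell summary\n")
  cat("  wall/floor/sky: ",
      paste(sprintf("%.3f", x$proportions), collapse = " / "), "\n", sep = "")
  if (!all(is.na(x$sector_proportions))) {
    cat("  sectors (star/square/circle): ",
        paste(sprintf("%.3f", x$sector_proportions), collapse = " / "), "\n", sep = "")
  }
  cat("  missing fraction: ", sprintf("%.3f", x$missing_fraction), "\n", sep = "")
  invisible(x)
}

#' Max-normalized gaze heatmap
#'
#' Accumulates gaze hit points on a grid - azimuth by elevation (degrees,
#' seen from the maze center) for the sky region, x by y (meters) for the
#' floor - and divides by the maximal cell count so the densest cell is 1.
#'
#' @param points Data frame or matrix with hit coordinates `x, y, z` (rows
#'   all on the named region).
#' @param region `"sky"` or `"floor"`.
#' @param resolution Cell size: degrees for sky (default 2), meters for
#'   floor (default 0.1).
#' @param xlim,ylim Optional grid limits (`c(min, max)` per axis); defaults
#'   cover the data.
#' @return Numeric matrix of fractions in `[0, 1]` with `xlim`/`ylim`/
#'   `resolution` attributes.
#' @export
gaze_heatmap <- function(points, region = c("sky", "floor"), resolution = NULL,
                         xlim = NULL, ylim = NULL) {
  region <- match.arg(region)
  points <- as.data.frame(points)
  if (nrow(points) == 0) stop("empty point set")
  if (is.null(resolution)) resolution <- if (region == "sky") 2 else 0.1
  if (region == "sky") {
    u <- atan2(points$y, points$x) / DEG
    r <- sqrt(points$x^2 + points$y^2)
    v <- atan2(points$z, r) / DEG
    if (is.null(xlim)) xlim <- c(-180, 180)
    if (is.null(ylim)) ylim <- c(0, 90)
  } else {
    u <- points$x
    v <- points$y
    if (is.null(xlim)) xlim <- range(u) + c(-1, 1) * resolution
    if (is.null(ylim)) ylim <- range(v) + c(-1, 1) * resolution
  }
  bx <- seq(xlim[1], xlim[2] + resolution, by = resolution)
  by <- seq(ylim[1], ylim[2] + resolution, by = resolution)
  iu <- findInterval(u, bx, rightmost.closed = TRUE)
  iv <- findInterval(v, by, rightmost.closed = TRUE)
  keep <- iu >= 1 & iu < length(bx) & iv >= 1 & iv < length(by)
  counts <- matrix(0, length(bx) - 1L, length(by) - 1L)
  tab <- table(factor(iu[keep], levels = seq_len(nrow(counts))),
               factor(iv[keep], levels = seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  m <- max(counts)
  out <- if (m > 0) counts / m else counts
  attr(out, "xlim") <- xlim
  attr(out, "ylim") <- ylim
  attr(out, "resolution") <- resolution
  out
}

#' Mean gaze altitude during the orientation period
#'
#' The feature used by the strategy classifier: the average elevation of the
#' gaze relative to eye level (degrees) over the non-missing samples of a
#' trial's orientation period.
#'
#' @param labels A `labelled_gaze` stream.
#' @param segmentation Output of [segment_trial()].
#' @return Mean elevation in degrees.
#' @export
mean_orientation_altitude <- function(labels, segmentation) {
  sel <- labels$t >= segmentation$orientation[1] &
    labels$t < segmentation$orientation[2] &
    labels$surface != "missing"
  if (!any(sel)) stop("no usable gaze samples in the orientation period")
  mean(labels$elevation[sel])
}

#' Per-trial gaze analysis over a cohort
#'
#' Fuses, labels and summarizes the gaze stream of every trial carrying one,
#' returning per-trial dwell summaries and (for B-start probes) the
#' mean-orientation-altitude classifier feature.
#'
#' @param cohort A `ymaze_cohort` simulated with full streams.
#' @param phases Phases to analyze (default `"test"`).
#' @return List with `dwell` (data frame: one row per trial with the region
#'   and sector proportions, missing fraction, altitude feature),
#'   `timecourses` (long data frame over trials) and `labels` (list of
#'   labelled streams, names = trial ids).
#' @export
cohort_gaze <- function(cohort, phases = "test") {
  stopifnot(inherits(cohort, "ymaze_cohort"))
  specs <- list()
  rows <- list(); tcs <- list(); labs <- list()
  for (tr in cohort$trials) {
    if (!(tr$phase %in% phases) || is.null(tr$gaze)) next
    key <- paste(tr$condition, round(tr$height, 6))
    if (is.null(specs[[key]])) specs[[key]] <- build_maze(tr$condition, tr$height)
    spec <- specs[[key]]
    seg <- segment_trial(tr, spec)
    fused <- fuse_streams(tr$pose, tr$gaze, spec$eye_height)
    lab <- label_stream(fused, spec)
    dw <- dwell_summary(lab, seg)
    alt <- tryCatch(mean_orientation_altitude(lab, seg), error = function(e) NA_real_)
    rows[[tr$trial_id]] <- data.frame(
      subject_id = tr$subject_id, trial_id = tr$trial_id,
      age_group = tr$age_group, condition = tr$condition,
      phase = tr$phase, start_arm = tr$start_arm,
      wall = dw$proportions[["wall"]], floor = dw$proportions[["floor"]],
      sky = dw$proportions[["sky"]],
      star = dw$sector_proportions[["star"]],
      square = dw$sector_proportions[["square"]],
      circle = dw$sector_proportions[["circle"]],
      missing_fraction = dw$missing_fraction,
      orientation_altitude = alt,
      stringsAsFactors = FALSE)
    if (!is.null(dw$timecourse)) {
      tc <- dw$timecourse
      tc$trial_id <- tr$trial_id
      tc$subject_id <- tr$subject_id
      tcs[[tr$trial_id]] <- tc
    }
    labs[[tr$trial_id]] <- lab
  }
  list(dwell = do.call(rbind, c(rows, make.row.names = FALSE)),
       timecourses = if (length(tcs)) do.call(rbind, c(tcs, make.row.names = FALSE)) else NULL,
       labels = labs)
}
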