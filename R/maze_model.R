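# Parametric geometry of the two Y-maze conditions: arm layout, wall panels,
# named floor zones, distal landmarks, and gaze-ray classification against
# walls, floor and the sky sphere.

DEG <- pi / 180

#' Build a parametric Y-maze specification
#'
#' Constructs the full geometry of one Y-maze condition. The landmark
#' condition is an equiangular maze (arm separations of 120 degrees) with
#' corridors 1.90 m long, polarized by three distal landmarks (star, square,
#' circle) placed 20 m from the maze center and 8 m above the wall tops, each
#' subtending a 10 degree visual angle from the center. The geometry condition
#' is landmark-free with corridors 2.30 m long and an anisotropic arm layout
#' (separations 50/155/155 degrees). Corridors are 0.66 m wide in both
#' conditions and wall height is the subject's height plus 0.10 m, so that the
#' visual experience of the walls is equated across subjects.
#'
#' The coordinate frame is right-handed with the maze center at the origin,
#' the floor at z = 0, and azimuths measured counter-clockwise from the +x
#' axis. By default the goal arm C points along azimuth 90 degrees; in the
#' geometry condition the 50 degree separation is between the two non-goal
#' arms A and B. These frame conventions (and the eye-height convention) are
#' free choices and may be changed through `overrides`; the physical maze
#' dimensions are fixed by the experimental design and cannot be overridden.
#'
#' @param condition `"landmark"` or `"geometry"`.
#' @param subject_height Subject height in meters (> 0). Wall height is
#'   `subject_height + 0.10`.
#' @param overrides Optional named list of free conventions:
#'   `frame_rotation` (degrees added to every azimuth), `fifty_pair`
#'   (geometry condition only; which arm pair is separated by 50 degrees:
#'   `"AB"`, `"AC"` or `"BC"`), and `eye_height` (meters; default
#'   `subject_height - 0.10`, used as the viewpoint height for
#'   viewpoint-dependent quantities). Attempting to override a fixed physical
#'   dimension is an error.
#' @return An object of class `maze_spec`: a list with the condition, arm
#'   azimuths (degrees, named A/B/C), corridor dimensions, wall height,
#'   landmark table (empty in the geometry condition), sky radius, zone radii,
#'   the central-area fraction, eye height, and precomputed wall panels and
#'   junction polygon.
#' @examples
#' spec <- build_maze("landmark", subject_height = 1.70)
#' spec$corridor_length  # 1.9
#' spec$wall_height      # 1.8
#' @export
build_maze <- function(condition = c("landmark", "geometry"),
                       subject_height,
                       overrides = list()) {
  condition <- match.arg(condition)
  if (!is.numeric(subject_height) || length(subject_height) != 1L ||
      !is.finite(subject_height) || subject_height <= 0) {
    stop("subject_height must be a single positive number (meters)")
  }
  allowed <- c("frame_rotation", "fifty_pair", "eye_height")
  if (length(overrides)) {
    bad <- setdiff(names(overrides), allowed)
    if (length(bad)) {
      stop("overrides may only change free conventions (",
           paste(allowed, collapse = ", "),
           "); fixed maze dimensions cannot be altered: ",
           paste(bad, collapse = ", "))
    }
  }
  rot <- overrides$frame_rotation %||% 0
  eye_height <- overrides$eye_height %||% (subject_height - 0.10)

  if (condition == "landmark") {
    az <- c(A = 210, B = 330, C = 90)
    corridor_length <- 1.90
  } else {
    pair <- overrides$fifty_pair %||% "AB"
    if (!pair %in% c("AB", "AC", "BC")) stop("fifty_pair must be AB, AC or BC")
    # the 50-degree pair straddles the direction opposite the remaining arm
    third <- setdiff(c("A", "B", "C"), strsplit(pair, "")[[1]])
    az <- c(A = NA_real_, B = NA_real_, C = NA_real_)
    az[third] <- if (third == "C") 90 else if (third == "A") 210 else 330
    opp <- az[third] + 180
    pp <- strsplit(pair, "")[[1]]
    az[pp[1]] <- opp - 25
    az[pp[2]] <- opp + 25
    corridor_length <- 2.30
  }
  az <- (az + rot) %% 360

  landmarks <- if (condition == "landmark") {
    # each landmark sits diametrically opposite the arm it faces, so that it
    # is straight ahead when standing at that arm's end looking at the center
    facing <- c(circle = "A", star = "B", square = "C")
    data.frame(
      label = names(facing),
      azimuth = unname((az[facing] + 180) %% 360),
      distance = 20,
      height_above_walls = 8,
      angular_size = 10,
      facing_arm = unname(facing),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(label = character(), azimuth = numeric(), distance = numeric(),
               height_above_walls = numeric(), angular_size = numeric(),
               facing_arm = character(), stringsAsFactors = FALSE)
  }

  spec <- structure(list(
    condition = condition,
    arm_azimuths = az,
    corridor_length = corridor_length,
    corridor_width = 0.66,
    wall_height = subject_height + 0.10,
    landmarks = landmarks,
    sky_radius = 6,
    goal_radius = 0.4,
    endpoint_radius = 0.4,
    departure_radius = 0.3,
    central_fraction = 1 / 3,
    goal_arm = "C",
    subject_height = subject_height,
    eye_height = eye_height,
    frame_rotation = rot,
    fifty_pair = if (condition == "geometry") (overrides$fifty_pair %||% "AB") else NA_character_
  ), class = "maze_spec")
  spec$walls <- maze_walls(spec)
  spec$junction <- maze_junction(spec)
  spec$arm_mouth <- maze_arm_mouths(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arm axis direction and arm-end coordinates
#'
#' `arm_axis` returns the 2D unit vector of an arm's azimuth; `arm_end`
#' returns the floor coordinates of the arm's end (distance `corridor_length`
#' from the center), the center of that arm's endpoint and departure disks.
#'
#' @param spec A `maze_spec`.
#' @param arm `"A"`, `"B"` or `"C"`.
#' @return Numeric length-2 vector.
#' @export
arm_axis <- function(spec, arm) {
  th <- spec$arm_azimuths[[arm]] * DEG
  c(cos(th), sin(th))
}

#' @rdname arm_axis
#' @export
arm_end <- function(spec, arm) arm_axis(spec, arm) * spec$corridor_length

# Wall panels as vertical rectangles: floor-level base segment (x1,y1)-(x2,y2)
# with height wall_height. Side walls start at the inner corner where they
# meet the neighboring arm's facing wall and run to the arm end; each arm end
# is closed by an end wall of the same height.
maze_walls <- function(spec) {
  arms <- names(spec$arm_azimuths)
  ord <- arms[order(spec$arm_azimuths)]
  w2 <- spec$corridor_width / 2
  L <- spec$corridor_length
  panels <- list()
  corners <- matrix(NA_real_, nrow = 0, ncol = 2)
  start_ccw <- start_cw <- stats::setNames(numeric(3), arms)
  n_arm <- length(ord)
  for (i in seq_len(n_arm)) {
    a_i <- ord[i]
    a_j <- ord[i %% n_arm + 1]  # counter-clockwise neighbor
    ui <- arm_axis(spec, a_i); ni <- c(-ui[2], ui[1])
    uj <- arm_axis(spec, a_j); nj <- c(-uj[2], uj[1])
    # arm i's CCW-side wall line: t*ui + w2*ni; arm j's CW-side: s*uj - w2*nj
    M <- cbind(ui, -uj)
    rhs <- -w2 * ni - w2 * nj
    ts <- solve(M, rhs)
    corner <- ts[1] * ui + w2 * ni
    corners <- rbind(corners, corner)
    start_ccw[a_i] <- ts[1]
    start_cw[a_j] <- ts[2]
  }
  for (a in arms) {
    u <- arm_axis(spec, a); n <- c(-u[2], u[1])
    p_ccw0 <- start_ccw[a] * u + w2 * n
    p_cw0 <- start_cw[a] * u - w2 * n
    p_ccw1 <- L * u + w2 * n
    p_cw1 <- L * u - w2 * n
    panels[[length(panels) + 1L]] <- list(arm = a, side = "ccw", p1 = p_ccw0, p2 = p_ccw1)
    panels[[length(panels) + 1L]] <- list(arm = a, side = "cw", p1 = p_cw0, p2 = p_cw1)
    panels[[length(panels) + 1L]] <- list(arm = a, side = "end", p1 = p_cw1, p2 = p_ccw1)
  }
  list(panels = panels, corners = corners,
       start_ccw = start_ccw, start_cw = start_cw)
}

# Central junction: convex hull of the six inner wall corner points (pairs
# coincide in the equiangular maze).
maze_junction <- function(spec) {
  pts <- spec$walls$corners
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  pts[hull, , drop = FALSE]
}

# Distance from center to each arm's corridor mouth (the farther of its two
# wall starting points); the fully-walled corridor runs from there to the end.
maze_arm_mouths <- function(spec) {
  arms <- names(spec$arm_azimuths)
  stats::setNames(pmax(spec$walls$start_ccw[arms], spec$walls$start_cw[arms]), arms)
}

point_in_convex_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  # hull vertices are in counter-clockwise order (grDevices::chull gives
  # clockwise; maze_junction preserves chull order) - test both orientations
  sgn <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
          (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    if (sgn == 0 && any(abs(cr) > 1e-12)) sgn <- sign(cr[which.max(abs(cr))])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  inside
}

#' Classify floor points into named maze zones
#'
#' Zones are tested in a fixed precedence order: endpoint disks (radius 0.4 m
#' at each arm end; arm C's endpoint is also the goal), departure disks
#' (radius 0.3 m, concentric with the endpoints), the central area (the
#' junction polygon plus the inner one-third of each arm's corridor), the arm
#' corridors, and finally `outside`.
#'
#' @param spec A `maze_spec`.
#' @param point Numeric vector `c(x, y)` or an n-by-2 matrix of floor
#'   coordinates (meters).
#' @return Character vector of zone labels among `endpoint_A/B/C`,
#'   `departure_A/B/C`, `central_area`, `arm_A/B/C_corridor`, `outside`.
#' @examples
#' spec <- build_maze("landmark", 1.7)
#' point_zone(spec, c(0, 0))              # "central_area"
#' point_zone(spec, arm_end(spec, "C"))   # "endpoint_C"
#' @export
point_zone <- function(spec, point) {
  stopifnot(inherits(spec, "maze_spec"))
  if (is.null(dim(point))) point <- matrix(point, ncol = 2, byrow = TRUE)
  px <- point[, 1]; py <- point[, 2]
  out <- rep("outside", length(px))
  assigned <- rep(FALSE, length(px))
  arms <- names(spec$arm_azimuths)
  ends <- lapply(arms, function(a) arm_end(spec, a))
  names(ends) <- arms
  # endpoint / goal disks first
  for (a in arms) {
    d2 <- (px - ends[[a]][1])^2 + (py - ends[[a]][2])^2
    hit <- !assigned & d2 <= spec$endpoint_radius^2
    out[hit] <- paste0("endpoint_", a)
    assigned <- assigned | hit
  }
  for (a in arms) {
    d2 <- (px - ends[[a]][1])^2 + (py - ends[[a]][2])^2
    hit <- !assigned & d2 <= spec$departure_radius^2
    out[hit] <- paste0("departure_", a)
    assigned <- assigned | hit
  }
  # central area: junction hull plus inner third of each corridor
  central <- point_in_convex_polygon(px, py, spec$junction)
  w2 <- spec$corridor_width / 2
  L <- spec$corridor_length
  in_arm <- matrix(FALSE, length(px), length(arms),
                   dimnames = list(NULL, arms))
  t_arm <- matrix(NA_real_, length(px), length(arms),
                  dimnames = list(NULL, arms))
  for (a in arms) {
    u <- arm_axis(spec, a)
    t <- px * u[1] + py * u[2]
    lat <- -px * u[2] + py * u[1]
    ok <- t > 0 & t <= L & abs(lat) <= w2
    in_arm[, a] <- ok
    t_arm[, a] <- t
    m <- spec$arm_mouth[[a]]
    central <- central | (ok & t <= m + spec$central_fraction * (L - m))
  }
  hit <- !assigned & central
  out[hit] <- "central_area"
  assigned <- assigned | hit
  # remaining corridor points: assign the arm the point lies deepest along
  any_arm <- rowSums(in_arm) > 0
  idx <- which(!assigned & any_arm)
  if (length(idx)) {
    best <- arms[max.col(replace(t_arm[idx, , drop = FALSE],
                                 !in_arm[idx, , drop = FALSE], -Inf))]
    out[idx] <- paste0("arm_", best, "_corridor")
  }
  out
}

#' Cast gaze rays against the maze surfaces
#'
#' Finds, for each ray, the nearest intersection among the wall panels
#' (corridor sides and closed arm ends, up to wall height), the floor plane
#' (z = 0), and - if the ray clears every wall - the sky sphere of radius 6 m
#' about the maze center. In the landmark condition, sky hits carry the
#' landmark-centered sector label from [sky_sector()].
#'
#' @param spec A `maze_spec`.
#' @param origin Numeric length-3 vector or n-by-3 matrix of ray origins
#'   (meters), inside the maze volume below the wall tops.
#' @param direction Numeric length-3 vector or n-by-3 matrix of ray
#'   directions (need not be unit length; must be non-zero).
#' @return A data frame with one row per ray: `surface` (`wall`, `floor` or
#'   `sky`), hit coordinates `x`, `y`, `z`, ray parameter `t` (meters for unit
#'   directions), and `sector` (landmark label for sky hits in the landmark
#'   condition, otherwise `NA`).
#' @export
cast_gaze_ray <- function(spec, origin, direction) {
  stopifnot(inherits(spec, "maze_spec"))
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3, byrow = TRUE)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3, byrow = TRUE)
  if (nrow(origin) == 1L && nrow(direction) > 1L) {
    origin <- origin[rep(1L, nrow(direction)), , drop = FALSE]
  }
  stopifnot(nrow(origin) == nrow(direction))
  nr <- nrow(origin)
  dn <- sqrt(rowSums(direction^2))
  if (any(dn < 1e-12)) stop("zero gaze direction")
  direction <- direction / dn
  r2 <- rowSums(origin[, 1:2, drop = FALSE]^2)
  if (any(r2 > spec$sky_radius^2) || any(origin[, 3] < 0) ||
      any(origin[, 3] > spec$wall_height)) {
    stop("ray origin outside the maze volume (below wall tops, above floor)")
  }
  h <- spec$wall_height
  eps <- 1e-9
  t_best <- rep(Inf, nr)
  for (p in spec$walls$panels) {
    e <- p$p2 - p$p1
    len <- sqrt(sum(e^2))
    nrm <- c(e[2], -e[1]) / len             # horizontal plane normal
    denom <- direction[, 1] * nrm[1] + direction[, 2] * nrm[2]
    tt <- ((p$p1[1] - origin[, 1]) * nrm[1] + (p$p1[2] - origin[, 2]) * nrm[2]) / denom
    tt[!is.finite(tt) | tt <= eps] <- Inf
    hx <- origin[, 1] + tt * direction[, 1]
    hy <- origin[, 2] + tt * direction[, 2]
    hz <- origin[, 3] + tt * direction[, 3]
    s <- ((hx - p$p1[1]) * e[1] + (hy - p$p1[2]) * e[2]) / len^2
    ok <- is.finite(tt) & s >= 0 & s <= 1 & hz >= 0 & hz <= h
    tt[!ok] <- Inf
    t_best <- pmin(t_best, tt)
  }
  # floor plane
  t_floor <- ifelse(direction[, 3] < -eps, -origin[, 3] / direction[, 3], Inf)
  surface <- ifelse(t_best <= t_floor, "wall", "floor")
  t_hit <- pmin(t_best, t_floor)
  # sky sphere for rays clearing all walls and the floor
  sky <- !is.finite(t_hit)
  if (any(sky)) {
    o <- origin[sky, , drop = FALSE]
    d <- direction[sky, , drop = FALSE]
    b <- rowSums(o * d)
    cc <- rowSums(o^2) - spec$sky_radius^2
    t_sky <- -b + sqrt(pmax(b^2 - cc, 0))   # origin inside: one positive root
    surface[sky] <- "sky"
    t_hit[sky] <- t_sky
  }
  hx <- origin[, 1] + t_hit * direction[, 1]
  hy <- origin[, 2] + t_hit * direction[, 2]
  hz <- origin[, 3] + t_hit * direction[, 3]
  sector <- rep(NA_character_, nr)
  if (spec$condition == "landmark" && any(surface == "sky")) {
    sector[surface == "sky"] <-
      sky_sector(spec, direction[surface == "sky", , drop = FALSE])
  }
  data.frame(surface = surface, x = hx, y = hy, z = hz, t = t_hit,
             sector = sector, stringsAsFactors = FALSE)
}

#' Landmark-centered sky sector of a gaze direction
#'
#' The sky region is divided into sectors centered on the three landmark
#' azimuths; sector boundaries are the angular bisectors between adjacent
#' landmarks. A direction exactly on a bisector is assigned to the
#' counter-clockwise neighbor (documented tie-break).
#'
#' @param spec A `maze_spec` in the landmark condition.
#' @param direction Length-3 vector or n-by-3 matrix of directions.
#' @return Character vector of landmark labels.
#' @export
sky_sector <- function(spec, direction) {
  stopifnot(inherits(spec, "maze_spec"))
  if (spec$condition != "landmark") {
    stop("sky sectors are defined only in the landmark condition")
  }
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3, byrow = TRUE)
  az <- atan2(direction[, 2], direction[, 1]) / DEG
  lm <- spec$landmarks
  d <- outer(az, lm$azimuth, function(a, b) ((b - a + 180) %% 360) - 180)
  # -180 and +180 are the same angular distance; fold to +180 so the
  # counter-clockwise side wins exact ties
  d[d <= -180 + 1e-12] <- 180
  ad <- abs(d)
  pick <- integer(length(az))
  for (i in seq_along(az)) {
    m <- min(ad[i, ])
    cand <- which(ad[i, ] <= m + 1e-12)
    if (length(cand) > 1L) cand <- cand[d[i, cand] > 0]  # CCW neighbor
    pick[i] <- cand[1L]
  }
  lm$label[pick]
}

#' Gaze elevation relative to the horizontal eye-level plane
#'
#' Signed elevation in degrees of a gaze direction relative to a horizontal
#' plane: 0 for horizontal gaze, +90 straight up, -90 straight down.
#'
#' @param direction Length-3 vector or n-by-3 matrix of directions (non-zero).
#' @return Numeric vector of elevations in degrees, in \[-90, 90\].
#' @export
gaze_elevation <- function(direction) {
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3, byrow = TRUE)
  nn <- sqrt(rowSums(direction^2))
  if (any(nn < 1e-12)) stop("zero gaze direction")
  asin(pmin(1, pmax(-1, direction[, 3] / nn))) / DEG
}

landmark_position <- function(spec, label) {
  lm <- spec$landmarks[spec$landmarks$label == label, ]
  if (nrow(lm) != 1L) stop("unknown landmark: ", label)
  th <- lm$azimuth * DEG
  c(lm$distance * cos(th), lm$distance * sin(th),
    spec$wall_height + lm$height_above_walls)
}

#' Physical landmark diameter from its angular size
#'
#' Landmarks are specified by the visual angle they subtend (10 degrees) from
#' the reference viewpoint, the maze center at eye height. The corresponding
#' physical diameter is `d = 2 * s * tan(angle / 2)` with `s` the slant
#' distance from the viewpoint to the landmark center.
#'
#' @param spec A `maze_spec` in the landmark condition.
#' @param landmark Landmark label (`"star"`, `"square"`, `"circle"`).
#' @param viewpoint Optional length-3 viewpoint; defaults to the maze center
#'   at the spec's eye height.
#' @return Diameter in meters.
#' @export
landmark_physical_size <- function(spec, landmark, viewpoint = NULL) {
  stopifnot(inherits(spec, "maze_spec"))
  if (spec$condition != "landmark") {
    stop("the geometry condition has no landmarks")
  }
  if (is.null(viewpoint)) viewpoint <- c(0, 0, spec$eye_height)
  pos <- landmark_position(spec, landmark)
  s <- sqrt(sum((pos - viewpoint)^2))
  lm <- spec$landmarks[spec$landmarks$label == landmark, ]
  2 * s * tan(lm$angular_size / 2 * DEG)
}

#' @export
print.maze_spec <- function(x, ...) {
  cat("Y-maze specification (", x$condition, " condition)\n", sep = "")
  cat("  corridors: ", x$corridor_length, " m x ", x$corridor_width,
      " m, walls ", x$wall_height, " m\n", sep = "")
  cat("  arm azimuths (deg): ",
      paste(names(x$arm_azimuths), round(x$arm_azimuths, 1),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (nrow(x$landmarks)) {
    cat("  landmarks: ",
        paste(x$landmarks$label, "->", x$landmarks$facing_arm, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a maze specification to YAML
#'
#' Writes the parametric fields of a `maze_spec` (SI units, degrees) to a YAML
#' document; [maze_from_yaml()] rebuilds the spec (and its derived wall
#' panels) from it.
#'
#' @param spec A `maze_spec`.
#' @param path Output file path; if `NULL`, the YAML text is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
maze_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "maze_spec"))
  doc <- list(
    condition = spec$condition,
    subject_height = spec$subject_height,
    eye_height = spec$eye_height,
    frame_rotation = spec$frame_rotation,
    fifty_pair = if (is.na(spec$fifty_pair)) NULL else spec$fifty_pair
  )
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname maze_to_yaml
#' @param input A file path or YAML string produced by [maze_to_yaml()].
#' @export
maze_from_yaml <- function(input) {
  doc <- if (file.exists(input)) yaml::read_yaml(input) else yaml::yaml.load(input)
  ov <- list(frame_rotation = doc$frame_rotation, eye_height = doc$eye_height)
  if (!is.null(doc$fifty_pair)) ov$fifty_pair <- doc$fifty_pair
  build_maze(doc$condition, doc$subject_height, overrides = ov[!vapply(ov, is.null, TRUE)])
}

#' Export the wall panels as JSON
#'
#' Writes the maze's vertical wall rectangles (base segment endpoints and
#' height) as a JSON polygon soup, for plotting or external ray oracles.
#'
#' @param spec A `maze_spec`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to a file.
#' @export
walls_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "maze_spec"))
  panels <- lapply(spec$walls$panels, function(p) {
    list(arm = p$arm, side = p$side,
         base = list(p1 = as.numeric(p$p1), p2 = as.numeric(p$p2)),
         z = c(0, spec$wall_height))
  })
  txt <- jsonlite::toJSON(list(wall_height = spec$wall_height, panels = panels),
                          auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
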