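# Independent geometric oracle for gaze-ray classification: detects surface
# crossings by sign sampling along the ray and locates each crossing by
# bisection (never by solving the ray/plane equations), then keeps the
# nearest in-bounds crossing among walls, floor and sky sphere.
#
# Returns per ray: surface, t, hit point, and a `marginal` flag for rays
# whose nearest crossing lies within `edge_tol` of a panel edge or within
# `edge_tol` (along the ray) of a competing surface - such rays are excluded
# from equivalence checks since an arbitrarily small perturbation flips the
# label.
march_oracle <- function(spec, origin, direction, tmax = 14,
                         iters = 60L, edge_tol = 2e-3) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3, byrow = TRUE)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3, byrow = TRUE)
  direction <- direction / sqrt(rowSums(direction^2))
  n <- nrow(origin)
  h <- spec$wall_height

  bisect <- function(f, lo, hi) {
    # f vectorized over t-vectors; sign(f(lo)) != sign(f(hi))
    s_lo <- sign(f(lo))
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      s_m <- sign(f(mid))
      same <- s_m == s_lo | s_m == 0
      lo <- ifelse(same, mid, lo)
      hi <- ifelse(same, hi, mid)
    }
    (lo + hi) / 2
  }

  events_t <- matrix(Inf, n, 0)
  events_marginal <- matrix(FALSE, n, 0)
  labels <- character(0)

  for (p in spec$walls$panels) {
    e <- p$p2 - p$p1
    len <- sqrt(sum(e^2))
    nv <- c(e[2], -e[1]) / len
    dist_at <- function(t) {
      (origin[, 1] + t * direction[, 1] - p$p1[1]) * nv[1] +
        (origin[, 2] + t * direction[, 2] - p$p1[2]) * nv[2]
    }
    # dense sign sampling to detect a crossing anywhere in (0, tmax]
    grid <- seq(0, tmax, length.out = 33)
    s0 <- sign(dist_at(rep(grid[1], n)))
    cross_lo <- rep(NA_real_, n); cross_hi <- rep(NA_real_, n)
    prev <- s0
    for (g in grid[-1]) {
      s <- sign(dist_at(rep(g, n)))
      newly <- is.na(cross_lo) & s != prev & prev != 0
      cross_lo[newly] <- g - diff(grid[1:2])
      cross_hi[newly] <- g
      prev <- ifelse(s == 0, prev, s)
    }
    t_w <- rep(Inf, n)
    marg <- rep(FALSE, n)
    has <- !is.na(cross_lo)
    if (any(has)) {
      tt <- bisect(function(t) dist_at(t),
                   ifelse(has, cross_lo, 0), ifelse(has, cross_hi, 1))
      hx <- origin[, 1] + tt * direction[, 1]
      hy <- origin[, 2] + tt * direction[, 2]
      hz <- origin[, 3] + tt * direction[, 3]
      s_par <- ((hx - p$p1[1]) * e[1] + (hy - p$p1[2]) * e[2]) / len
      inb <- has & tt > 1e-6 & s_par >= 0 & s_par <= len & hz >= 0 & hz <= h
      near_edge <- has & (pmin(abs(s_par), abs(len - s_par)) < edge_tol |
                            pmin(abs(hz), abs(h - hz)) < edge_tol)
      t_w[inb] <- tt[inb]
      marg <- near_edge
    }
    events_t <- cbind(events_t, t_w)
    events_marginal <- cbind(events_marginal, marg)
    labels <- c(labels, "wall")
  }

  # floor: z sign change
  zf <- function(t) origin[, 3] + t * direction[, 3]
  down <- sign(zf(rep(tmax, n))) < 0
  t_f <- rep(Inf, n)
  if (any(down)) {
    tt <- bisect(zf, rep(0, n), rep(tmax, n))
    t_f[down] <- tt[down]
  }
  events_t <- cbind(events_t, t_f)
  events_marginal <- cbind(events_marginal, rep(FALSE, n))
  labels <- c(labels, "floor")

  # sky sphere exit (origin inside; |p(t)| - R has one sign change upward)
  rad <- function(t) {
    sqrt((origin[, 1] + t * direction[, 1])^2 +
           (origin[, 2] + t * direction[, 2])^2 +
           (origin[, 3] + t * direction[, 3])^2) - spec$sky_radius
  }
  t_s <- bisect(rad, rep(0, n), rep(tmax, n))
  events_t <- cbind(events_t, t_s)
  events_marginal <- cbind(events_marginal, rep(FALSE, n))
  labels <- c(labels, "sky")

  best <- max.col(-events_t, ties.method = "first")
  t_best <- events_t[cbind(seq_len(n), best)]
  surface <- labels[best]
  # marginal: nearest event is edge-grazing, or a competing event is within
  # edge_tol along the ray
  sorted_gap <- apply(events_t, 1, function(r) {
    r <- sort(r[is.finite(r)])
    if (length(r) >= 2) r[2] - r[1] else Inf
  })
  marginal <- events_marginal[cbind(seq_len(n), best)] | sorted_gap < edge_tol
  data.frame(surface = surface, t = t_best,
             x = origin[, 1] + t_best * direction[, 1],
             y = origin[, 2] + t_best * direction[, 2],
             z = origin[, 3] + t_best * direction[, 3],
             marginal = marginal, stringsAsFactors = FALSE)
}

# random interior ray origins: inside a corridor or the junction, below walls
random_origins <- function(spec, n) {
  arms <- names(spec$arm_azimuths)
  arm <- sample(arms, n, replace = TRUE)
  t <- runif(n, 0.05, spec$corridor_length - 0.05)
  lat <- runif(n, -spec$corridor_width / 2 + 0.02, spec$corridor_width / 2 - 0.02)
  z <- runif(n, 0.2, spec$wall_height - 0.1)
  o <- t(vapply(seq_len(n), function(i) {
    u <- arm_axis(spec, arm[i])
    nv <- c(-u[2], u[1])
    t[i] * u + lat[i] * nv
  }, numeric(2)))
  cbind(o, z)
}

random_directions <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}
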