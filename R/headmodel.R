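# Spherical head model, sensor arrays and the analytic dipole-in-sphere
# forward solution.
#
# Coordinate convention (used throughout the package): right-handed head
# frame with the sphere center at the origin, +x towards the right ear,
# +y anterior (nasion), +z superior. Positions in mm, dipole moments in nAm,
# magnetometer fields in fT, planar-gradiometer signals in fT/cm.

#' Build a regular volumetric source space inside a spherical head
#'
#' Candidate source locations on a regular cubic grid, restricted to a sphere
#' of radius `head_radius - inner_margin`. This is the volumetric grid used
#' for lesional patients in clinical practice (typically 5 mm spacing).
#'
#' @param head_radius Head sphere radius in mm.
#' @param spacing Grid spacing in mm (> 0).
#' @param inner_margin Margin in mm kept between the outermost sources and
#'   the head surface, so that no source sits on the conductor boundary.
#' @return A `source_space` object: list with `points` (n x 3 matrix, mm),
#'   `kind = "volume"`, `spacing` and `head_radius`.
#' @examples
#' ss <- build_volume_source_space(head_radius = 90, spacing = 10)
#' nrow(ss$points)
#' @export
build_volume_source_space <- function(head_radius = 90, spacing = 5,
                                      inner_margin = 5) {
  stopifnot(spacing > 0, inner_margin >= 0, head_radius > 0)
  r_max <- head_radius - inner_margin
  if (r_max < 0) stop("degenerate geometry: inner_margin exceeds head_radius")
  s <- seq(0, head_radius, by = spacing)
  ax <- sort(unique(c(-s, s)))
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dimnames(pts) <- NULL
  keep <- sqrt(rowSums(pts^2)) <= r_max + 1e-9
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("degenerate geometry: no grid point fits inside the head sphere")
  new_source_space(pts, kind = "volume", spacing = spacing,
                   head_radius = head_radius)
}

#' Build a cortical-like source space on nested spherical shells
#'
#' Emulates the irregular cortical source sets used for MRI-negative patients
#' (on the order of 8000 points, ~5 mm spacing) by drawing quasi-uniform
#' points within a spherical shell band: directions uniform on the sphere,
#' radii volume-uniform within the band. Reproducible for a fixed seed.
#'
#' @param n_points Number of source points (>= 10).
#' @param head_radius Head sphere radius in mm.
#' @param shell_radii Length-2 numeric, inner and outer shell radius in mm;
#'   both must be strictly inside the head.
#' @param seed Integer seed controlling the point set.
#' @return A `source_space` with `kind = "cortical"`. `spacing` is set to the
#'   average nearest-neighbour expectation `(volume/n)^(1/3)`.
#' @export
build_cortical_source_space <- function(n_points = 8195, head_radius = 90,
                                        shell_radii = c(55, 80), seed = 1) {
  stopifnot(n_points >= 10, length(shell_radii) == 2)
  shell_radii <- sort(shell_radii)
  if (shell_radii[1] <= 0 || shell_radii[2] >= head_radius)
    stop("shell band must lie strictly inside the head sphere")
  pts <- withr_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r3 <- stats::runif(n_points, shell_radii[1]^3, shell_radii[2]^3)
    u * r3^(1 / 3)
  })
  band_vol <- 4 / 3 * pi * (shell_radii[2]^3 - shell_radii[1]^3)
  new_source_space(pts, kind = "cortical",
                   spacing = (band_vol / n_points)^(1 / 3),
                   head_radius = head_radius)
}

new_source_space <- function(points, kind, spacing, head_radius) {
  structure(list(points = points, kind = kind, spacing = spacing,
                 head_radius = head_radius),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %s, %d points, spacing %.2f mm, head radius %g mm\n",
              x$kind, nrow(x$points), x$spacing, x$head_radius))
  invisible(x)
}

#' Build a helmet-like MEG sensor array
#'
#' Sensor sites are placed quasi-uniformly (Fibonacci lattice) on a spherical
#' cap of radius `array_radius` covering the upper head. For planar
#' gradiometers each site carries two channels with orthogonal tangential
#' baseline directions, mirroring the 102-site / 204-gradiometer layout of
#' whole-head systems; for magnetometers each site carries one channel
#' measuring the radial field component.
#'
#' @param n_sites Number of sensor sites.
#' @param array_radius Distance of the sites from the sphere center, mm; must
#'   exceed the head radius of any source space used with the array.
#' @param sensor_kind `"planar_gradiometer"` (default) or `"magnetometer"`.
#' @param baseline Gradiometer baseline in mm.
#' @param cap_fraction Fraction of the full sphere covered by the cap,
#'   measured from the vertex down; the default 0.8 emulates a whole-head
#'   helmet (everything but the face/neck opening).
#' @return A `sensor_array`: per-channel `positions`, radial `orientations`,
#'   tangential `baseline_dirs` (gradiometers), `baseline`, `sensor_kind`
#'   and `channel_names`.
#' @export
meg_sensor_array <- function(n_sites = 102, array_radius = 110,
                             sensor_kind = c("planar_gradiometer",
                                             "magnetometer"),
                             baseline = 16.8, cap_fraction = 0.8) {
  sensor_kind <- match.arg(sensor_kind)
  stopifnot(n_sites >= 1, array_radius > 0, baseline > 0,
            cap_fraction > 0, cap_fraction <= 1)
  i <- seq_len(n_sites) - 0.5
  # Fibonacci cap: z descends from the vertex over the requested coverage.
  z <- 1 - 2 * cap_fraction * i / n_sites
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  sites <- array_radius * cbind(rho * cos(phi), rho * sin(phi), z)
  radial <- sites / array_radius
  # Tangential frame per site: t1 orthogonal to radial and to +z (fallback
  # +y at the vertex), t2 completes the right-handed triad.
  t1 <- cbind(-radial[, 2], radial[, 1], 0)
  bad <- sqrt(rowSums(t1^2)) < 1e-8
  t1[bad, ] <- rep(c(0, 1, 0), each = sum(bad))
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cross3(radial, t1)
  if (sensor_kind == "magnetometer") {
    arr <- list(positions = sites, orientations = radial, baseline_dirs = NULL,
                baseline = NA_real_, sensor_kind = sensor_kind,
                channel_names = sprintf("MAG%03d", seq_len(n_sites)))
  } else {
    idx <- rep(seq_len(n_sites), each = 2)
    bdir <- matrix(NA_real_, 2 * n_sites, 3)
    bdir[seq(1, 2 * n_sites, by = 2), ] <- t1
    bdir[seq(2, 2 * n_sites, by = 2), ] <- t2
    arr <- list(positions = sites[idx, , drop = FALSE],
                orientations = radial[idx, , drop = FALSE],
                baseline_dirs = bdir, baseline = baseline,
                sensor_kind = sensor_kind,
                channel_names = sprintf("GRAD%03d_%d", idx, rep(1:2, n_sites)))
  }
  structure(arr, class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d %s channels at |r| = %.1f mm\n",
              length(x$channel_names), x$sensor_kind,
              sqrt(sum(x$positions[1, ]^2))))
  invisible(x)
}

n_channels <- function(sensors) length(sensors$channel_names)

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Magnetic field of a current dipole inside a homogeneous conducting sphere
# (Sarvas closed form), sphere centered at the origin. r0: dipole location
# (length-3, mm); q: dipole moment (length-3, nAm); r: evaluation points
# (m x 3, mm, strictly outside the sphere). Returns an m x 3 matrix in fT.
# The radial dipole component is magnetically silent and the field of a
# dipole at the center vanishes; both limits are handled explicitly.
sarvas_field <- function(r0, q, r) {
  r0 <- r0 * 1e-3                      # mm -> m
  r <- r * 1e-3
  q <- q * 1e-9                        # nAm -> A*m
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (sqrt(sum(qxr0^2)) < .Machine$double.eps)
    return(matrix(0, nrow(r), 3))      # radial moment or dipole at center
  a_vec <- r - matrix(r0, nrow(r), 3, byrow = TRUE)
  a <- sqrt(rowSums(a_vec^2))
  rn <- sqrt(rowSums(r^2))
  r0_dot_r <- drop(r %*% r0)
  a_dot_r <- rowSums(a_vec * r)
  FF <- a * (rn * a + rn^2 - r0_dot_r)
  gF_r <- a^2 / rn + a_dot_r / a + 2 * a + 2 * rn
  gF_r0 <- a + 2 * rn + a_dot_r / a
  gradF <- r * gF_r - matrix(r0, nrow(r), 3, byrow = TRUE) * gF_r0
  qxr0_dot_r <- drop(r %*% qxr0)
  B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * FF - gradF * qxr0_dot_r) /
    FF^2 * 1e-7                        # mu0 / 4 pi
  B * 1e15                             # T -> fT
}

# Channel gain of the three Cartesian unit dipoles (1 nAm) at one location:
# n_channels x 3 matrix. Magnetometers read the field along the sensor
# orientation; planar gradiometers read the finite difference of that
# component across the baseline, in fT/cm.
forward_gain <- function(sensors, location) {
  eye <- diag(3)
  if (sensors$sensor_kind == "magnetometer") {
    g <- vapply(1:3, function(k) {
      rowSums(sarvas_field(location, eye[k, ], sensors$positions) *
                sensors$orientations)
    }, numeric(nrow(sensors$positions)))
    return(g)
  }
  half <- sensors$baseline_dirs * (sensors$baseline / 2)
  p_plus <- sensors$positions + half
  p_minus <- sensors$positions - half
  b_cm <- sensors$baseline / 10
  vapply(1:3, function(k) {
    bp <- rowSums(sarvas_field(location, eye[k, ], p_plus) *
                    sensors$orientations)
    bm <- rowSums(sarvas_field(location, eye[k, ], p_minus) *
                    sensors$orientations)
    (bp - bm) / b_cm
  }, numeric(nrow(sensors$positions)))
}

#' Analytic spherical-conductor leadfield
#'
#' Forward operator mapping unit dipole moments at every source point to all
#' channels, computed from the closed-form field of a current dipole in a
#' homogeneous conducting sphere. Columns are ordered point-major with the
#' x, y, z moment components minor, i.e. column `3 * (j - 1) + k` holds the
#' gain of the unit `k`-component dipole at point `j`. The same leadfield is
#' shared by all inverse procedures.
#'
#' @param space A `source_space`.
#' @param sensors A `sensor_array`; all channels must lie strictly outside
#'   the head sphere (gradiometer integration points included).
#' @return A `leadfield`: list with `matrix` (channels x 3 n_points),
#'   `channel_names`, `sensors` and `source_space`.
#' @export
sphere_leadfield <- function(space, sensors) {
  stopifnot(inherits(space, "source_space"), inherits(sensors, "sensor_array"))
  if (nrow(space$points) == 0L) stop("empty source space")
  rmin <- sqrt(min(rowSums(sensors$positions^2)))
  if (sensors$sensor_kind == "planar_gradiometer")
    rmin <- rmin - sensors$baseline / 2
  if (rmin <= space$head_radius)
    stop("sensor inside the head sphere: increase the array radius")
  n <- nrow(space$points)
  L <- matrix(NA_real_, n_channels(sensors), 3L * n)
  for (j in seq_len(n))
    L[, (3 * j - 2):(3 * j)] <- forward_gain(sensors, space$points[j, ])
  structure(list(matrix = L, channel_names = sensors$channel_names,
                 sensors = sensors, source_space = space),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels x %d source points (%s)\n",
              nrow(x$matrix), ncol(x$matrix) / 3, x$source_space$kind))
  invisible(x)
}

# Gain block (channels x 3) of source point j.
gain_block <- function(leadfield, j) {
  leadfield$matrix[, (3 * j - 2):(3 * j), drop = FALSE]
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
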