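# Shared small head models, built once per test run. Coarse grids and small
# arrays keep the suite fast; geometry-sensitive checks scale in grid units.

tiny_space <- function() build_volume_source_space(90, 20, 10)

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      space <- tiny_space()
      sensors <- meg_sensor_array(30, 110)
      lf <- sphere_leadfield(space, sensors)
      cache <<- list(space = space, sensors = sensors, leadfield = lf,
                     ops = leadfield_ops(lf), atlas = assign_lobes(space))
    }
    cache
  }
})

# Denser model for recovery studies: 12 mm grid, mid-size array.
solver_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      space <- build_volume_source_space(90, 12, 5)
      sensors <- meg_sensor_array(60, 110)
      lf <- sphere_leadfield(space, sensors)
      cache <<- list(space = space, sensors = sensors, leadfield = lf,
                     ops = leadfield_ops(lf), atlas = assign_lobes(space))
    }
    cache
  }
})

# Hand-built source space over arbitrary points (for metric toys).
new_space_from_points <- function(points, spacing = 5, head_radius = 90) {
  izbench:::new_source_space(points, kind = "volume", spacing = spacing,
                             head_radius = head_radius)
}

# Unit tangential moment at point p, deterministic (no RNG).
tangential_moment <- function(p, scale = 100) {
  r <- p / sqrt(sum(p^2))
  t_vec <- c(-r[2], r[1], 0)
  if (sqrt(sum(t_vec^2)) < 1e-8) t_vec <- c(1, 0, 0)
  t_vec <- t_vec - sum(t_vec * r) * r
  scale * t_vec / sqrt(sum(t_vec^2))
}

# Grid points at cortex-like depth, away from the sphere center and the
# unsampled face opening of the helmet.
cortical_candidates <- function(space, r_min = 50, r_max = 80) {
  r <- sqrt(rowSums(space$points^2))
  which(r >= r_min & r <= r_max)
}
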