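# Source spaces, sensor arrays and the spherical-conductor forward model.

test_that("volume source space enumerates the expected grid", {
  # 3^3 candidate grid intersected with a radius-6 sphere: origin + 6 axis
  # neighbours at distance 5.
  ss <- build_volume_source_space(head_radius = 6, spacing = 5,
                                  inner_margin = 0)
  expect_equal(nrow(ss$points), 7L)
  expect_true(all(sqrt(rowSums(ss$points^2)) <= 6))
  # Only the origin fits a radius-2 sphere on a 5 mm grid.
  ss1 <- build_volume_source_space(2, 5, 0)
  expect_equal(ss1$points, matrix(0, 1, 3))
  # Default-style grid: all points inside the margin, nearest neighbour at
  # exactly one spacing.
  ss2 <- build_volume_source_space(90, 15, 5)
  expect_true(all(sqrt(rowSums(ss2$points^2)) <= 85 + 1e-9))
  d2 <- as.matrix(stats::dist(ss2$points))
  diag(d2) <- Inf
  expect_equal(min(d2), 15)
  expect_error(build_volume_source_space(90, 5, 95), "degenerate")
})

test_that("cortical-like source space is seeded and confined to its shell", {
  s1 <- build_cortical_source_space(200, 90, c(55, 80), seed = 4)
  s2 <- build_cortical_source_space(200, 90, c(55, 80), seed = 4)
  s3 <- build_cortical_source_space(200, 90, c(55, 80), seed = 5)
  expect_identical(s1$points, s2$points)
  expect_false(identical(s1$points, s3$points))
  r <- sqrt(rowSums(s1$points^2))
  expect_true(all(r >= 55 & r <= 80))
  expect_identical(s1$kind, "cortical")
  expect_error(build_cortical_source_space(100, 90, c(55, 95)), "shell")
})

test_that("sensor arrays sit outside the head with unit orientations", {
  sen <- meg_sensor_array(30, 110)
  expect_equal(length(sen$channel_names), 60L)
  expect_equal(sqrt(rowSums(sen$positions^2)), rep(110, 60))
  expect_equal(rowSums(sen$orientations^2), rep(1, 60))
  expect_equal(rowSums(sen$baseline_dirs^2), rep(1, 60), tolerance = 1e-12)
  # baseline directions tangential to the radial orientation
  expect_lt(max(abs(rowSums(sen$baseline_dirs * sen$orientations))), 1e-12)
  mag <- meg_sensor_array(30, 110, sensor_kind = "magnetometer")
  expect_equal(length(mag$channel_names), 30L)
})

test_that("radial sources and central dipoles are magnetically silent", {
  m <- tiny_model()
  lf <- m$leadfield
  pts <- m$space$points
  for (j in seq_len(nrow(pts))) {
    G <- lf$matrix[, (3 * j - 2):(3 * j)]
    r <- sqrt(sum(pts[j, ]^2))
    if (r < 1e-9) {
      expect_equal(max(abs(G)), 0)  # dipole at the sphere center
    } else {
      tang_norm <- max(svd(G)$d)
      rad_norm <- sqrt(sum((G %*% (pts[j, ] / r))^2))
      expect_lt(rad_norm, 1e-10 * tang_norm)
    }
  }
})

test_that("forward fields are linear in the moment", {
  m <- tiny_model()
  p <- c(0, 40, 55)
  g <- izbench:::forward_gain(m$sensors, p)
  q <- c(30, -20, 10)
  expect_equal(drop(g %*% (2.5 * q)), 2.5 * drop(g %*% q), tolerance = 1e-12)
})

test_that("joint rigid rotation of sources and sensors leaves data unchanged", {
  m <- tiny_model()
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  p <- c(20, 40, 40)
  q <- tangential_moment(p, 150)
  y <- drop(izbench:::forward_gain(m$sensors, p) %*% q)
  rot <- m$sensors
  rot$positions <- m$sensors$positions %*% t(R)
  rot$orientations <- m$sensors$orientations %*% t(R)
  rot$baseline_dirs <- m$sensors$baseline_dirs %*% t(R)
  y_rot <- drop(izbench:::forward_gain(rot, drop(R %*% p)) %*% drop(R %*% q))
  expect_equal(y_rot, y, tolerance = 1e-9)
})

test_that("shallow tangential sources outgun deep ones on the same axis", {
  m <- tiny_model()
  # Same radial line under the vertex, tangential unit moments.
  g_shallow <- izbench:::forward_gain(m$sensors, c(0, 0, 70))
  g_deep <- izbench:::forward_gain(m$sensors, c(0, 0, 30))
  q <- c(1, 0, 0)
  expect_gt(sqrt(sum((g_shallow %*% q)^2)), sqrt(sum((g_deep %*% q)^2)))
})

test_that("leadfield construction validates geometry", {
  sp <- tiny_space()
  inside <- meg_sensor_array(10, 80)
  expect_error(sphere_leadfield(sp, inside), "inside")
  m <- tiny_model()
  expect_equal(dim(m$leadfield$matrix),
               c(60L, 3L * nrow(sp$points)))
  expect_true(all(is.finite(m$leadfield$matrix)))
})
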