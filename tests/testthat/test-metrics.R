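# Discrepancy metrics: DLD, grid discrepancy, MLD, SD, AUC.

test_that("dld is the Euclidean distance", {
  expect_equal(dld(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dld(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_error(dld(c(1, NA, 0), c(0, 0, 0)))
})

test_that("grid discrepancy matches exhaustive nearest-point search", {
  m <- tiny_model()
  expect_equal(grid_discrepancy(m$space$points[12, ], m$space)$distances, 0)
  origin_grid <- new_space_from_points(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(grid_discrepancy(c(2.5, 0, 0), origin_grid)$distances, 2.5)
  set.seed(2)
  ecds <- matrix(stats::runif(30, -70, 70), ncol = 3)
  gd <- grid_discrepancy(ecds, m$space)
  brute <- apply(ecds, 1, function(x)
    min(apply(m$space$points, 1, function(p) sqrt(sum((p - x)^2)))))
  expect_equal(gd$distances, brute)
  expect_equal(gd$median, stats::median(brute))
})

test_that("grid discrepancy of interior points is bounded by half the cell
           diagonal", {
  m <- tiny_model()
  set.seed(3)
  interior <- matrix(stats::runif(60, -30, 30), ncol = 3)
  gd <- grid_discrepancy(interior, m$space)
  expect_true(all(gd$distances <= m$space$spacing * sqrt(3) / 2 + 1e-9))
})

test_that("MLD reproduces hand-worked values and is scale invariant", {
  # two equally weighted voxels at 3 mm and 4 mm from the reference
  sp <- new_space_from_points(rbind(c(3, 0, 0), c(0, 4, 0)))
  expect_equal(mld(c(1, 1), c(0, 0, 0), sp), sqrt((9 + 16) / 2))
  expect_equal(mld(c(2, 2), c(0, 0, 0), sp), sqrt(12.5))  # S -> 2S
  # all mass on a voxel coinciding with the reference
  expect_equal(mld(c(1, 0), c(3, 0, 0), sp), 0)
  expect_error(mld(c(0, 0), c(0, 0, 0), sp), "zero")
})

test_that("spatial dispersion reproduces hand-worked values and equals MLD
           when the reference sits on the peak", {
  sp <- new_space_from_points(rbind(c(0, 0, 0), c(6, 0, 0)))
  # single active voxel
  expect_equal(spatial_dispersion(c(1, 0), sp), 0)
  # half/half mass, peak tie broken to the lowest index, 6 mm apart
  expect_equal(spatial_dispersion(c(1, 1), sp), sqrt(36 / 2))
  m <- tiny_model()
  set.seed(4)
  for (i in 1:100) {
    v <- stats::runif(nrow(m$space$points))
    peak <- which.max(v)
    expect_equal(spatial_dispersion(v, m$space),
                 mld(v, m$space$points[peak, ], m$space))
  }
})

test_that("AUC separates perfectly ranked maps, scores chance for constant
           maps, and matches brute-force enumeration on a toy", {
  pts <- cbind(seq(0, 40, by = 10), 0, 0)
  sp <- new_space_from_points(pts)
  # ECDs in voxels 1 and 3 (0-distance snaps)
  ecds <- rbind(c(0, 0, 0), c(20, 0, 0))
  expect_equal(map_auc(c(5, 1, 4, 1, 1), ecds, sp), 1)      # perfect
  expect_equal(map_auc(c(2, 2, 2, 2, 2), ecds, sp), 0.5)    # constant
  v <- c(5, 4, 3, 2, 1)
  # brute force: enumerate thresholds by hand under the strictly-above rule
  thr <- c(-Inf, 1, 2, 3, 4, 5, Inf)
  roc <- t(vapply(thr, function(t) {
    act <- v > t
    tp <- sum(act[c(1, 3)])
    fp <- sum(act[c(2, 4, 5)])
    c(fpr = fp / 3, tpr = tp / 2)
  }, numeric(2)))
  roc <- roc[order(roc[, 1], roc[, 2]), ]
  roc <- rbind(c(0, 0), roc, c(1, 1))
  brute <- sum(diff(roc[, 1]) * (roc[-1, 2] + roc[-nrow(roc), 2]) / 2)
  expect_equal(map_auc(v, ecds, sp), brute)
  expect_error(map_auc(v, ecds[0, , drop = FALSE], sp), "ECD")
})

test_that("AUC is invariant under strictly increasing transforms", {
  m <- tiny_model()
  set.seed(6)
  v <- stats::runif(nrow(m$space$points))
  ecds <- m$space$points[sample(nrow(m$space$points), 5), ]
  a1 <- map_auc(v, ecds, m$space)
  expect_equal(map_auc(exp(3 * v), ecds, m$space), a1)
  expect_equal(map_auc(rank(v), ecds, m$space), a1)
  expect_true(a1 >= 0 && a1 <= 1)
})

test_that("patient summaries average per-IED metrics and attach the AUC", {
  one <- summarize_patient_metrics(data.frame(dld = 7.5))
  expect_equal(one$dld_mean, 7.5)
  expect_equal(one$dld_sd, 0)
  s <- summarize_patient_metrics(data.frame(dld = c(2, 4, 6)))
  expect_equal(s$dld_mean, 4)
  expect_equal(s$dld_sd, 2)
  m <- tiny_model()
  v1 <- stats::setNames(numeric(nrow(m$space$points)), NULL); v1[10] <- 1
  map <- izbench:::new_source_map(v1, "probability", m$space)
  s2 <- summarize_patient_metrics(data.frame(dld = c(1, 2)),
                                  averaged_map = map,
                                  ecd_locations = m$space$points[10, ,
                                                                 drop = FALSE])
  expect_equal(s2$auc, 1)
})

test_that("map averaging preserves normalization and kind", {
  m <- tiny_model()
  n <- nrow(m$space$points)
  maps <- lapply(1:3, function(i) {
    v <- stats::runif(n)
    izbench:::new_source_map(v / sum(v), "probability", m$space)
  })
  avg <- average_maps(maps)
  expect_equal(sum(avg$values), 1)
  expect_identical(avg$kind, "probability")
})
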