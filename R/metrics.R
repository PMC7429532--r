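# Discrepancy metrics between automatic localizations and the benchmark ECD:
# dipole localization discrepancy (DLD), map localization discrepancy (MLD),
# spatial dispersion (SD), and the ROC area under the curve (AUC) of the
# active/inactive voxel classification.

#' Dipole localization discrepancy
#'
#' Euclidean distance (mm) between an automatic point estimate and the
#' benchmark ECD location.
#'
#' @param estimated,reference Length-3 positions in mm.
#' @return Distance in mm.
#' @export
dld <- function(estimated, reference) {
  stopifnot(all(is.finite(estimated)), all(is.finite(reference)))
  sqrt(sum((estimated - reference)^2))
}

#' Grid-discretization discrepancy of ECD locations
#'
#' Distance from each (continuous) ECD location to the closest source-space
#' point; quantifies the systematic error a grid-bound method cannot avoid.
#'
#' @param ecd_locations n x 3 matrix (or length-3 vector) of ECD positions.
#' @param space A `source_space` with at least 2 points.
#' @return List with per-ECD `distances` (mm) and their `median`.
#' @export
grid_discrepancy <- function(ecd_locations, space) {
  if (is.null(dim(ecd_locations)))
    ecd_locations <- matrix(ecd_locations, ncol = 3)
  stopifnot(nrow(ecd_locations) >= 1, nrow(space$points) >= 2)
  d <- apply(ecd_locations, 1, function(x) {
    sqrt(min(colSums((t(space$points) - x)^2)))
  })
  list(distances = d, median = stats::median(d))
}

map_values <- function(map) {
  if (inherits(map, "source_map")) map$values else as.numeric(map)
}

# Map-weighted root-mean-square distance to a reference point:
# sqrt( sum_j (d_j |S_j|)^2 / sum_j |S_j|^2 ).
weighted_rms_distance <- function(values, reference, space) {
  if (all(values == 0)) stop("all-zero map")
  d <- sqrt(colSums((t(space$points) - reference)^2))
  sqrt(sum((d * abs(values))^2) / sum(values^2))
}

#' Map localization discrepancy
#'
#' Weights the distance between each voxel and the ECD location by the map
#' value of the voxel: penalizes maps peaked in the wrong place and maps that
#' are widely dispersed. Invariant to positive rescaling of the map.
#'
#' @param map A `source_map` or numeric vector of per-point map values.
#' @param ecd_location Length-3 reference position, mm.
#' @param space The `source_space` the map lives on (taken from the map if
#'   omitted).
#' @return MLD in mm.
#' @export
mld <- function(map, ecd_location, space = NULL) {
  if (is.null(space)) space <- map$source_space
  weighted_rms_distance(map_values(map), ecd_location, space)
}

#' Spatial dispersion of a cortical map
#'
#' Same weighted root-mean-square distance as [mld()], but measured to the
#' map's own peak voxel (lowest index on ties), so it quantifies the spread
#' of the map independently of the ECD benchmark.
#'
#' @inheritParams mld
#' @return SD in mm.
#' @export
spatial_dispersion <- function(map, space = NULL) {
  if (is.null(space)) space <- map$source_space
  v <- map_values(map)
  if (all(v == 0)) stop("all-zero map")
  peak <- argmax_low(v)
  weighted_rms_distance(v, space$points[peak, ], space)
}

#' ROC area under the curve of the active-voxel classification
#'
#' Each ECD is assigned to its nearest voxel. For every threshold (all unique
#' map values plus -Inf/+Inf sentinels) the voxels strictly above threshold
#' are "active"; ECDs in active voxels count as true positives, ECDs in
#' inactive voxels as false negatives, active voxels containing no ECD as
#' false positives and inactive voxels containing no ECD as true negatives.
#' The ROC is traced as the threshold varies and integrated by the trapezoid
#' rule with endpoints (0,0) and (1,1). Note the deliberate asymmetry of the
#' convention: positives count ECDs, negatives count voxels.
#'
#' @param map `source_map` or numeric vector, typically the IED-averaged map.
#' @param ecd_locations n x 3 matrix (or length-3 vector) of ECD positions.
#' @param space The `source_space` (taken from the map if omitted).
#' @return AUC in [0, 1].
#' @export
map_auc <- function(map, ecd_locations, space = NULL) {
  if (is.null(space)) space <- map$source_space
  v <- map_values(map)
  if (is.null(dim(ecd_locations)))
    ecd_locations <- matrix(ecd_locations, ncol = 3)
  if (nrow(ecd_locations) < 1) stop("need at least one ECD")
  ecd_vox <- nearest_source_point(space, ecd_locations)
  has_ecd <- seq_along(v) %in% ecd_vox
  n_ecd <- length(ecd_vox)
  n_neg <- sum(!has_ecd)
  thr <- c(-Inf, sort(unique(v)), Inf)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    active <- v > thr[i]
    tpr[i] <- sum(active[ecd_vox]) / n_ecd
    fpr[i] <- sum(active & !has_ecd) / n_neg
  }
  fpr <- c(0, rev(fpr), 1)
  tpr <- c(0, rev(tpr), 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Per-patient metric summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-IED
#' metric values, plus the AUC of the IED-averaged map when supplied.
#'
#' @param records Data frame with one row per IED; all numeric columns are
#'   summarized.
#' @param averaged_map Optional IED-averaged `source_map` for the AUC.
#' @param ecd_locations Optional n x 3 matrix of the patient's ECD locations
#'   (required with `averaged_map`).
#' @return One-row data frame with `<metric>_mean` / `<metric>_sd` columns
#'   and `auc` when computed.
#' @export
summarize_patient_metrics <- function(records, averaged_map = NULL,
                                      ecd_locations = NULL) {
  stopifnot(nrow(records) >= 1)
  num <- records[vapply(records, is.numeric, logical(1))]
  out <- list()
  for (nm in names(num)) {
    out[[paste0(nm, "_mean")]] <- mean(num[[nm]])
    out[[paste0(nm, "_sd")]] <- if (nrow(records) > 1) stats::sd(num[[nm]]) else 0
  }
  if (!is.null(averaged_map)) {
    stopifnot(!is.null(ecd_locations))
    out$auc <- map_auc(averaged_map, ecd_locations)
  }
  as.data.frame(out)
}

#' Average source maps across IEDs
#'
#' Element-wise mean of per-IED map values on a shared source space
#' (probability maps stay normalized; intensity maps average linearly).
#'
#' @param maps List of `source_map`s on the same space and of the same kind.
#' @return A `source_map`.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  vals <- rowMeans(vapply(maps, map_values, numeric(length(maps[[1]]$values))))
  new_source_map(vals, maps[[1]]$kind, maps[[1]]$source_space)
}
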