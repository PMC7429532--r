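# Geometric lobar atlas: ten regions, five per hemisphere.

#' Names of the ten lobar regions
#'
#' Five lobes per hemisphere: frontal (F), temporal (T), central (C),
#' parietal (P) and occipital (O), prefixed by hemisphere (L/R).
#' @return Character vector of length 10.
#' @export
lobar_region_names <- function() {
  as.vector(outer(c("L", "R"), c("F", "T", "C", "P", "O"), paste))
}

#' Assign lobar labels to source-space points
#'
#' Geometric surrogate of an anatomical lobar parcellation. The hemisphere
#' is the sign of the lateral coordinate (x >= 0 is right). Within a
#' hemisphere the five lobes are contiguous angular sectors of the
#' sagittal-plane angle `phi = atan2(z, y)` (degrees, 0 = anterior
#' horizontal, 90 = vertex):
#' frontal (-45, 60], central (60, 105], parietal (105, 150],
#' occipital (150, 180] plus (-180, -160], temporal (-160, -45].
#'
#' @param space A `source_space`.
#' @return Character vector of region labels (e.g. `"R T"`), one per point.
#' @export
assign_lobes <- function(space) {
  stopifnot(inherits(space, "source_space"), nrow(space$points) > 0)
  p <- space$points
  hemi <- ifelse(p[, 1] >= 0, "R", "L")
  phi <- atan2(p[, 3], p[, 2]) * 180 / pi
  lobe <- rep("T", nrow(p))
  lobe[phi > -45 & phi <= 60] <- "F"
  lobe[phi > 60 & phi <= 105] <- "C"
  lobe[phi > 105 & phi <= 150] <- "P"
  lobe[phi > 150 | phi <= -160] <- "O"
  paste(hemi, lobe)
}

#' Index of the nearest source point
#'
#' @param space A `source_space`.
#' @param locations Numeric 3-vector or n x 3 matrix of positions (mm).
#' @return Integer vector of row indices into `space$points`; ties broken by
#'   the lowest index.
#' @export
nearest_source_point <- function(space, locations) {
  if (is.null(dim(locations))) locations <- matrix(locations, ncol = 3)
  pts <- space$points
  apply(locations, 1, function(x) {
    which.min(colSums((t(pts) - x)^2))
  })
}
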