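# Synthetic interictal-spike cohort generator. Each interictal epileptiform
# discharge (IED) is reduced to its peak sensor topography, generated by one
# dominant dipolar source plus white sensor noise.

#' Simulate a single-IED peak topography
#'
#' Forward-projects one dipole through the leadfield and adds white sensor
#' noise scaled so that mean signal power over channels divided by noise
#' variance equals `snr`.
#'
#' @param leadfield A `leadfield`.
#' @param location Dipole location (mm); snapped to the nearest source point.
#' @param moment Dipole moment 3-vector in nAm (non-zero).
#' @param snr Signal-to-noise power ratio (> 0); `Inf` for noiseless.
#' @param seed Optional integer seed for the noise realization.
#' @return An `ied_record`: `topography` (channel vector), `true_location`,
#'   `true_index`, `moment`, `snr`, `noise_std`, `seed`.
#' @export
simulate_ied_topography <- function(leadfield, location, moment, snr = Inf,
                                    seed = NULL) {
  stopifnot(inherits(leadfield, "leadfield"))
  if (sqrt(sum(moment^2)) <= 0) stop("zero dipole moment")
  if (!(snr > 0)) stop("snr must be positive (use Inf for noiseless)")
  j <- nearest_source_point(leadfield$source_space, location)
  y0 <- drop(gain_block(leadfield, j) %*% moment)
  noise_std <- 0
  y <- y0
  if (is.finite(snr)) {
    noise_std <- sqrt(mean(y0^2) / snr)
    eps <- if (is.null(seed)) stats::rnorm(length(y0)) else
      withr_seed(seed, stats::rnorm(length(y0)))
    y <- y0 + noise_std * eps
  }
  structure(list(topography = y, true_location = leadfield$source_space$points[j, ],
                 true_index = j, moment = moment, snr = snr,
                 noise_std = noise_std, seed = seed),
            class = "ied_record")
}

#' Default synthetic-cohort configuration
#'
#' The defaults mirror the clinical study conditions the package benchmarks
#' against: 22 patients, 8 to 100 IEDs per patient, dipole moment magnitudes
#' uniform in 50-500 nAm, and an IED generator cloud jittered around a
#' per-patient irritative-zone center. `p_plan_concordant` is the fraction of
#' patients whose surgical plan covers the true irritative-zone region;
#' `p_good_concordant` / `p_good_discordant` are the probabilities of a good
#' (Engel I) outcome given a concordant / discordant plan.
#'
#' @param n_patients Number of patients.
#' @param ied_count_range Length-2 integer range of IEDs per patient.
#' @param snr Signal-to-noise power ratio of each IED topography.
#' @param jitter_mm Isotropic standard deviation of the IED dipole scatter
#'   around the patient's irritative-zone center, mm.
#' @param moment_range Length-2 range of dipole moment magnitudes, nAm.
#' @param center_radius_range Radial band (mm) the per-patient IZ center is
#'   drawn from; the default keeps generators at cortical depth (interictal
#'   discharges arise in cortex, not deep white matter, and lobar labels are
#'   ill-defined near the sphere center).
#' @param midline_margin_mm Minimum distance of IED generators from the
#'   midsagittal plane, emulating the interhemispheric fissure (hemisphere
#'   labels are ill-defined on the midplane itself).
#' @param p_plan_concordant,p_good_concordant,p_good_discordant Probabilities
#'   as described above.
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 22, ied_count_range = c(8, 100),
                          snr = 10, jitter_mm = 10,
                          moment_range = c(50, 500),
                          center_radius_range = c(55, 80),
                          midline_margin_mm = 5,
                          p_plan_concordant = 0.65,
                          p_good_concordant = 0.8,
                          p_good_discordant = 0.3) {
  stopifnot(n_patients >= 1, length(ied_count_range) == 2,
            ied_count_range[1] >= 1,
            ied_count_range[1] <= ied_count_range[2],
            snr > 0, jitter_mm >= 0,
            length(moment_range) == 2, moment_range[1] > 0,
            moment_range[1] <= moment_range[2],
            length(center_radius_range) == 2,
            center_radius_range[1] <= center_radius_range[2],
            midline_margin_mm >= 0)
  structure(list(n_patients = n_patients,
                 ied_count_range = as.integer(ied_count_range),
                 snr = snr, jitter_mm = jitter_mm,
                 moment_range = moment_range,
                 center_radius_range = center_radius_range,
                 midline_margin_mm = midline_margin_mm,
                 p_plan_concordant = p_plan_concordant,
                 p_good_concordant = p_good_concordant,
                 p_good_discordant = p_good_discordant),
            class = "cohort_config")
}

# Random unit vector tangential to the sphere at point p (radial dipoles are
# magnetically silent, so synthetic generators are drawn tangentially).
random_tangential <- function(p) {
  r <- sqrt(sum(p^2))
  v <- stats::rnorm(3)
  if (r < 1e-9) return(v / sqrt(sum(v^2)))
  rad <- p / r
  t_vec <- v - sum(v * rad) * rad
  n <- sqrt(sum(t_vec^2))
  while (n < 1e-9) {
    v <- stats::rnorm(3)
    t_vec <- v - sum(v * rad) * rad
    n <- sqrt(sum(t_vec^2))
  }
  t_vec / n
}

#' Simulate a synthetic patient cohort
#'
#' Each patient receives a true irritative-zone (IZ) region, a cloud of IED
#' dipoles jittered around a center point of that region (snapped back to the
#' source grid), a surgical plan that equals the true region with probability
#' `p_plan_concordant` (otherwise a different region), and an Engel outcome
#' drawn according to plan concordance. All randomness flows from `seed`.
#'
#' @param leadfield A `leadfield`.
#' @param atlas Lobar labels of the leadfield's source space
#'   (see [assign_lobes()]).
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @return List of `patient_record`s: `id`, `ieds` (list of `ied_record`),
#'   `true_region`, `plan_lobes`, `engel`, `operated`.
#' @export
simulate_cohort <- function(leadfield, atlas, config = cohort_config(),
                            seed = 1) {
  stopifnot(inherits(leadfield, "leadfield"), inherits(config, "cohort_config"))
  space <- leadfield$source_space
  if (length(atlas) != nrow(space$points))
    stop("atlas does not cover the source space")
  if (config$jitter_mm > 2 * space$head_radius)
    stop("impossible configuration: jitter exceeds the head diameter")
  radii <- sqrt(rowSums(space$points^2))
  in_band <- radii >= config$center_radius_range[1] &
    radii <= config$center_radius_range[2] &
    abs(space$points[, 1]) >= config$midline_margin_mm
  if (!any(in_band))
    stop("impossible configuration: no source point in center_radius_range")
  regions <- intersect(lobar_region_names(), unique(atlas[in_band]))
  resample <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1
  withr_seed(seed, {
    lapply(seq_len(config$n_patients), function(i) {
      true_region <- resample(regions)
      in_region <- which(atlas == true_region & in_band)
      center_j <- resample(in_region)
      center <- space$points[center_j, ]
      n_ied <- resample(seq(config$ied_count_range[1],
                            config$ied_count_range[2]))
      region_pts <- space$points[in_region, , drop = FALSE]
      ieds <- lapply(seq_len(n_ied), function(k) {
        # Jittered proposal snapped to the nearest source point that carries
        # the true region's label: generators stay inside the IZ region, and
        # jitter only controls their spread within it.
        prop <- center + stats::rnorm(3, sd = config$jitter_mm)
        loc <- region_pts[which.min(colSums((t(region_pts) - prop)^2)), ]
        mom <- random_tangential(loc) *
          stats::runif(1, config$moment_range[1], config$moment_range[2])
        simulate_ied_topography(leadfield, loc, mom, snr = config$snr)
      })
      concordant_plan <- stats::runif(1) < config$p_plan_concordant
      plan <- if (concordant_plan) true_region else
        resample(setdiff(regions, true_region))
      p_good <- if (concordant_plan) config$p_good_concordant else
        config$p_good_discordant
      engel <- if (stats::runif(1) < p_good) "1" else
        resample(c("2", "3", "4"))
      structure(list(id = sprintf("S%02d", i), ieds = ieds,
                     true_region = true_region, plan_lobes = plan,
                     engel = engel, operated = TRUE),
                class = "patient_record")
    })
  })
}
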