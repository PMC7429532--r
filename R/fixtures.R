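# Bundled reference-cohort tables: per-patient clinical data, localization
# metric summaries and lobar percentage tables from a published 22-patient
# MEG validation study, transcribed as plain-text fixtures.

#' Load the bundled reference-cohort tables
#'
#' Reads and validates the three fixture files shipped with the package:
#' `cohort_clinical.csv` (surgical plan, Engel class and operated status per
#' patient), `cohort_metrics.csv` (per-patient IED-averaged DLD/MLD/SD and
#' map AUC per method) and `cohort_lobar.csv` (percentage of dipoles or map
#' mass per lobar region, per patient and method; only regions above the 10%
#' reporting threshold).
#'
#' Validation enforces the documented invariants: 22 patients of which
#' exactly two (P9, P10) are non-operated, plan and Engel present for every
#' operated patient (the ambiguous Engel "2/3" is kept verbatim), and every
#' lobar percentage in (10, 100].
#'
#' @param dir Directory holding the fixture files; defaults to the copies
#'   installed with the package.
#' @return A `reference_cohort`: list with data frames `clinical`, `metrics`
#'   and `lobar`.
#' @export
load_reference_cohort <- function(dir = system.file("extdata",
                                                    package = "izbench")) {
  read_fix <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("fixture file missing: ", path)
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  clinical <- read_fix("cohort_clinical.csv")
  metrics <- read_fix("cohort_metrics.csv")
  lobar <- read_fix("cohort_lobar.csv")

  fail <- function(...) stop("fixture integrity: ", sprintf(...))
  if (nrow(clinical) != 22L) fail("expected 22 patients, got %d", nrow(clinical))
  if (anyDuplicated(clinical$id)) fail("duplicated patient ids")
  non_op <- clinical$id[!clinical$operated]
  if (!setequal(non_op, c("P9", "P10")))
    fail("non-operated patients must be exactly P9 and P10")
  op <- clinical[clinical$operated, ]
  if (any(!nzchar(op$plan_lobes)) || any(!nzchar(op$engel)))
    fail("operated patients need plan_lobes and engel")
  bad_plan <- setdiff(unlist(strsplit(op$plan_lobes, ";")), lobar_region_names())
  if (length(bad_plan)) fail("unknown plan region(s): %s",
                             paste(bad_plan, collapse = ", "))
  if (!all(clinical$n_ied >= 1)) fail("IED counts must be >= 1")

  if (!all(metrics$method %in% c("sesame", "rapmusic", "wmne")))
    fail("unknown method in metrics table")
  if (!all(metrics$metric %in% c("dld", "mld", "sd", "auc")))
    fail("unknown metric in metrics table")
  cnt <- table(metrics$metric, metrics$method)
  if (!all(cnt["dld", c("sesame", "rapmusic", "wmne")] == 22) ||
      !all(cnt[c("mld", "sd", "auc"), c("sesame", "wmne")] == 22) ||
      any(cnt[c("mld", "sd", "auc"), "rapmusic"] != 0))
    fail("metrics table shape mismatch")
  if (!all(is.finite(metrics$mean)) || any(metrics$mean < 0))
    fail("metric means must be finite and non-negative")

  if (!all(lobar$method %in% c("ecd", "sesame", "rapmusic", "wmne")))
    fail("unknown method in lobar table")
  if (!all(lobar$region %in% lobar_region_names()))
    fail("unknown region in lobar table")
  if (!all(lobar$percent > 10 & lobar$percent <= 100))
    fail("lobar percentages must lie in (10, 100]")
  if (!setequal(unique(lobar$id), clinical$id))
    fail("lobar table does not cover the cohort")

  structure(list(clinical = clinical, metrics = metrics, lobar = lobar),
            class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat(sprintf("<reference_cohort> %d patients (%d operated), %d metric rows, %d lobar rows\n",
              nrow(x$clinical), sum(x$clinical$operated), nrow(x$metrics),
              nrow(x$lobar)))
  invisible(x)
}

# Column of per-patient metric means, ordered as the clinical table.
metric_column <- function(cohort, method, metric) {
  m <- cohort$metrics
  rows <- m[m$method == method & m$metric == metric, ]
  rows$mean[match(cohort$clinical$id, rows$id)]
}
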