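# Lobar concordance with the surgical plan and post-surgical outcome
# prediction: lobar percentages -> concordance classification -> confusion
# counts -> TPR/TNR/PPV/NPV/F1.

#' Lobar percentage distribution of a localization result
#'
#' For dipole methods (ECD fitting, MUSIC) the percentage of a region is the
#' share of dipoles whose nearest source point carries that region's label;
#' for map methods it is the share of total map mass (posterior probability
#' or current intensity) in the region. Raw percentages are returned; the
#' 10% reporting threshold is a display rule applied by [filter_lobar()].
#'
#' @param x Either an n x 3 matrix / list of dipole locations, or a
#'   `source_map`.
#' @param atlas Region label per source point (see [assign_lobes()]).
#' @param space The `source_space`; taken from a `source_map` input if
#'   omitted.
#' @return Data frame with columns `region` and `percent` (summing to 100),
#'   regions with zero mass omitted, sorted by decreasing percent.
#' @export
lobar_percentages <- function(x, atlas, space = NULL) {
  if (inherits(x, "source_map")) {
    if (is.null(space)) space <- x$source_space
    stopifnot(length(atlas) == length(x$values))
    mass <- tapply(x$values, atlas, sum)
    if (sum(x$values) == 0) stop("all-zero map")
    pct <- 100 * mass / sum(x$values)
  } else {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    stopifnot(!is.null(space), nrow(x) >= 1)
    lab <- atlas[nearest_source_point(space, x)]
    pct <- 100 * table(lab) / nrow(x)
  }
  out <- data.frame(region = names(pct), percent = as.numeric(pct))
  out <- out[out$percent > 0, ]
  out[order(-out$percent, out$region), , drop = FALSE]
}

#' Apply the 10% reporting threshold to a lobar table
#'
#' Regions whose percentage is not greater than the threshold are dropped
#' from the displayed table (a region at exactly the threshold is excluded).
#'
#' @param lobar Data frame with a `percent` column.
#' @param threshold Percent threshold (default 10).
#' @return Filtered data frame.
#' @export
filter_lobar <- function(lobar, threshold = 10) {
  lobar[lobar$percent > threshold, , drop = FALSE]
}

engel_good <- function(engel) {
  engel <- trimws(as.character(engel))
  if (!nzchar(engel)) stop("missing Engel class on an operated patient")
  engel %in% c("1", "I")
}

#' Classify one patient's localization against plan and outcome
#'
#' The localization is concordant when any region attaining the maximal raw
#' percentage belongs to the set of planned (treated) regions; ties therefore
#' count as concordant if any tied region matches. Outcomes are dichotomized
#' as good (Engel I) versus poor (Engel II-IV, including the ambiguous
#' "2/3"). Non-operated patients are excluded.
#'
#' @param lobar Data frame of `region`/`percent` for one patient and method.
#' @param plan_lobes Character vector of planned regions (or a single
#'   semicolon-separated string).
#' @param engel Engel class as character (`"1"`..`"4"`, `"2/3"`, or Roman).
#' @param operated Logical.
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`, or `"excluded"`.
#' @export
classify_patient <- function(lobar, plan_lobes, engel, operated = TRUE) {
  if (!isTRUE(operated)) return("excluded")
  stopifnot(nrow(lobar) >= 1)
  if (length(plan_lobes) == 1L && grepl(";", plan_lobes))
    plan_lobes <- strsplit(plan_lobes, ";")[[1]]
  plan_lobes <- trimws(plan_lobes)
  top <- lobar$region[lobar$percent == max(lobar$percent)]
  concordant <- any(top %in% plan_lobes)
  good <- engel_good(engel)
  if (concordant && good) "TP" else if (concordant) "FP" else
    if (good) "FN" else "TN"
}

#' Confusion counts of the concordance-outcome classification
#'
#' Applies [classify_patient()] to every operated patient of a cohort and
#' accumulates the counts.
#'
#' @param lobar Long data frame with columns `id`, `method`, `region`,
#'   `percent` (as in the bundled lobar fixture).
#' @param clinical Data frame with columns `id`, `plan_lobes`, `engel`,
#'   `operated`.
#' @param method Method name to select from `lobar`.
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn` plus the
#'   per-patient `classes`.
#' @export
outcome_confusion <- function(lobar, clinical, method) {
  rows <- lobar[lobar$method == method, , drop = FALSE]
  if (nrow(rows) == 0) stop("no lobar rows for method ", method)
  op <- clinical[clinical$operated, , drop = FALSE]
  if (nrow(op) < 1) stop("need at least one operated patient")
  cls <- vapply(seq_len(nrow(op)), function(i) {
    pat <- rows[rows$id == op$id[i], , drop = FALSE]
    classify_patient(pat, op$plan_lobes[i], op$engel[i], TRUE)
  }, character(1))
  names(cls) <- op$id
  structure(list(tp = sum(cls == "TP"), fp = sum(cls == "FP"),
                 tn = sum(cls == "TN"), fn = sum(cls == "FN"),
                 classes = cls),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Outcome-prediction statistics from confusion counts
#'
#' Sensitivity (TPR), specificity (TNR), positive and negative predictive
#' values and the F1 score (harmonic mean of PPV and TPR). A statistic with a
#' zero denominator is returned as `NA` rather than an error.
#'
#' @param counts A `confusion_counts` or list with `tp`, `fp`, `tn`, `fn`.
#' @return Data frame with columns `tpr`, `tnr`, `ppv`, `npv`, `f1`.
#' @export
prediction_stats <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) stop("all-zero confusion counts")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rate(tp, tp + fn)
  tnr <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  f1 <- if (!is.na(tpr) && !is.na(ppv) && (tpr + ppv) > 0)
    2 * ppv * tpr / (ppv + tpr) else NA_real_
  data.frame(tpr = tpr, tnr = tnr, ppv = ppv, npv = npv, f1 = f1)
}
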