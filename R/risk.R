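## Risk evaluation: per-patient classification from inducibility and
## confusion metrics against clinical outcomes.

#' Round half away from zero to a given number of decimals
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify a patient as at risk from per-site induction results
#'
#' A heart is at risk of ventricular arrhythmia if rapid pacing induced
#' reentry from at least one of the seven pacing sites.
#'
#' @param induction_results List of per-site results, each with a
#'   logical `induced` field (or a logical vector of length 7).
#' @return Logical.
#' @export
classify_patient <- function(induction_results) {
  ind <- if (is.logical(induction_results)) induction_results
         else vapply(induction_results, function(r) isTRUE(r$induced), logical(1))
  if (length(ind) != 7)
    stop("expected induction results for all 7 pacing sites")
  any(ind)
}

#' Confusion metrics of a binary risk predictor
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy (percent), from predicted vs observed outcomes.  Raw values
#' are retained alongside values rounded half-up to one decimal, the
#' convention used for reporting.  Degenerate denominators yield `NA`
#' (undefined), not 0.
#'
#' @param predictions Logical vector of at-risk verdicts.
#' @param outcomes Logical vector of observed events.
#' @return List of class `confusion_metrics` with `counts` (tp, fp, tn,
#'   fn), `raw`, and `rounded`.
#' @export
compute_metrics <- function(predictions, outcomes) {
  stopifnot(length(predictions) == length(outcomes),
            is.logical(predictions), is.logical(outcomes))
  if (!any(outcomes) || all(outcomes))
    stop("need at least one positive and one negative outcome")
  tp <- sum(predictions & outcomes)
  fp <- sum(predictions & !outcomes)
  tn <- sum(!predictions & !outcomes)
  fn <- sum(!predictions & outcomes)
  div <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  raw <- c(sensitivity = div(tp, tp + fn),
           specificity = div(tn, tn + fp),
           ppv = div(tp, tp + fp),
           npv = div(tn, tn + fn),
           accuracy = div(tp + tn, tp + fp + tn + fn))
  # reporting convention: half-up at the second decimal, then the first
  # (53.846% -> 53.85 -> 53.9)
  structure(list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 raw = raw,
                 rounded = round_half_up(round_half_up(raw, 2), 1)),
            class = "confusion_metrics")
}

#' Predictive-capability table for all four risk predictors
#'
#' One row of confusion metrics per method (ACCF/AHA and ESC clinical
#' risk scores, LGE-T1 and LGE-only virtual-heart verdicts) computed
#' from a cohort outcome table such as [cohort_outcomes_fixture()].
#'
#' @param fixture Data frame with logical columns `clinical_va`,
#'   `accf_aha`, `esc`, `lge_t1`, `lge_only`.
#' @return Data frame (one row per method) of rounded percentages, with
#'   the raw values in attribute `"raw"`.
#' @export
reproduce_table3 <- function(fixture = cohort_outcomes_fixture()) {
  methods <- c(accf_aha = "ACCF/AHA risk model",
               esc = "ESC risk model",
               lge_t1 = "Virtual-heart: LGE-T1",
               lge_only = "Virtual-heart: LGE only")
  rows <- lapply(names(methods), function(m)
    compute_metrics(fixture[[m]], fixture$clinical_va))
  tab <- do.call(rbind, lapply(rows, function(r) r$rounded))
  out <- data.frame(method = unname(methods), tab, row.names = NULL,
                    check.names = FALSE)
  attr(out, "raw") <- do.call(rbind, lapply(rows, function(r) r$raw))
  out
}
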