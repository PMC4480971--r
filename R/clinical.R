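#' Assemble a clinical test cohort
#'
#' Bundles a patient expression matrix (already mapped onto the training
#' platform and quantile-normalized against the training reference) with
#' progression-free survival and grouping annotations.
#'
#' @param expr Expression matrix, genes x patients.
#' @param pfs_months Positive PFS in months, one per patient.
#' @param event Progression indicator (1 = progression observed,
#'   0 = censored).
#' @param arm Optional treatment-arm label per patient.
#' @param indication Optional cancer-indication label per patient.
#' @return A `clinical_cohort` list.
#' @export
clinical_cohort <- function(expr, pfs_months, event, arm = NULL,
                            indication = NULL) {
  n <- ncol(expr)
  stopifnot(length(pfs_months) == n, length(event) == n)
  if (any(!is.finite(pfs_months)) || any(pfs_months <= 0))
    stop("pfs_months must be finite and positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  structure(list(expr = expr,
                 pfs_months = as.numeric(pfs_months),
                 event = as.integer(event),
                 arm = if (is.null(arm)) rep(NA_character_, n) else as.character(arm),
                 indication = if (is.null(indication)) rep(NA_character_, n)
                              else as.character(indication),
                 patient_id = colnames(expr)),
            class = "clinical_cohort")
}

#' Classify patients with a trained signature model
#'
#' Scores each patient with the signature's PLSR model and calls a patient
#' sensitive when the predicted log2 IC50 score is strictly below the
#' model's calibrated cutoff (a score exactly at the cutoff is resistant).
#'
#' @param sig A `functional_signature` (see [fit_final_model()]).
#' @param cohort A [clinical_cohort()] normalized against the model's
#'   training reference.
#' @return Data frame: `patient_id`, `score`, `class`.
#' @export
classify_patients <- function(sig, cohort) {
  stopifnot(inherits(sig, "functional_signature"),
            inherits(cohort, "clinical_cohort"))
  scores <- predict(sig$model, t(cohort$expr))
  data.frame(patient_id = cohort$patient_id,
             score = as.numeric(scores),
             class = ifelse(scores < sig$cutoff$value, "sensitive", "resistant"),
             stringsAsFactors = FALSE)
}

#' Confusion metrics of predicted class against dichotomized PFS
#'
#' Patients with PFS at or above the drug-specific cutoff (in months) are
#' responders. A predicted-sensitive responder is a true positive. Rates
#' with a zero denominator are reported `NA`, never 0.
#'
#' @param classes Character vector of predicted classes
#'   (`"sensitive"`/`"resistant"`).
#' @param pfs PFS in months, aligned with `classes`.
#' @param pfs_cutoff Responder cutoff in months (e.g. 2.4 or 4.2).
#' @return List with `counts` (TP, FP, TN, FN) and `metrics` (accuracy,
#'   sensitivity, specificity, ppv, npv as fractions in \[0, 1\]).
#' @export
confusion_vs_pfs <- function(classes, pfs, pfs_cutoff) {
  stopifnot(length(classes) == length(pfs), pfs_cutoff > 0)
  pred_pos <- classes == "sensitive"
  responder <- pfs >= pfs_cutoff
  tp <- sum(pred_pos & responder)
  fp <- sum(pred_pos & !responder)
  tn <- sum(!pred_pos & !responder)
  fn <- sum(!pred_pos & responder)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       metrics = c(accuracy = ratio(tp + tn, length(classes)),
                   sensitivity = ratio(tp, tp + fn),
                   specificity = ratio(tn, tn + fp),
                   ppv = ratio(tp, tp + fp),
                   npv = ratio(tn, tn + fn)))
}

#' Survival stratification by predicted class
#'
#' Kaplan-Meier median PFS per predicted class, the two-group log-rank
#' test, and a univariate Cox proportional-hazards fit of sensitive vs
#' resistant (Breslow ties) with a Wald 95% confidence interval. A hazard
#' ratio below 1 means the predicted-sensitive group progresses later.
#'
#' @param classes Predicted classes (both must be present).
#' @param pfs PFS in months.
#' @param events Progression indicator (1 = progressed, 0 = censored).
#' @return List: `median_pfs` (named, per class), `logrank_p`,
#'   `hazard_ratio`, `hr_ci` (lower/upper), `n` (per class).
#' @export
survival_stratify <- function(classes, pfs, events) {
  stopifnot(length(classes) == length(pfs), length(pfs) == length(events))
  cls <- factor(classes, levels = c("resistant", "sensitive"))
  if (any(table(cls) == 0L)) stop("both predicted classes must be present")
  s <- survival::Surv(pfs, events)
  fit <- survival::survfit(s ~ cls)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^cls=", "", names(med))
  lr <- survival::survdiff(s ~ cls)
  logrank_p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  cox <- survival::coxph(s ~ cls, ties = "breslow")
  beta <- unname(stats::coef(cox)[1L])
  se <- sqrt(unname(stats::vcov(cox)[1L, 1L]))
  list(median_pfs = med,
       logrank_p = logrank_p,
       hazard_ratio = exp(beta),
       hr_ci = c(lower = exp(beta - 1.96 * se),
                 upper = exp(beta + 1.96 * se)),
       n = table(cls))
}

#' Full matched-arm or cross-drug evaluation of a model on a cohort
#'
#' Classifies the cohort, computes confusion metrics against dichotomized
#' PFS and the survival stratification, and tags the result `matched` or
#' `cross`. Cross-drug evaluation (model for drug A applied to patients
#' treated with drug B) uses the identical computation — only the tag
#' differs — which is how drug specificity of a signature is demonstrated.
#'
#' @param sig A `functional_signature`.
#' @param cohort A [clinical_cohort()].
#' @param pfs_cutoff Responder cutoff in months.
#' @param tag `"matched"` or `"cross"`.
#' @return A `stratification_result` list: `tag`, `per_patient`,
#'   `confusion`, `survival`.
#' @export
evaluate_cohort <- function(sig, cohort, pfs_cutoff, tag = "matched") {
  cls <- classify_patients(sig, cohort)
  conf <- confusion_vs_pfs(cls$class, cohort$pfs_months, pfs_cutoff)
  surv <- if (length(unique(cls$class)) == 2L)
    survival_stratify(cls$class, cohort$pfs_months, cohort$event)
  else NULL
  structure(list(tag = tag, per_patient = cls, confusion = conf,
                 survival = surv, pfs_cutoff = pfs_cutoff),
            class = "stratification_result")
}

#' @rdname evaluate_cohort
#' @export
cross_drug_check <- function(sig, cohort, pfs_cutoff) {
  evaluate_cohort(sig, cohort, pfs_cutoff, tag = "cross")
}

#' Percent predicted-sensitive per cancer indication
#'
#' Applies the model to an expression matrix grouped by indication and
#' reports, per group, the percentage of samples predicted sensitive
#' (rounded to 2 decimals). Empty groups are skipped.
#'
#' @param sig A `functional_signature`.
#' @param expr Normalized expression matrix, genes x samples.
#' @param indication Indication label per sample.
#' @return Data frame: `indication`, `n`, `percent_sensitive`.
#' @export
indication_scan <- function(sig, expr, indication) {
  stopifnot(ncol(expr) == length(indication))
  scores <- predict(sig$model, t(expr))
  sens <- scores < sig$cutoff$value
  groups <- split(sens, as.character(indication))
  out <- data.frame(
    indication = names(groups),
    n = vapply(groups, length, integer(1)),
    percent_sensitive = vapply(groups, function(g)
      round(100 * mean(g), 2), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$n > 0L, , drop = FALSE]
}
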