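#' Run the full assignment + QC pipeline
#'
#' Convenience wrapper chaining formula assignment ([assign_spectra()])
#' and the quality-control pipeline ([qc_pipeline()]) into a normalized
#' formula table.
#'
#' @param spectra named list of peak-list data frames.
#' @param meta sample metadata.
#' @param rules an [assignment_rules()] object.
#' @param ... further arguments passed to [qc_pipeline()].
#' @return list with `table` (normalized `formula_table`), `assigned`
#'   (per-spectrum assignments), `outliers` and `report`.
#' @export
run_vdom_pipeline <- function(spectra, meta, rules = assignment_rules(),
                              ...) {
  assigned <- assign_spectra(spectra, rules)
  qc <- qc_pipeline(assigned, meta, tol_ppm = rules$tolerance_ppm, ...)
  c(list(assigned = assigned), qc)
}

#' Score vDOM recovery against the simulation ground truth
#'
#' Compares a detected vDOM formula set with the planted pulse:
#' precision = |detected AND planted| / |detected|,
#' recall = |detected AND planted| / |planted|. Also contrasts the
#' estimated removed fraction with the truly removed subset.
#'
#' @param report a `vdom_report` (or character vector of detected
#'   formulas).
#' @param truth a `ground_truth` object.
#' @return list with `precision`, `recall`, `n_detected`, `n_true`,
#'   `removed_fraction_true`.
#' @export
evaluate_vdom_recovery <- function(report, truth) {
  detected <- if (inherits(report, "vdom_report")) report$vdom_set else
    as.character(report)
  planted <- truth$vdom$formula
  tp <- length(intersect(detected, planted))
  list(
    precision = if (length(detected) > 0) tp / length(detected) else NA_real_,
    recall = if (length(planted) > 0) tp / length(planted) else NA_real_,
    n_detected = length(detected),
    n_true = length(planted),
    removed_fraction_true = if (nrow(truth$vdom) > 0)
      mean(truth$vdom$removed) else NA_real_
  )
}
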