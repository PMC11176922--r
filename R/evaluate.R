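#' Root-mean-square error
#'
#' RMSE over paired samples; pairs where either side is NA (prediction gaps)
#' are excluded.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    bc_abort("bc_shape_error", "pred and truth differ in length.")
  }
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) bc_abort("bc_empty_eval", "no prediction/truth pairs.")
  sqrt(mean((pred[ok] - truth[ok])^2))
}

#' Circular RMSE of phase angles
#'
#' Per-sample error is the minimal angular difference in (-180, 180]
#' degrees, so a prediction of 350 deg against a truth of 10 deg counts as
#' 20 deg, not 340 deg.
#'
#' @param pred_deg,truth_deg Angles in degrees.
#' @return RMSE in degrees (at most 180).
#' @export
circular_rmse <- function(pred_deg, truth_deg) {
  if (length(pred_deg) != length(truth_deg)) {
    bc_abort("bc_shape_error", "pred and truth differ in length.")
  }
  ok <- !is.na(pred_deg) & !is.na(truth_deg)
  if (!any(ok)) bc_abort("bc_empty_eval", "no prediction/truth pairs.")
  d <- (pred_deg[ok] - truth_deg[ok]) %% 360
  d[d > 180] <- d[d > 180] - 360
  sqrt(mean(d^2))
}

#' Amplitude group of a dataset
#'
#' Datasets are split by whether any breathing cycle exceeds 12 mm
#' peak-to-trough (strictly); cycle amplitudes are the swings between
#' consecutive alternating anchors of the decomposition.
#'
#' @param dec A `bc_decomp` from [decompose_signal()].
#' @param threshold_mm Group threshold (default 12 mm, strict).
#' @return `"large"` or `"small"`.
#' @export
amplitude_group <- function(dec, threshold_mm = 12) {
  peaks <- decomp_peaks(dec)
  if (is.null(peaks) || nrow(peaks$anchors) < 2) {
    bc_abort("bc_empty_eval", "no complete breathing cycle.")
  }
  amps <- abs(diff(peaks$anchors$pos_mm))
  if (any(amps > threshold_mm)) "large" else "small"
}

#' Evaluate a streaming prediction against its decomposition
#'
#' Computes the per-dataset metrics of a prediction run: signal RMSE in mm
#' and, when the prediction carries component columns, circular phase RMSE
#' in degrees plus deflection and baseline RMSEs in mm. Only samples that
#' are valid in the decomposition and carry a prediction enter; the leading
#' gap is excluded automatically.
#'
#' @param pred A `bc_prediction` from [predict_stream()] (or
#'   [predict_persistence()]).
#' @param dec The `bc_decomp` of the same trace (the ground truth).
#' @param id Dataset identifier carried into the report.
#' @return A one-row tibble: `id`, `rmse_y_mm`, `rmse_phase_deg`,
#'   `rmse_d_mm`, `rmse_bl_mm`, `group`, `n_predictions`.
#' @export
evaluate_prediction <- function(pred, dec, id = "dataset") {
  if (nrow(pred) != nrow(dec)) {
    bc_abort("bc_shape_error", "prediction and decomposition differ in length.")
  }
  ok <- dec$valid & !is.na(pred$y_pred_mm)
  if (!any(ok)) bc_abort("bc_empty_eval", "no evaluable predictions.")
  has_comp <- "phase_pred_deg" %in% names(pred)
  tibble::tibble(
    id = id,
    rmse_y_mm = rmse(pred$y_pred_mm[ok], dec$pos_mm[ok]),
    rmse_phase_deg = if (has_comp) {
      circular_rmse(pred$phase_pred_deg[ok], dec$phase_deg[ok])
    } else NA_real_,
    rmse_d_mm = if (has_comp) {
      rmse(pred$deflection_pred_mm[ok], dec$deflection_mm[ok])
    } else NA_real_,
    rmse_bl_mm = if (has_comp) {
      rmse(pred$baseline_pred_mm[ok], dec$baseline_mm[ok])
    } else NA_real_,
    group = amplitude_group(dec),
    n_predictions = sum(ok)
  )
}

#' Cohort summary of per-dataset metrics
#'
#' Aggregates per-dataset RMSEs into mean +/- SD rows, overall ("All") and
#' per amplitude group. Datasets are weighted equally regardless of
#' duration; the SD is the sample standard deviation (n - 1), reported as 0
#' and flagged when a row holds a single dataset.
#'
#' @param per_dataset Tibble of per-dataset metrics as produced by
#'   [evaluate_prediction()] (one row per dataset).
#' @return An `bc_eval_report` tibble with one row per group ("All" first),
#'   `n`, and `mean`/`sd` columns per metric, plus `sd_flagged`.
#' @export
cohort_summary <- function(per_dataset) {
  if (nrow(per_dataset) == 0) {
    bc_abort("bc_empty_eval", "no datasets to summarise.")
  }
  metrics <- c("rmse_y_mm", "rmse_phase_deg", "rmse_d_mm", "rmse_bl_mm")
  metrics <- metrics[metrics %in% names(per_dataset)]
  one_row <- function(df, label) {
    row <- tibble::tibble(group = label, n = nrow(df),
                          sd_flagged = nrow(df) < 2)
    for (m in metrics) {
      row[[paste0("mean_", m)]] <- mean(df[[m]])
      row[[paste0("sd_", m)]] <- if (nrow(df) < 2) 0 else sd(df[[m]])
    }
    row
  }
  groups <- sort(unique(per_dataset$group))
  out <- dplyr::bind_rows(
    one_row(per_dataset, "All"),
    lapply(groups, function(g) {
      one_row(per_dataset[per_dataset$group == g, , drop = FALSE], g)
    })
  )
  class(out) <- c("bc_eval_report", class(out))
  out
}
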