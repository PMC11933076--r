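#' Reference values reported by the original analysis
#'
#' The literature-mined dataset behind the original study was never
#' deposited, so its final numbers cannot be recomputed from raw data. The
#' reported tables are embedded here as plain inputs for
#' internal-consistency checks: the evaluation metrics per label, the
#' per-label feature optima, and the aggregated optimal ranges
#' (both rounded to the display precision of the source tables).
#'
#' Two known inconsistencies in the reported values, surfaced by
#' [check_metric_consistency()] and [check_range_aggregation()]:
#' the anticancer metrics row has MAE > RMSE, which the power-mean
#' inequality rules out for any single evaluation set; and the reported
#' additive-molecular-weight optimal range is not the min/max of the
#' corresponding optima row.
#'
#' @return List with data frames \code{metrics} (label, mae, mse, rmse),
#'   \code{optima} (feature x label matrix, original units; \code{NA} where
#'   a study-time feature does not apply) and \code{ranges}
#'   (feature, range_min, range_max).
#' @export
published_reference <- function() {
  labs <- label_names()
  metrics <- data.frame(
    label = labs,
    mae  = c(43.74205, 2.35201, 3.21023, 13.14296),
    mse  = c(8361.02123, 117.63967, 47.71458, 99.67285),
    rmse = c(91.43862, 10.84618, 6.90757, 9.98362),
    stringsAsFactors = FALSE
  )
  feats <- c("polymer_mw_kda", "polymer_density_g_cm3", "additive_mw_kda",
             "additive_concentration_wt_pct", "dox_concentration_wt_pct",
             "dielectric_constant", "polymer_concentration_wt_pct",
             "flow_rate_ml_h", "distance_cm", "voltage_kv",
             "drug_release_time_d", "anticancer_study_time_d")
  optima <- matrix(c(
    80.8597, 474.8010, 318.1338, 262.0249,
    1.5299,  1.1960,   1.1983,   1.5207,
    493.0598, 188.3852, 250.7143, 83.3650,
    0.0848,  22.3219,  2.5661,   23.2383,
    1.0044,  9.6091,   2.0584,   3.1828,
    14.8257, 65.1107,  5.3971,   25.8070,
    0.2593,  7.1982,   6.6184,   0.1391,
    0.8129,  15.0100,  19.6483,  6.2994,
    15.0380, 13.0735,  14.1093,  19.5443,
    19.9763, 31.2323,  46.1441,  26.7860,
    NA,      NA,       0.2208,   NA,
    NA,      NA,       NA,       15.4382
  ), nrow = length(feats), byrow = TRUE,
  dimnames = list(feats, labs))
  ranges <- data.frame(
    feature = feats[1:10],
    range_min = c(80.85, 1.19, 83.36, 0.08, 1.01, 5.39, 0.14, 0.81, 13.07, 19.97),
    range_max = c(474.80, 1.53, 250.71, 23.23, 9.61, 65.11, 7.19, 19.65, 19.54, 46.14),
    stringsAsFactors = FALSE
  )
  list(metrics = metrics, optima = optima, ranges = ranges)
}

#' Internal-consistency check of reported evaluation metrics
#'
#' For each label, recomputes RMSE as the square root of the reported MSE
#' and compares with the reported RMSE at its display precision (5
#' decimals), and checks the power-mean requirement MAE <= RMSE.
#'
#' @param metrics Data frame with \code{label}, \code{mae}, \code{mse},
#'   \code{rmse}; default the reported values.
#' @return Data frame with \code{label}, \code{rmse_reported},
#'   \code{rmse_from_mse}, \code{rmse_consistent}, \code{mae_le_rmse}.
#' @export
check_metric_consistency <- function(metrics = published_reference()$metrics) {
  rmse_from_mse <- sqrt(metrics$mse)
  data.frame(
    label = metrics$label,
    rmse_reported = metrics$rmse,
    rmse_from_mse = rmse_from_mse,
    rmse_consistent = round(rmse_from_mse, 5) == round(metrics$rmse, 5),
    mae_le_rmse = metrics$mae <= metrics$rmse,
    stringsAsFactors = FALSE
  )
}

#' Check a reported optimal-range table against strict min/max aggregation
#'
#' Aggregates a feature-by-label optima matrix with [aggregate_optimal_ranges()]
#' and compares with a reported range table within its display precision:
#' the source table mixes rounding and truncation at two decimals, so
#' endpoints agree when they differ by at most 0.011. Disagreements are
#' flagged, not reconciled.
#'
#' @param optima Feature-by-label matrix of optima (default the reported
#'   ones).
#' @param ranges Reported range table (default the reported one).
#' @param tol Endpoint agreement tolerance (default 0.011).
#' @return Data frame: \code{feature}, computed \code{range_min}/
#'   \code{range_max}, reported endpoints, and logical \code{agrees}.
#' @export
check_range_aggregation <- function(optima = published_reference()$optima,
                                    ranges = published_reference()$ranges,
                                    tol = 0.011) {
  per_label <- lapply(label_names(), function(lab)
    stats::setNames(optima[, lab], rownames(optima)))
  names(per_label) <- label_names()
  agg <- aggregate_optimal_ranges(per_label)
  agg <- agg[match(ranges$feature, agg$feature), ]
  data.frame(
    feature = ranges$feature,
    range_min = agg$range_min, range_max = agg$range_max,
    reported_min = ranges$range_min, reported_max = ranges$range_max,
    agrees = abs(agg$range_min - ranges$range_min) <= tol &
      abs(agg$range_max - ranges$range_max) <= tol,
    stringsAsFactors = FALSE
  )
}
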