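#' Assemble a report bundle
#'
#' The bundle is the pipeline's complete output artifact: one importance
#' report, one metrics block and one optimum per label, plus the aggregated
#' optimal-range table. Completeness (every label exactly once per section)
#' is enforced at construction.
#'
#' @param importance Named list of [importance_report()]s.
#' @param metrics Named list of \code{evaluation_metrics}.
#' @param optima Named list of \code{optimization_result}s.
#' @param ranges An \code{optimal_range_table}.
#' @param meta Optional named list of run metadata (seeds, sizes, notes).
#' @return Object of class \code{report_bundle}.
#' @export
report_bundle <- function(importance, metrics, optima, ranges, meta = list()) {
  labs <- label_names()
  for (sec in list(importance = importance, metrics = metrics, optima = optima)) {
    if (!setequal(names(sec), labs) || anyDuplicated(names(sec)))
      stop("completeness error: each section needs every label exactly once",
           call. = FALSE)
  }
  structure(list(importance = importance[labs], metrics = metrics[labs],
                 optima = optima[labs], ranges = ranges, meta = meta),
            class = "report_bundle")
}

round4 <- function(x) round(x, 4)

#' Write a report bundle to JSON
#'
#' Stable key order; every numeric result carries both a full-precision
#' value and a \code{rounded} companion at 4 decimals (the display
#' convention of the published optimization tables).
#'
#' @param bundle A [report_bundle()].
#' @param path Output path.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "report_bundle"))
  labs <- label_names()
  obj <- list(
    importance = lapply(bundle$importance[labs], function(ir) {
      df <- as.data.frame(ir)
      list(label = attr(ir, "label"),
           feature = df$feature, rho = df$rho,
           relative_pct = df$relative_pct,
           rho_rounded = round4(df$rho))
    }),
    metrics = lapply(bundle$metrics[labs], function(m)
      list(mae = m$mae, mse = m$mse, rmse = m$rmse, n = m$n,
           rounded = list(mae = round4(m$mae), mse = round4(m$mse),
                          rmse = round4(m$rmse)))),
    optima = lapply(bundle$optima[labs], function(o)
      list(label = o$label, direction = o$direction,
           feature = names(o$x_opt), x_opt = as.numeric(o$x_opt),
           x_opt_rounded = round4(as.numeric(o$x_opt)),
           predicted_value = o$predicted_value,
           predicted_value_rounded = round4(o$predicted_value))),
    ranges = list(feature = bundle$ranges$feature,
                  range_min = bundle$ranges$range_min,
                  range_max = bundle$ranges$range_max,
                  range_min_rounded = round4(bundle$ranges$range_min),
                  range_max_rounded = round4(bundle$ranges$range_max)),
    meta = bundle$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a report bundle back from JSON
#'
#' @param path Path written by [write_report()].
#' @return A [report_bundle()].
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labs <- label_names()
  importance <- lapply(labs, function(lab) {
    e <- obj$importance[[lab]]
    structure(data.frame(feature = e$feature, rho = e$rho,
                         relative_pct = e$relative_pct,
                         stringsAsFactors = FALSE),
              label = e$label, class = c("importance_report", "data.frame"))
  })
  names(importance) <- labs
  metrics <- lapply(labs, function(lab) {
    m <- obj$metrics[[lab]]
    structure(list(mae = m$mae, mse = m$mse, rmse = m$rmse, n = m$n),
              class = "evaluation_metrics")
  })
  names(metrics) <- labs
  optima <- lapply(labs, function(lab) {
    o <- obj$optima[[lab]]
    structure(list(label = o$label, direction = o$direction,
                   x_opt = stats::setNames(o$x_opt, o$feature),
                   predicted_value = o$predicted_value,
                   history = NULL),
              class = "optimization_result")
  })
  names(optima) <- labs
  ranges <- structure(data.frame(feature = obj$ranges$feature,
                                 range_min = obj$ranges$range_min,
                                 range_max = obj$ranges$range_max,
                                 stringsAsFactors = FALSE),
                      class = c("optimal_range_table", "data.frame"))
  report_bundle(importance, metrics, optima, ranges,
                meta = as.list(obj$meta))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n\nSurrogate test metrics (original units):\n")
  for (lab in names(x$metrics)) {
    m <- x$metrics[[lab]]
    cat(sprintf("  %-30s MAE %10.4f  RMSE %10.4f\n", lab, m$mae, m$rmse))
  }
  cat("\nPer-label optima (original units):\n")
  for (lab in names(x$optima)) {
    o <- x$optima[[lab]]
    cat(sprintf("  %-30s %s -> predicted %.4f\n", lab, o$direction,
                o$predicted_value))
  }
  cat("\nOptimal ranges (fixed features):\n")
  r <- x$ranges
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-30s %.4f - %.4f\n", r$feature[i], r$range_min[i],
                r$range_max[i]))
  invisible(x)
}
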