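#' Spearman's rank correlation
#'
#' Ranks both series with average-rank tie handling and returns the
#' product-moment correlation of the ranks. With no ties this equals the
#' classical \eqn{r_s = 1 - 6\sum d_i^2 / (n(n^2-1))} with
#' \eqn{d_i = R(X_i) - R(Y_i)}.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("undefined correlation: constant series", call. = FALSE)
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Feature-importance report for one label
#'
#' Spearman's rho between the label and each feature in the label's feature
#' set ([feature_set()]), computed on rows where both cells are observed.
#' Relative importance is the magnitude normalized to the strongest feature:
#' \eqn{100 |\rho_i| / \max_j |\rho_j|}, so exactly one feature scores 100
#' (schema order breaks exact ties). Features with no usable overlap are
#' reported with \code{NA} and excluded from the normalization.
#'
#' Because every step of the preprocessing chain is strictly monotone per
#' column, the report is identical whether computed on raw or preprocessed
#' values (for observed cells).
#'
#' @param ds A [nanofiber_dataset()] (raw or preprocessed).
#' @param label Label column name.
#' @return Object of class \code{importance_report}: data frame with
#'   \code{feature}, \code{rho}, \code{relative_pct}, plus attributes
#'   \code{label} and \code{n_used}.
#' @export
importance_report <- function(ds, label) {
  stopifnot(inherits(ds, "nanofiber_dataset"))
  if (!label %in% colnames(ds$labels))
    stop("unknown label: ", label, call. = FALSE)
  feats <- feature_set(label)
  yall <- ds$labels[, label]
  rho <- vapply(feats, function(f) {
    xf <- ds$features[, f]
    ok <- !is.na(xf) & !ds$missing_mask[, f] & !is.na(yall)
    if (sum(ok) < 3L || diff(range(xf[ok])) == 0 || diff(range(yall[ok])) == 0)
      return(NA_real_)
    spearman_rho(xf[ok], yall[ok])
  }, numeric(1))
  mx <- max(abs(rho), na.rm = TRUE)
  rel <- 100 * abs(rho) / mx
  # exactly one entry reports 100; exact ties broken by schema order
  top <- which(!is.na(rel) & rel == 100)
  if (length(top) > 1L) rel[top[-1L]] <- 100 * (1 - .Machine$double.eps)
  res <- data.frame(feature = feats, rho = unname(rho),
                    relative_pct = unname(rel), stringsAsFactors = FALSE)
  structure(res, label = label,
            n_used = sum(!is.na(yall)), class = c("importance_report", "data.frame"))
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("Feature importance for %s (Spearman, %d features)\n",
              attr(x, "label"), nrow(x)))
  df <- as.data.frame(x)
  df <- df[order(-df$relative_pct, na.last = TRUE), ]
  df$rho <- round(df$rho, 4)
  df$relative_pct <- round(df$relative_pct, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
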