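#' Construct a nanofiber formulation dataset
#'
#' Bundles the feature matrix (original units, \code{NA} at missing cells),
#' the label matrix and the missing-cell mask into a classed object that all
#' pipeline stages consume. The mask refers to feature cells only; labels are
#' never imputed, so label \code{NA}s stay plain \code{NA}s.
#'
#' @param features Numeric matrix (n x 12) with columns named per
#'   [nanofiber_schema()].
#' @param labels Numeric matrix (n x 4) with columns named per
#'   [label_schema()].
#' @param missing_mask Logical matrix aligned to \code{features}; \code{TRUE}
#'   marks an absent cell. Defaults to \code{is.na(features)}.
#' @return An object of class \code{nanofiber_dataset}.
#' @export
nanofiber_dataset <- function(features, labels, missing_mask = NULL) {
  schema <- nanofiber_schema()
  lsc <- label_schema()
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (!identical(colnames(features), schema$name))
    features <- features[, schema$name, drop = FALSE]
  if (!identical(colnames(labels), lsc$name))
    labels <- labels[, lsc$name, drop = FALSE]
  if (is.null(missing_mask)) missing_mask <- is.na(features)
  missing_mask <- as.matrix(missing_mask)
  dimnames(missing_mask) <- dimnames(features)
  stopifnot(
    nrow(features) == nrow(labels),
    all(dim(missing_mask) == dim(features)),
    all(is.na(features[missing_mask]))
  )
  structure(
    list(features = features, labels = labels,
         missing_mask = missing_mask, schema = schema, label_schema = lsc),
    class = "nanofiber_dataset"
  )
}

#' @export
print.nanofiber_dataset <- function(x, ...) {
  cat(sprintf(
    "<nanofiber_dataset> %d records, %d features, %d labels, %d missing feature cells\n",
    nrow(x$features), ncol(x$features), ncol(x$labels), sum(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.nanofiber_dataset <- function(x) dim(x$features)

#' @export
as.data.frame.nanofiber_dataset <- function(x, ...) {
  as.data.frame(cbind(x$features, x$labels))
}

#' Read a formulation table from CSV
#'
#' The CSV dialect is strict: comma separated, UTF-8, header row with the
#' exact snake_case column names from [nanofiber_schema()] and
#' [label_schema()], "." decimal separator. Missing feature cells are empty
#' strings; literal \code{"NA"}/\code{"NaN"} tokens are rejected so that the
#' absent-cell encoding stays unambiguous.
#'
#' @param path Path to a CSV file.
#' @return A [nanofiber_dataset()].
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  schema <- nanofiber_schema()
  lsc <- label_schema()
  needed <- c(schema$name, lsc$name)
  absent <- setdiff(needed, colnames(raw))
  if (length(absent))
    stop("schema error: missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  parse_col <- function(txt, col) {
    txt <- trimws(txt)
    if (any(toupper(txt) %in% c("NA", "NAN")))
      stop(sprintf(
        "parse error: literal NA/NaN token in column '%s' (missing cells must be empty)",
        col), call. = FALSE)
    out <- rep(NA_real_, length(txt))
    nonempty <- nzchar(txt)
    val <- suppressWarnings(as.numeric(txt[nonempty]))
    if (anyNA(val)) {
      bad <- which(nonempty)[which(is.na(val))[1L]]
      stop(sprintf("parse error: non-numeric cell at row %d, column '%s': '%s'",
                   bad, col, txt[bad]), call. = FALSE)
    }
    out[nonempty] <- val
    out
  }
  features <- vapply(schema$name, function(col) parse_col(raw[[col]], col),
                     numeric(nrow(raw)))
  labels <- vapply(lsc$name, function(col) parse_col(raw[[col]], col),
                   numeric(nrow(raw)))
  if (nrow(raw) == 1L) {  # vapply drops to vector shape consistency
    features <- matrix(features, nrow = 1, dimnames = list(NULL, schema$name))
    labels <- matrix(labels, nrow = 1, dimnames = list(NULL, lsc$name))
  }
  nanofiber_dataset(features, labels)
}

#' Write a formulation table to CSV
#'
#' Inverse of [load_dataset()]: missing feature cells are written as empty
#' strings, numbers at full precision (17 significant digits) so a
#' write/load round trip is the identity.
#'
#' @param ds A [nanofiber_dataset()].
#' @param path Output path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "nanofiber_dataset"))
  m <- cbind(ds$features, ds$labels)
  txt <- apply(m, 2, function(col)
    ifelse(is.na(col), "", formatC(col, digits = 17, format = "g")))
  if (nrow(m) == 1L) txt <- matrix(txt, nrow = 1, dimnames = list(NULL, colnames(m)))
  utils::write.csv(as.data.frame(txt, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate feature and label values against schema bounds
#'
#' Default bounds are the published dataset minima and maxima, inclusive at
#' both ends. Reports violations; it never throws.
#'
#' @param ds A [nanofiber_dataset()].
#' @return Data frame with one row per out-of-bounds cell: \code{row},
#'   \code{column}, \code{value}, \code{lower}, \code{upper}. Zero rows means
#'   the dataset is valid.
#' @export
validate_bounds <- function(ds) {
  stopifnot(inherits(ds, "nanofiber_dataset"))
  out <- list()
  check <- function(m, names, lower, upper) {
    for (j in seq_along(names)) {
      v <- m[, names[j]]
      bad <- which(!is.na(v) & (v < lower[j] | v > upper[j]))
      if (length(bad))
        out[[length(out) + 1L]] <<- data.frame(
          row = bad, column = names[j], value = v[bad],
          lower = lower[j], upper = upper[j], stringsAsFactors = FALSE)
    }
  }
  check(ds$features, ds$schema$name, ds$schema$lower, ds$schema$upper)
  check(ds$labels, ds$label_schema$name, ds$label_schema$lower, ds$label_schema$upper)
  if (!length(out))
    return(data.frame(row = integer(), column = character(), value = numeric(),
                      lower = numeric(), upper = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$row, match(res$column, c(ds$schema$name, ds$label_schema$name))), ,
      drop = FALSE]
}
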