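#' Column schema for the nanofiber formulation table
#'
#' The dataset layout used throughout the package: 10 "fixed" features
#' describing the electrospinning machine settings and the materials, 2
#' study-time features, and 4 labels (responses). Column headers are fixed
#' snake_case tokens and are the single source of truth for CSV interchange.
#'
#' Default feature bounds are the minimum/maximum of the published summary
#' statistics of the literature-mined dataset, inclusive at both ends.
#' The drug-release-time column has no published statistics; its bounds and
#' anchors are synthetic stand-ins mirroring the anticancer study time.
#'
#' @return A data frame with one row per feature: \code{name}, \code{unit},
#'   \code{role} (one of \code{"machine"}, \code{"material"},
#'   \code{"study_time"}) and numeric \code{lower}, \code{upper} bounds in
#'   original units.
#' @examples
#' sc <- nanofiber_schema()
#' sum(sc$role != "study_time")  # 10 fixed features
#' @export
nanofiber_schema <- function() {
  sc <- data.frame(
    name = c(
      "flow_rate_ml_h", "distance_cm", "voltage_kv",
      "polymer_mw_kda", "polymer_density_g_cm3", "additive_mw_kda",
      "additive_concentration_wt_pct", "dox_concentration_wt_pct",
      "dielectric_constant", "polymer_concentration_wt_pct",
      "drug_release_time_d", "anticancer_study_time_d"
    ),
    unit = c(
      "mL/h", "cm", "kV", "kDa", "g/cm3", "kDa", "wt%", "wt%",
      "", "wt%", "day", "day"
    ),
    role = c(
      "machine", "machine", "machine",
      rep("material", 7),
      "study_time", "study_time"
    ),
    stringsAsFactors = FALSE
  )
  a <- default_anchors()
  sc$lower <- vapply(sc$name, function(nm) a[[nm]][1L], numeric(1))
  sc$upper <- vapply(sc$name, function(nm) a[[nm]][5L], numeric(1))
  rownames(sc) <- NULL
  sc
}

#' Label (response) schema
#'
#' @return A data frame with \code{name}, \code{unit}, \code{direction}
#'   (\code{"minimize"} for the fiber diameter, \code{"maximize"} otherwise)
#'   and default \code{lower}, \code{upper} bounds in original units.
#' @export
label_schema <- function() {
  sc <- data.frame(
    name = c(
      "average_diameter_nm", "encapsulation_efficiency_pct",
      "drug_release_pct", "anticancer_activity_pct"
    ),
    unit = c("nm", "%", "%", "%"),
    direction = c("minimize", "maximize", "maximize", "maximize"),
    stringsAsFactors = FALSE
  )
  a <- default_anchors()
  sc$lower <- vapply(sc$name, function(nm) a[[nm]][1L], numeric(1))
  sc$upper <- vapply(sc$name, function(nm) a[[nm]][5L], numeric(1))
  rownames(sc) <- NULL
  sc
}

#' Marginal anchors calibrated to the published dataset statistics
#'
#' Five-number summaries (minimum, quartiles, maximum) per column, used by
#' the synthetic generator's piecewise-linear inverse CDF and as default
#' validation bounds. Values are the printed overall statistics of the
#' literature-mined dataset; \code{drug_release_time_d} is a synthetic
#' stand-in (no statistics were published for it).
#'
#' @return Named list; each element is \code{c(min, q1, q2, q3, max)}.
#' @export
default_anchors <- function() {
  list(
    flow_rate_ml_h                = c(0.006, 0.5, 0.6, 1, 26),
    distance_cm                   = c(8, 13.21, 15, 15, 24),
    voltage_kv                    = c(0, 15, 20, 21.33, 95.4),
    polymer_mw_kda                = c(1750.36, 81000, 119250, 172000, 1300000),
    polymer_density_g_cm3         = c(0.559, 1.117, 1.19, 1.26, 1.53),
    additive_mw_kda               = c(12.01, 157.24, 234.4, 853.9, 100000),
    additive_concentration_wt_pct = c(0, 1, 4.1151, 5.4762, 30),
    dox_concentration_wt_pct      = c(0, 0.0387, 0.2, 1.8772, 26.66),
    dielectric_constant           = c(4.81, 8.55, 16.7, 31.3275, 80.1),
    polymer_concentration_wt_pct  = c(0.1, 6, 8, 10, 50),
    drug_release_time_d           = c(0.02, 1, 2, 3, 35),
    anticancer_study_time_d       = c(0.02, 1, 2, 3, 35),
    average_diameter_nm           = c(37, 267, 452.34, 750, 1500),
    encapsulation_efficiency_pct  = c(0.031, 0.7327, 2.8, 92, 99),
    drug_release_pct              = c(0.1, 0.7775, 29, 60, 99),
    anticancer_activity_pct       = c(0.07, 16.325, 35.25, 54.75, 90)
  )
}

#' Feature set used to model each label
#'
#' Diameter and encapsulation efficiency are modelled on the 10 fixed
#' features; drug release adds the release-time feature and anticancer
#' activity adds the study-time feature.
#'
#' @param label Label column name (see [label_schema()]).
#' @return Character vector of feature column names.
#' @export
feature_set <- function(label) {
  fixed <- fixed_features()
  switch(label,
    average_diameter_nm          = fixed,
    encapsulation_efficiency_pct = fixed,
    drug_release_pct             = c(fixed, "drug_release_time_d"),
    anticancer_activity_pct      = c(fixed, "anticancer_study_time_d"),
    stop("unknown label: ", label, call. = FALSE)
  )
}

#' @rdname feature_set
#' @export
fixed_features <- function() {
  sc <- nanofiber_schema()
  sc$name[sc$role != "study_time"]
}

label_names <- function() label_schema()$name
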