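#' Load a packaged cohort fixture table
#'
#' The published 16-patient cohort tables ship with the package as CSV
#' fixtures: \code{"table1"} demographics and pre/post volumes,
#' \code{"table2"} per-patient phase stresses from the one- and two-geometry
#' models (kPa), \code{"table3"} the corresponding strains, \code{"table4"}
#' cohort-level wall thickness and curvature values, \code{"table6"}
#' per-patient begin-ejection metrics with the outcome group, and
#' \code{"printed_aggregates"} the tables' printed summary rows (kept
#' verbatim, including their known internal rounding inconsistencies, for
#' transcription self-tests). Files are checksum-verified against the
#' packaged manifest on every load.
#'
#' @param name fixture name (see above).
#' @return data.frame with typed columns.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4",
                                  "table6", "printed_aggregates")) {
  name <- match.arg(name)
  files <- c(table1 = "table1_demographics.csv",
             table2 = "table2_stress.csv",
             table3 = "table3_strain.csv",
             table4 = "table4_wt_curvature.csv",
             table6 = "table6_be_metrics.csv",
             printed_aggregates = "printed_aggregates.csv")
  dir <- system.file("extdata", package = "rv2g")
  path <- file.path(dir, files[[name]])
  if (!file.exists(path)) stop("fixture file missing: ", files[[name]])
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              colClasses = "character")
  want <- manifest$md5[manifest$file == files[[name]]]
  have <- unname(tools::md5sum(path))
  if (length(want) != 1L || !identical(want, have))
    stop("fixture corruption: checksum mismatch for ", files[[name]])
  utils::read.csv(path)
}

#' List packaged fixtures with checksums
#' @return the manifest data.frame (name, file, md5).
#' @export
list_fixtures <- function() {
  utils::read.csv(system.file("extdata", "manifest.csv", package = "rv2g"),
                  colClasses = "character")
}

#' Fixture-derived predictor matrix
#'
#' Convenience wrapper: assembles the 8-predictor matrix from the packaged
#' phase-stress (table2) and begin-ejection metrics (table6) fixtures via
#' \code{\link{build_predictors}}.
#'
#' @return data.frame as returned by \code{\link{build_predictors}}.
#' @export
fixture_predictors <- function() {
  t2 <- load_fixture("table2")
  t6 <- load_fixture("table6")
  geometry <- data.frame(patient = t6$patient, group = t6$group,
                         wt = t6$wt, ccur = t6$ccur, lcur = t6$lcur,
                         edv = t6$edv)
  build_predictors(t2, geometry)
}
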