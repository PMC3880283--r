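# md5 checksums of the packaged reference tables, verified at load
.fixture_md5 <- c(
  survey_inventory = "c7f57dc3468f5f98f763ecd859f084f0",
  wealth_descriptives = "cb6de2683b3d897e3dfe5b5530b86724"
)
.fixture_rows <- c(survey_inventory = 69L, wealth_descriptives = 15L)

fixture_path <- function(name) {
  f <- system.file("extdata", paste0(name, ".tsv"), package = "aidequity")
  if (f == "") stop_ae("packaged fixture not found: ", name)
  f
}

load_fixture <- function(name) {
  f <- fixture_path(name)
  sum_ <- unname(tools::md5sum(f))
  if (sum_ != .fixture_md5[[name]])
    stop_ae("fixture ", name, " failed its checksum (", sum_, ")")
  d <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) != .fixture_rows[[name]])
    stop_ae("fixture ", name, " has ", nrow(d), " rows; manifest says ",
            .fixture_rows[[name]])
  d
}

#' Packaged study-survey inventory
#'
#' The checksummed reference table of study surveys: one row per survey with
#' the number of households with complete asset information, under-5 deaths,
#' and child-years of exposure (thousands) in the decade preceding each
#' survey.
#'
#' @return data frame with columns `country`, `survey_dates`, `households`,
#'   `deaths`, `child_years_thousands` (69 rows).
#' @export
survey_inventory <- function() load_fixture("survey_inventory")

#' Packaged sample descriptives by wealth quintile
#'
#' The checksummed reference table of asset ownership, rooms per person,
#' urban residence and period under-5 mortality (with declines) by pooled
#' wealth quintile, columns ordered poorest to wealthiest.
#'
#' @return data frame with a `variable` column and one column per quintile.
#' @export
wealth_descriptives <- function() load_fixture("wealth_descriptives")

#' Column totals of the survey inventory
#'
#' Sums the households, under-5 deaths and child-years columns over all
#' surveys of the packaged inventory (or a table with the same layout).
#'
#' @param inventory data frame as returned by [survey_inventory()]; the
#'   packaged fixture by default.
#' @return named numeric vector `households`, `deaths`,
#'   `child_years_thousands`.
#' @export
fixture_totals <- function(inventory = survey_inventory()) {
  c(households = sum(inventory$households),
    deaths = sum(inventory$deaths),
    child_years_thousands = sum(inventory$child_years_thousands))
}
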