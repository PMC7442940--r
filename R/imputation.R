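#' Read a population-average imputation table
#'
#' When a user does not know their blood pressure or cholesterol level,
#' the calculator substitutes the population average for their sex and
#' 5-year age band. The table is a CSV with columns `sex`, `age_min`,
#' `age_max`, `sbp` (mmHg), `total_cholesterol` and `hdl_cholesterol`
#' (mmol/L); bands must tile the 35-75 target range per sex with no
#' gaps. HDL is never user-entered, so it always comes from this table.
#'
#' The table shipped with the package
#' (`inst/extdata/imputation-synthetic.csv`) is a synthetic stand-in
#' with clinically plausible Australian adult values: the national
#' health-survey band means used by the deployed calculator are not
#' public. Replace it with real survey means for production use.
#'
#' @param path CSV path; defaults to the shipped synthetic table.
#' @return An object of class `imputation_table`.
#' @export
read_imputation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "imputation-synthetic.csv",
                        package = "heartage", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_min", "age_max", "sbp", "total_cholesterol",
                "hdl_cholesterol")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("imputation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (sx in unique(tab$sex)) {
    sub <- tab[tab$sex == sx, ]
    sub <- sub[order(sub$age_min), ]
    if (any(sub$age_min[-1] != sub$age_max[-nrow(sub)] + 1)) {
      stop("imputation bands for ", sx, " do not tile without gaps",
           call. = FALSE)
    }
  }
  structure(tab, class = c("imputation_table", "data.frame"))
}

lookup_band <- function(table, sex, age) {
  hit <- table$sex == sex & table$age_min <= age & age <= table$age_max
  if (!any(hit)) {
    stop(sprintf("no imputation band covers sex=%s age=%g", sex, age),
         call. = FALSE)
  }
  table[which(hit)[1], ]
}

#' Fill unknown risk factors from population averages
#'
#' Replaces an unknown systolic blood pressure or total cholesterol
#' with the band mean for the profile's sex and age; known values are
#' untouched. HDL cholesterol is always taken from the table (it is not
#' collected from users). The original known/unknown flags are
#' preserved so reports can state that a population average was used.
#'
#' @param profile A [risk_profile()].
#' @param table An [read_imputation_table()] result.
#' @return The profile with no remaining unknowns.
#' @export
impute_unknowns <- function(profile, table = read_imputation_table()) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(table, "imputation_table"))
  band <- lookup_band(table, profile$sex, profile$age)
  if (!profile$sbp_known || is.na(profile$sbp)) {
    profile$sbp <- band$sbp
  }
  if (!profile$cholesterol_known || is.na(profile$total_cholesterol)) {
    profile$total_cholesterol <- band$total_cholesterol
  }
  profile$hdl_cholesterol <- band$hdl_cholesterol
  profile
}
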