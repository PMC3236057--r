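#' Synthetic linear reference equations for predicted normal values
#'
#' Returns a reference table with one row per variable and sex giving the
#' coefficients of a linear predicted-value model
#' `predicted = intercept + age_coef * age_years + height_coef * height_cm`.
#'
#' These are *synthetic defaults*: round-number coefficients chosen to give
#' physiologically plausible predicted values over the supported demographic
#' range (ages 16-70 years, heights 145-200 cm), so that percent-of-predicted
#' machinery can be exercised end to end. They are not any published reference
#' equation; analyses of real data should supply their own table with the same
#' columns (for example via [read_reference_set()]).
#'
#' Units: FEV1/FVC/TLC/FRC/RV in L BTPS, CO_uptake in mmol min^-1 kPa^-1,
#' N2_slope in % N2 per L.
#'
#' @return A tibble with columns `variable`, `sex` ("M"/"F"), `intercept`,
#'   `age_coef`, `height_coef`.
#' @export
#' @examples
#' refset <- default_reference_set()
#' predicted_value("FEV1", "M", age_years = 40, height_cm = 178, refset)
default_reference_set <- function() {
  tribble_rows <- list(
    # variable, sex, intercept, age_coef, height_coef
    list("FEV1", "M", -2.50, -0.028, 0.0430),
    list("FEV1", "F", -2.00, -0.022, 0.0370),
    list("FVC", "M", -4.00, -0.026, 0.0550),
    list("FVC", "F", -2.70, -0.024, 0.0450),
    list("TLC", "M", -7.00, 0.000, 0.0800),
    list("TLC", "F", -5.60, 0.000, 0.0660),
    list("FRC", "M", -5.00, 0.008, 0.0500),
    list("FRC", "F", -4.50, 0.005, 0.0450),
    list("RV", "M", -3.40, 0.017, 0.0270),
    list("RV", "F", -3.80, 0.016, 0.0280),
    list("CO_uptake", "M", -6.00, -0.066, 0.1100),
    list("CO_uptake", "F", -4.50, -0.050, 0.0900),
    list("N2_slope", "M", 0.40, 0.022, 0.0000),
    list("N2_slope", "F", 0.40, 0.022, 0.0000)
  )
  out <- dplyr::bind_rows(lapply(tribble_rows, function(r) {
    tibble::tibble(
      variable = r[[1]], sex = r[[2]],
      intercept = r[[3]], age_coef = r[[4]], height_coef = r[[5]]
    )
  }))
  out
}

#' Read a reference-equation table from a TSV file
#'
#' The file must have columns `variable`, `sex`, `intercept`, `age_coef`,
#' `height_coef`; lines starting with `#` are treated as comments (use them to
#' document units and provenance).
#'
#' @param path Path to a tab-separated reference table.
#' @return A tibble with the same columns as [default_reference_set()].
#' @export
read_reference_set <- function(path) {
  if (!file.exists(path)) {
    config_error(sprintf("reference table not found: %s", path))
  }
  ref <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  needed <- c("variable", "sex", "intercept", "age_coef", "height_coef")
  missing <- setdiff(needed, names(ref))
  if (length(missing) > 0) {
    config_error(sprintf(
      "reference table %s lacks column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  ref
}

#' Predicted normal value for a variable and demographics
#'
#' @param variable Variable name (see [lung_function_variables()]).
#' @param sex "M" or "F".
#' @param age_years Age in years.
#' @param height_cm Standing height in cm.
#' @param refset Reference table, as from [default_reference_set()].
#' @return Predicted value in the variable's units (vectorised over
#'   demographics).
#' @export
predicted_value <- function(variable, sex, age_years, height_cm,
                            refset = default_reference_set()) {
  key <- paste(refset$variable, refset$sex)
  idx <- match(paste(variable, sex), key)
  if (anyNA(idx)) {
    bad <- unique(paste(variable, sex)[is.na(idx)])
    config_error(sprintf("no reference equation for: %s", paste(bad, collapse = ", ")))
  }
  pred <- refset$intercept[idx] + refset$age_coef[idx] * age_years +
    refset$height_coef[idx] * height_cm
  if (any(pred <= 0)) {
    config_error("reference equation gives non-positive predicted value; demographics outside supported range")
  }
  pred
}

#' Express a measurement in percent of the predicted normal value
#'
#' @param value Measured value (same units as the reference equation).
#' @inheritParams predicted_value
#' @return `100 * value / predicted`, vectorised.
#' @export
#' @examples
#' refset <- default_reference_set()
#' pred <- predicted_value("FEV1", "F", 30, 165, refset)
#' percent_predicted(pred, "FEV1", "F", 30, 165, refset) # 100
percent_predicted <- function(value, variable, sex, age_years, height_cm,
                              refset = default_reference_set()) {
  100 * value / predicted_value(variable, sex, age_years, height_cm, refset)
}
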