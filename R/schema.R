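#' Clinical parameter schema
#'
#' A parameter schema is the closed list of clinical parameters a cohort may
#' contain: laboratory tests and vital signs, each with a unit and a
#' machine-friendly identifier used for feature naming. The packaged default
#' ([default_parameter_schema()]) holds the 25-parameter general-ward panel
#' (19 laboratory tests and 6 vital signs) used throughout the package.
#'
#' @param parameter character vector of parameter display names (unique).
#' @param unit character vector of unit strings, same length.
#' @param kind character vector, each `"lab"` or `"vital"`.
#' @return A `parameter_schema`: a [data.table::data.table] with columns
#'   `parameter`, `unit`, `kind` and `id` (sanitized identifier).
#' @examples
#' sch <- default_parameter_schema()
#' nrow(sch)           # 25
#' sum(sch$kind == "vital")  # 6
#' @export
parameter_schema <- function(parameter, unit, kind) {
  stopifnot(length(parameter) == length(unit), length(parameter) == length(kind))
  if (anyDuplicated(parameter)) {
    stop("parameter names must be unique; duplicated: ",
         paste(unique(parameter[duplicated(parameter)]), collapse = ", "))
  }
  if (!all(kind %in% c("lab", "vital"))) {
    stop("kind must be 'lab' or 'vital'")
  }
  sch <- data.table(
    parameter = as.character(parameter),
    unit = as.character(unit),
    kind = as.character(kind),
    id = clean_id(parameter)
  )
  if (anyDuplicated(sch$id)) stop("sanitized parameter ids collide")
  setattr(sch, "class", c("parameter_schema", class(sch)))
  sch[]
}

## turn display names into identifier-safe tokens
clean_id <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  x
}

#' @rdname parameter_schema
#' @export
default_parameter_schema <- function() {
  labs <- c(
    "P(aB)-Hydrogen carbonate" , "mmol/L",
    "P(aB)-Potassium"          , "mmol/L",
    "P-Bilirubin"              , "umol/L",
    "P(aB)-pO2"                , "kPa",
    "B-Leukocytes"             , "10^9/L",
    "P-Potassium"              , "mmol/L",
    "P(aB)-pCO2"               , "kPa",
    "B-Neutrophils"            , "10^9/L",
    "P-Glucose"                , "mmol/L",
    "P(aB)-pH"                 , "pH",
    "B-Platelets"              , "10^9/L",
    "P-C-reactive protein"     , "mg/L",
    "P(aB)-Lactate"            , "mmol/L",
    "P-Sodium"                 , "mmol/L",
    "eGFR"                     , "mL/min/1.73m2",
    "P(aB)-Sodium"             , "mmol/L",
    "P-Albumin"                , "g/L",
    "P(aB)-Chloride"           , "mmol/L",
    "P-Creatinine"             , "umol/L"
  )
  vitals <- c(
    "Systolic blood pressure"  , "mmHg",
    "Diastolic blood pressure" , "mmHg",
    "Pulse"                    , "/min",
    "Respiratory frequency"    , "/min",
    "SpO2"                     , "%",
    "Temperature"              , "degC"
  )
  lab_m <- matrix(labs, ncol = 2, byrow = TRUE)
  vit_m <- matrix(vitals, ncol = 2, byrow = TRUE)
  parameter_schema(
    parameter = c(lab_m[, 1], vit_m[, 1]),
    unit = c(lab_m[, 2], vit_m[, 2]),
    kind = c(rep("lab", nrow(lab_m)), rep("vital", nrow(vit_m)))
  )
}

assert_schema <- function(schema) {
  if (!inherits(schema, "parameter_schema")) stop("not a parameter_schema")
  invisible(schema)
}

#' Names of the vital-sign parameters in a schema
#' @param schema a `parameter_schema`.
#' @return character vector of display names.
#' @export
vital_parameters <- function(schema) {
  assert_schema(schema)
  schema$parameter[schema$kind == "vital"]
}
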