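# Feature registry: the closed vocabulary of model input variables, their
# measurement class, sampling tier, plausibility ranges and imputation policy.

#' Default ICU feature registry
#'
#' Returns the registry of the 41 model input variables: seven continuously
#' monitored vital signs (the high-frequency tier routed through the recurrent
#' stream), four Glasgow Coma Scale fields, 24 laboratory biochemical markers,
#' four vasoactive medication dose records and two demographic variables
#' (age, gender). All non-vital variables form the 34-entry low-frequency
#' tier consumed by the feed-forward stream.
#'
#' Each row carries the variable's plausibility range in native units (values
#' outside it are treated as invalid and set missing), its imputation policy
#' (`training_mean` for physiological measurements, `physiologic_default` for
#' variables whose absence is informative: vasopressor doses default to 0,
#' FiO2 to room air), the carry-forward lookback horizon used when assembling
#' windows and SOFA timelines, and a flag marking the variables that feed the
#' six SOFA organ systems.
#'
#' @param extra_vars optional data.frame of additional rows with the same
#'   columns, appended after validation (for custom registries).
#' @return a data.frame with columns `variable`, `class`, `tier`, `low`,
#'   `high`, `unit`, `imputation`, `default`, `lookback_h`, `sofa_related`.
#' @export
feature_registry <- function(extra_vars = NULL) {
  row <- function(variable, class, tier, low, high, unit, imputation,
                  default, lookback_h, sofa_related) {
    data.frame(variable = variable, class = class, tier = tier,
               low = low, high = high, unit = unit, imputation = imputation,
               default = default, lookback_h = lookback_h,
               sofa_related = sofa_related, stringsAsFactors = FALSE)
  }
  vit <- function(v, lo, hi, unit, sofa = FALSE)
    row(v, "vital", "high_frequency", lo, hi, unit, "training_mean", NA_real_, 4, sofa)
  lab <- function(v, lo, hi, unit, sofa = FALSE, imput = "training_mean", def = NA_real_)
    row(v, "lab", "low_frequency", lo, hi, unit, imput, def, 24, sofa)
  med <- function(v, hi)
    row(v, "medication", "low_frequency", 0, hi, "ug/kg/min",
        "physiologic_default", 0, 4, TRUE)

  reg <- rbind(
    # high-frequency vitals (hourly monitoring)
    vit("HR", 20, 300, "bpm"),
    vit("SBP", 30, 300, "mmHg"),
    vit("DBP", 20, 200, "mmHg"),
    vit("MBP", 20, 250, "mmHg", sofa = TRUE),
    vit("Temperature", 25, 45, "degC"),
    vit("SpO2", 50, 100, "%"),
    vit("Resp_Rate", 4, 60, "breaths/min"),
    # Glasgow Coma Scale fields (recorded with nursing assessments)
    lab("GCS", 3, 15, "points", sofa = TRUE),
    lab("GCS_Motor", 1, 6, "points", sofa = TRUE),
    lab("GCS_Verbal", 1, 5, "points", sofa = TRUE),
    lab("GCS_Eyes", 1, 4, "points", sofa = TRUE),
    # laboratory biochemical markers
    lab("PaO2", 30, 600, "mmHg", sofa = TRUE),
    lab("Hematocrit", 10, 70, "%"),
    lab("Hemoglobin", 3, 25, "g/dL"),
    lab("WBC", 0.1, 200, "K/uL"),
    lab("Creatinine", 0.1, 20, "mg/dL", sofa = TRUE),
    lab("BUN", 1, 200, "mg/dL"),
    lab("Sodium", 110, 175, "mEq/L"),
    lab("Albumin", 0.5, 6, "g/dL"),
    lab("Bilirubin", 0.1, 50, "mg/dL", sofa = TRUE),
    lab("Glucose", 20, 1000, "mg/dL"),
    lab("pH", 6.6, 7.8, ""),
    lab("PaCO2", 10, 150, "mmHg"),
    lab("PaO2FiO2", 30, 700, "mmHg", sofa = TRUE),
    lab("Platelet", 1, 2000, "K/uL", sofa = TRUE),
    lab("PT", 5, 150, "s"),
    lab("Potassium", 1, 10, "mEq/L"),
    lab("ALT", 1, 10000, "IU/L"),
    lab("AST", 1, 10000, "IU/L"),
    lab("Base_Excess", -35, 35, "mEq/L"),
    lab("Chloride", 70, 140, "mEq/L"),
    lab("Total_CO2", 5, 60, "mEq/L"),
    lab("Lactate", 0.1, 30, "mmol/L"),
    lab("Free_Calcium", 0.3, 3, "mmol/L"),
    lab("FiO2", 21, 100, "%", sofa = TRUE,
        imput = "physiologic_default", def = 21),
    # vasoactive medication doses; unrecorded means not administered
    med("Epinephrine", 5),
    med("Norepinephrine", 5),
    med("Dopamine", 50),
    med("Dobutamine", 50),
    # demographics from the stay manifest (not the event stream)
    row("Age", "demographic", "low_frequency", 18, 120, "years",
        "training_mean", NA_real_, Inf, FALSE),
    row("Gender", "demographic", "low_frequency", NA, NA, "",
        "physiologic_default", NA_real_, Inf, FALSE)
  )
  if (!is.null(extra_vars)) reg <- rbind(reg, extra_vars)
  validate_registry(reg)
  rownames(reg) <- NULL
  reg
}

#' Validate a feature registry
#'
#' Checks the structural invariants the pipeline relies on: unique variable
#' names, exactly seven high-frequency variables all of class vital, and a
#' plausibility range for every non-categorical variable.
#'
#' @param registry a registry data.frame as returned by [feature_registry()].
#' @return the registry, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(registry) {
  needed <- c("variable", "class", "tier", "low", "high", "unit",
              "imputation", "default", "lookback_h", "sofa_related")
  missing_cols <- setdiff(needed, names(registry))
  if (length(missing_cols))
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(registry$variable))
    stop("registry has duplicated variable names")
  hf <- registry$variable[registry$tier == "high_frequency"]
  if (length(hf) != 7L)
    stop("registry must contain exactly 7 high-frequency variables, found ",
         length(hf))
  if (!all(registry$class[registry$tier == "high_frequency"] == "vital"))
    stop("every high-frequency variable must be of class 'vital'")
  bad_tier <- setdiff(unique(registry$tier), c("high_frequency", "low_frequency"))
  if (length(bad_tier)) stop("unknown tier: ", paste(bad_tier, collapse = ", "))
  invisible(registry)
}

#' High- and low-frequency variable names
#'
#' @param registry a feature registry.
#' @return character vector of variable names in registry order.
#' @export
high_frequency_vars <- function(registry)
  registry$variable[registry$tier == "high_frequency"]

#' @rdname high_frequency_vars
#' @export
low_frequency_vars <- function(registry)
  registry$variable[registry$tier == "low_frequency"]

#' SOFA-related variable names
#'
#' The registry rows flagged as feeding one of the six SOFA organ systems
#' (oxygenation, platelets, bilirubin, mean arterial pressure plus the four
#' vasoactive drugs, the GCS fields and creatinine). Used by the
#' feature-subset evaluation harness.
#'
#' @param registry a feature registry.
#' @return character vector of variable names.
#' @export
sofa_related_vars <- function(registry)
  registry$variable[registry$sofa_related]

# event-stream variables (everything not taken from the stay manifest)
event_vars <- function(registry)
  registry$variable[registry$class != "demographic"]
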