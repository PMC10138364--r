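#' Patient-state variable schema
#'
#' The 21 care-plan input variables, each with its closed value set. The
#' published variable list leaves several value sets open-ended ("etc.");
#' this schema closes them with representative clinical values so that
#' states can be validated, sampled and split on deterministically.
#'
#' @return Named list mapping variable code to its character value set.
#' @export
patient_state_schema <- function() {
  list(
    MoveC = c("lying", "sitting_in_wheelchair", "with_assistive_devices",
              "independent"),
    RiskC = c("none", "low", "medium", "high"),
    Bedsores = c("yes", "no"),
    Diseases = c("none", "heart_failure", "alzheimer", "dementia", "cancer",
                 "diabetes", "other"),
    Med = c("none", "antibiotics", "antihypertensives", "antidepressants",
            "analgesics", "other"),
    BMI = c("stable", "lt0.5_plus", "lt0.5_minus", "0.5_1_plus",
            "0.5_1_minus", "gt1_plus", "gt1_minus"),
    MoveH = c("unchanged", "slowed down", "increased",
              "falling on the ground"),
    EatH = c("parenteral_nutrition", "fed_by_another_person",
             "independent_eating"),
    EatC = c("swallows_solid_food", "swallows_only_mashed_food",
             "swallows_only_liquids"),
    Bowel = c("regular", "diarrhoea", "constipation", "faecal_incontinence"),
    Sleep = c("lt4h", "4_6h", "6_8h", "gt8h", "apnoea"),
    Breath = c("normal", "increased", "slowing_down", "with_apnoeas"),
    PL = c("normal", "bradycardia", "tachycardia"),
    BP = c("normotension", "hypotension", "hypertension_mild",
           "hypertension_moderate", "hypertension_severe"),
    Temp = c("lt36.0", "36.0_37.4", "37.5_38.4", "gt38.4"),
    Sat = c("ge94", "lt94"),
    Urine = c("normal", "concentrated", "very_frequent", "scarce"),
    Fluid = c("lt500ml", "ge500ml"),
    Gly = c("lt2.5", "ge2.5"),
    Con = c("unchanged", "changed", "unconscious"),
    Pain = c("none", "mild", "moderate", "severe", "unbearable")
  )
}

#' Construct a patient state
#'
#' A patient state holds the 21 categorical care variables plus
#' demographics (first/last name, birth date, height in metres).
#'
#' @param ... Named variable values (codes as in [patient_state_schema()]).
#' @param first_name,last_name,birth_date Demographics.
#' @param height Height in metres; must lie in \[1.20, 2.20\].
#' @return An object of class `patient_state` (a named list).
#' @export
patient_state <- function(..., first_name = "", last_name = "",
                          birth_date = NA, height = 1.70) {
  vars <- list(...)
  if (length(vars) == 1 && is.null(names(vars)) && is.list(vars[[1]])) {
    vars <- vars[[1]]
  }
  st <- structure(c(vars,
                    list(first_name = first_name, last_name = last_name,
                         birth_date = birth_date, height = as.numeric(height))),
                  class = "patient_state")
  validate_patient_state(st)
  st
}

#' Validate a patient state against the schema
#'
#' @param state A `patient_state` or named list.
#' @return `TRUE` invisibly; otherwise an error listing every offending
#'   field.
#' @export
validate_patient_state <- function(state) {
  schema <- patient_state_schema()
  problems <- character(0)
  for (v in names(schema)) {
    val <- state[[v]]
    if (is.null(val) || is.na(val)) {
      problems <- c(problems, sprintf("%s: missing", v))
    } else if (!val %in% schema[[v]]) {
      problems <- c(problems, sprintf("%s: invalid value '%s'", v, val))
    }
  }
  h <- state[["height"]]
  if (!is.null(h) && !is.na(h) && (h < 1.20 || h > 2.20)) {
    problems <- c(problems, sprintf("height: %.2f outside [1.20, 2.20] m", h))
  }
  if (length(problems) > 0) {
    stop("invalid patient state:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' @export
print.patient_state <- function(x, ...) {
  schema <- patient_state_schema()
  cat("<patient_state>\n")
  for (v in names(schema)) cat(sprintf("  %-9s %s\n", v, x[[v]]))
  cat(sprintf("  height    %.2f m\n", x[["height"]]))
  invisible(x)
}

#' Read patient states from JSON or CSV
#'
#' JSON holds a list of objects keyed by variable code; CSV one state per
#' row with variable codes as column names.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return List of `patient_state` objects.
#' @export
read_patient_states <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(doc, function(x) patient_state(
      x[setdiff(names(x), c("first_name", "last_name", "birth_date", "height"))],
      first_name = x$first_name %||% "", last_name = x$last_name %||% "",
      birth_date = x$birth_date %||% NA,
      height = x$height %||% 1.70)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    patient_state(
      row[intersect(names(row), names(patient_state_schema()))],
      first_name = row$first_name %||% "", last_name = row$last_name %||% "",
      birth_date = row$birth_date %||% NA, height = row$height %||% 1.70)
  })
}

#' Write patient states to JSON
#'
#' @param states List of `patient_state` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_states <- function(states, path) {
  jsonlite::write_json(lapply(states, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
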