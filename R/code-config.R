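#' Default clinical code configuration
#'
#' Code sets driving cohort selection, covariate flags, and claim
#' classification. Patterns match a code when they equal it or are a prefix of
#' it, so `"J44"` covers `"J44.9"`. The sets shipped here are small
#' illustrative defaults chosen to exercise every rule in the pipeline; a real
#' study would substitute its full ICD-9/10, HCPCS and drug lists, either by
#' editing the returned list or via [read_code_config()].
#'
#' @return A named list with elements:
#'   `drug_a`, `drug_b` (the two index antifibrotics; `drug_a` receives the
#'   titration adjustment), `ipf`, `other_ild`, `copd`, `stroke`, `pneumonia`,
#'   `cardiovascular`, `cancer`, `lung_cancer`, `dyspnea` (diagnosis pattern
#'   sets), `oxygen_proc`, `transplant_proc` (procedure pattern sets),
#'   `opioid_drugs`, `respiratory_drugs` (pharmacy drug-name sets),
#'   `respiratory_dx` (first-position diagnosis patterns defining
#'   respiratory-related medical claims), and `nondiagnostic_excluded_types`
#'   (claim types that do not count as non-diagnostic evidence of disease).
#' @export
#' @examples
#' cc <- default_code_config()
#' cc$ipf
default_code_config <- function() {
  list(
    drug_a = "pirfenidone",
    drug_b = "nintedanib",
    titration_drug = "pirfenidone",
    ipf = c("J84.112", "516.3", "516.31"),
    other_ild = c("D86", "J67", "M05", "M06", "J70.1",
                  "J60", "J61", "J62", "J63", "J64"),
    copd = c("J44", "490", "491", "492", "496"),
    stroke = c("I63", "434"),
    pneumonia = c("J18", "J15", "481", "486"),
    cardiovascular = c("I20", "I21", "I25"),
    cancer = c("C"),
    lung_cancer = c("C34"),
    dyspnea = c("R06.0", "786.0"),
    oxygen_proc = c("E0424", "E0431", "E1390"),
    opioid_drugs = c("oxycodone", "hydrocodone", "morphine", "tramadol"),
    transplant_proc = c("33935", "0BYC0Z0", "0BYD0Z0"),
    respiratory_dx = c("J", "516", "481", "486", "490", "491", "492",
                       "493", "494", "496", "786.0"),
    respiratory_drugs = c("pirfenidone", "nintedanib", "prednisone",
                          "azathioprine", "acetylcysteine",
                          "mycophenolate mofetil", "azithromycin",
                          "levofloxacin"),
    nondiagnostic_excluded_types = c("lab", "radiology")
  )
}

#' Read a code configuration from a YAML file
#'
#' Reads a file with the same structure as [default_code_config()]; keys
#' missing from the file fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A code-configuration list.
#' @export
read_code_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_code_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

#' Default Charlson (Deyo) condition-to-weight map
#'
#' One row per (condition, code pattern); a condition contributes its weight
#' once no matter how many of its codes appear. This is an illustrative subset
#' of the Deyo ICD-10 mapping, sufficient for testing; swap in an authoritative
#' map for production use.
#'
#' @return A tibble with columns `condition`, `weight`, `pattern`.
#' @export
default_charlson_map <- function() {
  map <- list(
    mi = list(1, c("I21", "I22")),
    chf = list(1, "I50"),
    pvd = list(1, c("I70", "I71")),
    cerebrovascular = list(1, "I6"),
    dementia = list(1, c("F00", "F01", "F02", "F03", "G30")),
    chronic_pulmonary = list(1, paste0("J4", 0:7)),
    rheumatic = list(1, c("M05", "M06")),
    peptic_ulcer = list(1, c("K25", "K26", "K27", "K28")),
    mild_liver = list(1, c("K70", "K73", "K74")),
    diabetes = list(1, c("E10", "E11")),
    hemiplegia = list(2, c("G81", "G82")),
    renal = list(2, c("N18", "N19")),
    malignancy = list(2, c("C0", "C1", "C2", "C3", "C4", "C5", "C6",
                           "C80", "C81", "C82", "C83", "C85", "C90",
                           "C91", "C92")),
    severe_liver = list(3, "K72"),
    metastatic = list(6, c("C77", "C78", "C79")),
    aids = list(6, "B20")
  )
  dplyr::bind_rows(lapply(names(map), function(cn) {
    tibble(condition = cn, weight = map[[cn]][[1]], pattern = map[[cn]][[2]])
  }))
}

#' Medical-care CPI table for cost inflation
#'
#' Annual values of the medical care component of the US Consumer Price Index,
#' used to express paid amounts in reference-year (default 2017) dollars.
#'
#' @return A tibble with columns `year` and `cpi`.
#' @export
default_cpi_table <- function() {
  tibble(
    year = 2013:2019,
    cpi = c(425.134, 435.292, 446.752, 463.675, 475.323, 484.706, 498.425)
  )
}
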