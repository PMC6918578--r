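# Thermodynamic property records and inverse-variance reconciliation.
#
# A thermo table is a plain data.frame with one row per literature estimate
# of a formation property. Units follow the usual convention of formation
# tables: kJ/mol for Gibbs energy and enthalpy, J/(mol K) for entropy and
# heat capacity. `property` takes one of:
#   formation_gibbs, formation_enthalpy, entropy,
#   heat_capacity, heat_capacity_b, heat_capacity_c
# where the last two are the linear and quadratic coefficients of a
# polynomial heat-capacity model Cp(T) = a + b T + c T^2.

THERMO_PROPERTIES <- c(
  "formation_gibbs", "formation_enthalpy", "entropy",
  "heat_capacity", "heat_capacity_b", "heat_capacity_c"
)

#' Construct a table of thermodynamic records
#'
#' @param species_id character vector of species identifiers.
#' @param property one of `formation_gibbs`, `formation_enthalpy`,
#'   `entropy`, `heat_capacity`, `heat_capacity_b`, `heat_capacity_c`.
#' @param value property value; kJ/mol for Gibbs energy and enthalpy,
#'   J/(mol K) for entropy and heat capacity.
#' @param uncertainty one-sigma standard uncertainty, same units as `value`.
#' @param temperature_ref reference temperature in kelvin (default 298.15).
#' @param source_label free-text provenance label.
#' @return a `data.frame` of class `thermo_table`.
#' @export
thermo_records <- function(species_id, property, value,
                           uncertainty = 0,
                           temperature_ref = 298.15,
                           source_label = "unspecified") {
  tab <- data.frame(
    species_id = as.character(species_id),
    property = as.character(property),
    value = as.numeric(value),
    uncertainty = as.numeric(uncertainty),
    temperature_ref = as.numeric(temperature_ref),
    source_label = as.character(source_label),
    stringsAsFactors = FALSE
  )
  validate_thermo_table(tab)
}

#' Validate (and class) a thermodynamic record table
#'
#' Checks required columns, property names, nonnegative uncertainties and
#' positive reference temperatures.
#'
#' @param tab a data.frame of thermodynamic records.
#' @return the table with class `thermo_table`.
#' @export
validate_thermo_table <- function(tab) {
  need <- c("species_id", "property", "value", "uncertainty",
            "temperature_ref", "source_label")
  missing_cols <- setdiff(need, names(tab))
  assert_that(length(missing_cols) == 0,
              "thermo table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(tab$property), THERMO_PROPERTIES)
  assert_that(length(bad) == 0, "unknown thermo property: %s",
              paste(bad, collapse = ", "))
  assert_that(all(tab$uncertainty >= 0), "uncertainty must be >= 0")
  assert_that(all(tab$temperature_ref > 0), "temperature_ref must be > 0")
  class(tab) <- unique(c("thermo_table", class(tab)))
  tab
}

#' Read a thermodynamic record table from tab-separated text
#'
#' Expects the header `species_id property value uncertainty T_ref source`
#' (the canonical interchange header) or the internal column names.
#'
#' @param path path to a TSV file.
#' @return a `thermo_table` data.frame.
#' @export
read_thermo_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  ren <- c(T_ref = "temperature_ref", source = "source_label")
  for (old in names(ren)) {
    if (old %in% names(tab)) names(tab)[names(tab) == old] <- ren[[old]]
  }
  validate_thermo_table(tab)
}

#' Write a thermodynamic record table as tab-separated text
#'
#' @param tab a `thermo_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thermo_table <- function(tab, path) {
  tab <- validate_thermo_table(tab)
  out <- tab[, c("species_id", "property", "value", "uncertainty",
                 "temperature_ref", "source_label")]
  names(out) <- c("species_id", "property", "value", "uncertainty",
                  "T_ref", "source")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged reference thermodynamic table for the methanol/formaldehyde system
#'
#' Formation data (transformed standard state, water at unit activity) for
#' methanol, free formaldehyde, methylene glycol and the NAD redox pair,
#' encoding the literature-reconciled Gibbs energy of formation of the
#' aqueous formaldehyde/methylene-glycol pool, 130.54 +/- 3.3 kJ/mol, and
#' reaction enthalpies consistent with the reported temperature dependence
#' of the alcohol-dehydrogenase equilibrium.
#'
#' @return a `thermo_table` data.frame.
#' @export
reference_thermo_table <- function() {
  read_thermo_table(system.file("extdata", "formaldehyde_thermo.tsv",
                                package = "methylopath", mustWork = TRUE))
}

#' Packaged compilation of pool formation-energy estimates
#'
#' A small set of independent literature-style estimates of the formation
#' Gibbs energy of the formaldehyde/methylene-glycol pool, suitable for
#' [reconcile()]. Synthetic records constructed so that their
#' inverse-variance reconciliation equals the published consensus value.
#'
#' @return a `thermo_table` data.frame.
#' @export
pool_compilation_records <- function() {
  read_thermo_table(system.file("extdata", "formaldehyde_pool_compilation.tsv",
                                package = "methylopath", mustWork = TRUE))
}

#' Reconcile repeated estimates of one thermodynamic property
#'
#' Combines independent estimates of a single property of a single species
#' by inverse-variance weighting. The combined standard error is inflated
#' by the Birge ratio sqrt(chi2/(n-1)) whenever the reduced chi-square of
#' the weighted mean exceeds one, the standard treatment of mutually
#' inconsistent literature data.
#'
#' @param records a `thermo_table` (or plain data.frame with the same
#'   columns) holding at least one record, all for the same species and
#'   property, each with strictly positive uncertainty.
#' @return a list with elements `value`, `uncertainty`, `n`,
#'   `chi2_reduced` and `birge_ratio` (the inflation actually applied,
#'   floored at 1).
#' @export
reconcile <- function(records) {
  records <- validate_thermo_table(as.data.frame(records))
  assert_that(nrow(records) >= 1, "reconcile: empty record list")
  assert_that(length(unique(records$species_id)) == 1,
              "reconcile: records mix species: %s",
              paste(unique(records$species_id), collapse = ", "))
  assert_that(length(unique(records$property)) == 1,
              "reconcile: records mix properties: %s",
              paste(unique(records$property), collapse = ", "))
  assert_that(all(records$uncertainty > 0),
              "reconcile: all uncertainties must be > 0")

  w <- 1 / records$uncertainty^2
  m <- sum(w * records$value) / sum(w)
  se <- sqrt(1 / sum(w))
  n <- nrow(records)
  if (n > 1) {
    chi2_red <- sum(w * (records$value - m)^2) / (n - 1)
    birge <- max(1, sqrt(chi2_red))
  } else {
    chi2_red <- NA_real_
    birge <- 1
  }
  list(value = m, uncertainty = birge * se, n = n,
       chi2_reduced = chi2_red, birge_ratio = birge)
}
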