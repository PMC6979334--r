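#' Kinetic constants for trait derivation
#'
#' Bundles the biochemical constants used throughout the trait-derivation
#' equations: the CO2 compensation point in the absence of daytime
#' respiration (`gamma_star`), daytime respiration (`Rd`), the product of
#' leaf absorptance and PSII partitioning (`alpha_beta`), the Rubisco
#' Michaelis constants for carboxylation (`Kc`) and oxygenation (`Ko`),
#' intercellular O2 (`Oi`), and the acceptance window for the dCc/dA
#' quality criterion applied to variable-J mesophyll conductance
#' estimates.
#'
#' Defaults follow common C3 practice at a 25 degC calibration:
#' `gamma_star` = 40 umol mol-1 and `Rd` = 1 umol m-2 s-1 (typical values
#' for rice leaves), `alpha_beta` = 0.44, `Kc` = 404.9 umol mol-1,
#' `Ko` = 278.4 mmol mol-1, `Oi` = 210 mmol mol-1.  No leaf-temperature
#' adjustment is applied; all derivations use these constants as-is.
#'
#' @param gamma_star CO2 compensation point without respiration
#'   (umol mol-1).
#' @param Rd Daytime (mitochondrial) respiration rate (umol m-2 s-1).
#' @param alpha_beta Product of leaf absorptance and the fraction of
#'   absorbed quanta reaching PSII (dimensionless).
#' @param Kc Michaelis constant for carboxylation (umol mol-1).
#' @param Ko Michaelis constant for oxygenation (mmol mol-1).
#' @param Oi Intercellular O2 mole fraction (mmol mol-1).
#' @param qc_low,qc_high Acceptance bounds on dCc/dA for the variable-J
#'   quality criterion (dimensionless); a record passes when
#'   `qc_low <= dCc/dA <= qc_high`.
#'
#' @return An object of class `kinetic_constants` (a named list).
#' @examples
#' kc <- kinetic_constants()
#' compute_km(kc)
#' @export
kinetic_constants <- function(gamma_star = 40, Rd = 1, alpha_beta = 0.44,
                              Kc = 404.9, Ko = 278.4, Oi = 210,
                              qc_low = 10, qc_high = 50) {
  vals <- list(gamma_star = gamma_star, Rd = Rd, alpha_beta = alpha_beta,
               Kc = Kc, Ko = Ko, Oi = Oi,
               qc_low = qc_low, qc_high = qc_high)
  num <- vapply(vals, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("kinetic constants must be finite numeric scalars; offending: ",
                 paste(names(vals)[!num], collapse = ", ")))
  }
  pos <- c("gamma_star", "Rd", "alpha_beta", "Kc", "Ko", "Oi")
  bad <- pos[vapply(pos, function(nm) vals[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("kinetic constants must be strictly positive; offending: ",
                 paste(bad, collapse = ", ")))
  }
  if (vals$qc_low >= vals$qc_high) {
    abort("qc_low must be smaller than qc_high")
  }
  structure(vals, class = "kinetic_constants")
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("<kinetic_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-10s %g  (derived: Kc * (1 + Oi/Ko))\n", "Km", compute_km(x)))
  invisible(x)
}

#' Apparent Michaelis constant for carboxylation
#'
#' Computes the O2-adjusted (apparent) Michaelis constant
#' `Km = Kc * (1 + Oi / Ko)` used by the one-point Vcmax estimator.
#' `Kc` is in umol mol-1 while `Oi` and `Ko` share mmol mol-1, so the
#' ratio is dimensionless and `Km` is in umol mol-1.
#'
#' @param constants A [kinetic_constants()] object.
#' @return Apparent Michaelis constant (umol mol-1); always `>= Kc`.
#' @examples
#' compute_km(kinetic_constants())  # ~ 710.3 umol mol-1
#' @export
compute_km <- function(constants = kinetic_constants()) {
  stopifnot(inherits(constants, "kinetic_constants"))
  constants$Kc * (1 + constants$Oi / constants$Ko)
}
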