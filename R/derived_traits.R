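#' Electron transport rate from fluorescence
#'
#' `J = phi_psii * ppfd * alpha_beta`: linear electron transport estimated
#' from the PSII operating efficiency measured by chlorophyll fluorescence
#' at a known incident photon flux, with `alpha_beta` the product of leaf
#' absorptance and the PSII partitioning fraction.
#'
#' @param phi_psii PSII operating efficiency, in \[0, 1\] (vectorised).
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1), `>= 0`.
#' @param constants A [kinetic_constants()] object (supplies `alpha_beta`).
#' @return Electron transport rate J (umol m-2 s-1).
#' @examples
#' compute_j(0.3, 1500)  # 198
#' @export
compute_j <- function(phi_psii, ppfd, constants = kinetic_constants()) {
  stopifnot(inherits(constants, "kinetic_constants"))
  ok_phi <- is.na(phi_psii) | (phi_psii >= 0 & phi_psii <= 1)
  ok_q <- is.na(ppfd) | ppfd >= 0
  if (!all(ok_phi)) abort("phi_psii must lie in [0, 1]")
  if (!all(ok_q)) abort("ppfd must be non-negative")
  phi_psii * ppfd * constants$alpha_beta
}

#' Mesophyll conductance by the variable-J method
#'
#' Estimates mesophyll conductance from a single light-saturated
#' measurement by combining gas exchange (A, Ci) with fluorescence-derived
#' electron transport J:
#' \deqn{g_m = A / (C_i - \Gamma^* (J + 8(A + R_d)) / (J - 4(A + R_d)))}
#' The second term is the chloroplast CO2 mole fraction implied by the
#' RuBP-regeneration-limited demand, so `Cc = Ci - A/gm` whenever `gm` is
#' finite and positive.
#'
#' Singular or unphysical cases never raise: they yield `NA` with a QC
#' reason code per element — `"J_limit_singular"` when
#' `J <= 4 (A + Rd)`, `"nonpositive_denominator"` when the implied
#' `Cc >= Ci`, and `"nonpositive_gm"` when the estimate is not strictly
#' positive (e.g. `A = 0`).
#'
#' @param A Net assimilation (umol m-2 s-1), vectorised.
#' @param ci Intercellular CO2 mole fraction (umol mol-1).
#' @param J Electron transport rate (umol m-2 s-1), e.g. [compute_j()].
#' @param constants A [kinetic_constants()] object (`gamma_star`, `Rd`).
#' @return A tibble with columns `gm` (mol m-2 s-1), `cc` (umol mol-1)
#'   and `qc_reason` (`""` when clean).
#' @examples
#' compute_gm(A = 20, ci = 280, J = 198)  # gm ~ 0.132, cc ~ 128.4
#' @export
compute_gm <- function(A, ci, J, constants = kinetic_constants()) {
  stopifnot(inherits(constants, "kinetic_constants"))
  n <- max(length(A), length(ci), length(J))
  A <- rep_len(A, n); ci <- rep_len(ci, n); J <- rep_len(J, n)
  gs <- constants$gamma_star
  x <- A + constants$Rd
  vlim <- J - 4 * x

  gm <- rep(NA_real_, n); cc <- rep(NA_real_, n); reason <- character(n)

  singular <- is.na(vlim) | vlim <= 0
  reason[singular & !is.na(vlim)] <- "J_limit_singular"

  cc_dem <- ifelse(singular, NA_real_, gs * (J + 8 * x) / vlim)
  denom <- ci - cc_dem
  bad_den <- !singular & !is.na(denom) & denom <= 0
  reason[bad_den] <- "nonpositive_denominator"

  ok <- !singular & !bad_den & !is.na(denom)
  gm[ok] <- A[ok] / denom[ok]
  cc[ok] <- cc_dem[ok]
  nonpos <- ok & gm <= 0
  reason[nonpos] <- "nonpositive_gm"

  tibble(gm = gm, cc = cc, qc_reason = reason)
}

#' Sensitivity of chloroplast CO2 to assimilation, dCc/dA
#'
#' Closed-form derivative of the variable-J chloroplast CO2
#' `Cc(A) = Gamma* (J + 8(A+Rd)) / (J - 4(A+Rd))` with respect to A:
#' \deqn{dC_c/dA = 12 J \Gamma^* / (J - 4(A + R_d))^2}
#' Used as the quality criterion for variable-J mesophyll conductance:
#' estimates are reliable only in an intermediate sensitivity window
#' (default 10–50; see [apply_qc()]).  Strictly positive on the
#' admissible domain and `-> 12 Gamma*/J -> 0` as J grows large.
#'
#' @inheritParams compute_gm
#' @return A tibble with columns `dccda` and `qc_reason`
#'   (`"J_limit_singular"` where `J <= 4 (A + Rd)`).
#' @examples
#' compute_dccda(A = 20, J = 198)  # ~ 7.313
#' @export
compute_dccda <- function(A, J, constants = kinetic_constants()) {
  stopifnot(inherits(constants, "kinetic_constants"))
  n <- max(length(A), length(J))
  A <- rep_len(A, n); J <- rep_len(J, n)
  vlim <- J - 4 * (A + constants$Rd)
  singular <- is.na(vlim) | vlim <= 0
  d <- ifelse(singular, NA_real_, 12 * J * constants$gamma_star / vlim^2)
  tibble(dccda = d,
         qc_reason = ifelse(!is.na(vlim) & vlim <= 0, "J_limit_singular", ""))
}

#' Quality criterion for variable-J estimates
#'
#' A record passes when `qc_low <= dCc/dA <= qc_high` and the mesophyll
#' conductance is defined and strictly positive.  Every failure carries a
#' reason code (`"dCcdA_out_of_range"`, `"nonpositive_gm"`); `qc_pass` is
#' true exactly when `qc_reasons` is empty.
#'
#' @param dccda dCc/dA values, e.g. from [compute_dccda()].
#' @param gm Mesophyll conductance values (may be `NA`).
#' @param constants A [kinetic_constants()] object (`qc_low`, `qc_high`).
#' @return A tibble with `qc_pass` (logical) and `qc_reasons`
#'   (semicolon-joined codes, `""` when passing).
#' @export
apply_qc <- function(dccda, gm, constants = kinetic_constants()) {
  stopifnot(inherits(constants, "kinetic_constants"))
  n <- max(length(dccda), length(gm))
  dccda <- rep_len(dccda, n); gm <- rep_len(gm, n)
  reasons <- vector("list", n)
  bad_gm <- is.na(gm) | gm <= 0
  bad_d <- is.na(dccda) | dccda < constants$qc_low | dccda > constants$qc_high
  out <- purrr::map2_chr(bad_d, bad_gm, function(d, g) {
    paste(c(if (d) "dCcdA_out_of_range", if (g) "nonpositive_gm"),
          collapse = ";")
  })
  tibble(qc_pass = out == "", qc_reasons = out)
}

#' One-point Vcmax from a light-saturated measurement
#'
#' Estimates the maximum Rubisco carboxylation rate from a single
#' light-saturated gas-exchange record, assuming the leaf is
#' Rubisco-limited and that daytime respiration is 1.5% of Vcmax.
#' Two algebraic forms are provided:
#' * `"printed"` (default): `Vcmax = A * ((Ci + Km)/(Ci - Gamma*) - 0.015)`,
#'   the form in common field use.
#' * `"inverted"`: `Vcmax = A / ((Ci - Gamma*)/(Ci + Km) - 0.015)`, the
#'   exact inversion of the Rubisco-limited FvCB demand equation under
#'   `Rd = 0.015 Vcmax`; this form recovers the true Vcmax exactly on
#'   consistent data.
#'
#' The two differ by the factor `(1 - 0.015 f)(1 - 0.015/f)` with
#' `f = (Ci - Gamma*)/(Ci + Km)` — a few percent at typical Ci.  See the
#' package vignette for discussion.
#'
#' @param A Net assimilation (umol m-2 s-1), vectorised.
#' @param ci Intercellular (or, for infinite mesophyll conductance,
#'   chloroplast) CO2 mole fraction (umol mol-1).
#' @param constants A [kinetic_constants()] object.
#' @param form `"printed"` or `"inverted"` (see Details).
#' @return A tibble with `vcmax` and `qc_reason`
#'   (`"Ci_below_gamma_star"` where `ci <= gamma_star`;
#'   `"unidentifiable"` if the inverted-form denominator is not positive).
#' @examples
#' compute_vcmax_one_point(A = 20, ci = 280)  # ~ 82.22
#' @export
compute_vcmax_one_point <- function(A, ci, constants = kinetic_constants(),
                                    form = c("printed", "inverted")) {
  stopifnot(inherits(constants, "kinetic_constants"))
  form <- match.arg(form)
  n <- max(length(A), length(ci))
  A <- rep_len(A, n); ci <- rep_len(ci, n)
  km <- compute_km(constants)
  gs <- constants$gamma_star
  vc <- rep(NA_real_, n); reason <- character(n)
  bad <- !is.na(ci) & ci <= gs
  reason[bad] <- "Ci_below_gamma_star"
  ok <- !bad & !is.na(ci) & !is.na(A)
  if (form == "printed") {
    vc[ok] <- A[ok] * ((ci[ok] + km) / (ci[ok] - gs) - 0.015)
  } else {
    f <- (ci[ok] - gs) / (ci[ok] + km) - 0.015
    good <- f > 0
    vc[ok][good] <- A[ok][good] / f[good]
    reason[ok][!good] <- "unidentifiable"
  }
  tibble(vcmax = vc, qc_reason = reason)
}

#' Intrinsic water-use efficiency
#'
#' `iWUE = A / gsw` (umol CO2 per mol H2O): the ratio of net assimilation
#' to stomatal conductance to water vapour.
#'
#' @param A Net assimilation (umol m-2 s-1).
#' @param gsw Stomatal conductance to water vapour (mol m-2 s-1); must be
#'   strictly positive.
#' @return iWUE (umol mol-1).
#' @examples
#' compute_iwue(21.03, 0.69)  # ~ 30.5
#' @export
compute_iwue <- function(A, gsw) {
  if (any(!is.na(gsw) & gsw <= 0)) abort("gsw must be positive")
  A / gsw
}

#' Derive all per-record photosynthetic traits
#'
#' Runs the full per-record derivation over a table of gas-exchange
#' records: electron transport `J` from fluorescence, variable-J
#' mesophyll conductance `gm` with chloroplast CO2 `cc`, the dCc/dA
#' quality criterion, apparent Michaelis constant `km`, one-point
#' `vcmax`, intrinsic water-use efficiency `iwue`, and stomatal
#' conductance on the CO2 basis `gsc = gsw / 1.6`.  Singular or
#' out-of-window records are retained with `qc_pass = FALSE` and reason
#' codes — one bad record never aborts a batch — and QC-failed rows are
#' excluded from downstream summaries by default (see
#' [summarize_traits()]).
#'
#' @param records A tibble of gas-exchange records in the canonical
#'   schema (see [gasex_schema]); extra columns are carried through.
#' @param constants A [kinetic_constants()] object.
#' @param vcmax_form Passed to [compute_vcmax_one_point()].
#' @return The input tibble augmented with columns `J`, `gm`, `cc`, `km`,
#'   `vcmax`, `iwue`, `gsc`, `dccda`, `qc_pass`, `qc_reasons`.
#' @export
derive_traits <- function(records, constants = kinetic_constants(),
                          vcmax_form = c("printed", "inverted")) {
  vcmax_form <- match.arg(vcmax_form)
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    out <- records
    for (col in c("J", "gm", "cc", "km", "vcmax", "iwue", "gsc", "dccda"))
      out[[col]] <- numeric(0)
    out$qc_pass <- logical(0); out$qc_reasons <- character(0)
    return(out)
  }
  need <- c("A", "gsw", "ci", "ppfd", "phi_psii")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("records lack required column(s): ",
                 paste(missing, collapse = ", ")))
  }

  J <- compute_j(records$phi_psii, records$ppfd, constants)
  gmres <- compute_gm(records$A, records$ci, J, constants)
  dres <- compute_dccda(records$A, J, constants)
  vres <- compute_vcmax_one_point(records$A, records$ci, constants,
                                  form = vcmax_form)
  qc <- apply_qc(dres$dccda, gmres$gm, constants)
  extra <- ifelse(vres$qc_reason == "", "",
                  vres$qc_reason)
  qc_reasons <- ifelse(extra == "", qc$qc_reasons,
                       ifelse(qc$qc_reasons == "", extra,
                              paste(qc$qc_reasons, extra, sep = ";")))
  iwue <- rep(NA_real_, nrow(records))
  pos <- !is.na(records$gsw) & records$gsw > 0
  iwue[pos] <- records$A[pos] / records$gsw[pos]

  out <- records
  out$J <- J
  out$gm <- gmres$gm
  out$cc <- gmres$cc
  out$km <- compute_km(constants)
  out$vcmax <- vres$vcmax
  out$iwue <- iwue
  out$gsc <- ifelse(pos, records$gsw / 1.6, NA_real_)
  out$dccda <- dres$dccda
  out$qc_pass <- qc_reasons == ""
  out$qc_reasons <- qc_reasons
  out
}

#' Detect the first steady-state point in an assimilation time series
#'
#' Scans a time-ordered series of (t, A) and returns the index of the
#' earliest point whose trailing window of `window` seconds shows only
#' relative changes below `rel_tol` — the acquisition rule "record once A
#' changes by less than 0.5% over one minute".  A point qualifies when a
#' full window lies behind it and `|A(t) - A(s)| / |A(t)| < rel_tol` for
#' every sample `s` within `[t - window, t]`.
#'
#' @param series A data frame with numeric columns `t` (seconds, strictly
#'   increasing) and `A`.
#' @param window Trailing window length in seconds (default 60).
#' @param rel_tol Relative tolerance (default 0.005, i.e. 0.5%).
#' @return Integer index into `series` of the first steady point, or
#'   `NA_integer_` if none qualifies.
#' @export
detect_steady_state <- function(series, window = 60, rel_tol = 0.005) {
  series <- as_tibble(series)
  stopifnot(all(c("t", "A") %in% names(series)))
  t <- series$t; A <- series$A
  if (any(diff(t) <= 0)) abort("t must be strictly increasing")
  n <- length(t)
  for (i in seq_len(n)) {
    if (t[i] - t[1] < window) next
    in_win <- t >= t[i] - window & t <= t[i]
    if (abs(A[i]) == 0) next
    if (max(abs(A[i] - A[in_win])) / abs(A[i]) < rel_tol) return(i)
  }
  NA_integer_
}
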