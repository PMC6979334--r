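#' True leaf parameters for the coupled FvCB simulator
#'
#' Bundles the "truth" driving the synthetic-leaf forward model: maximum
#' carboxylation rate `vcmax`, electron transport `j` (the point value
#' used at the measurement light level), mesophyll conductance `gm`,
#' stomatal conductance to water vapour `gsw`, daytime respiration `rd`,
#' and — for light-response simulation — a nonrectangular hyperbola for
#' J(PPFD) with its own `jmax`, `phi_j` (initial slope, electrons per
#' incident photon) and `theta_j`.  Measurement noise is additive
#' Gaussian on A, gsw and PhiPSII only; noise on Ci arises implicitly
#' because the record's Ci is back-computed from the noisy A and gsw.
#'
#' Defaults portray a healthy rice flag leaf at saturating light:
#' `vcmax` 108, `j` 198, `gm` 0.21, `gsw` 0.69, `rd` 1 (all in the
#' units of [gasex_schema]), `jmax` 190, `phi_j` 0.36, `theta_j` 0.9.
#' `gm` and `gsw` may be `Inf` to remove a diffusion resistance.
#'
#' @param vcmax,j,gm,gsw,rd Leaf parameters (see Description).
#' @param jmax,phi_j,theta_j Light dependence of J (used when a PPFD is
#'   supplied to the solver or when simulating light curves).
#' @param constants A [kinetic_constants()] object.
#' @param noise_sd_a,noise_sd_gsw,noise_sd_phi Gaussian measurement noise
#'   SDs (0 = deterministic).
#' @return An object of class `sim_leaf_params`.
#' @export
sim_leaf_params <- function(vcmax = 108, j = 198, gm = 0.21, gsw = 0.69,
                            rd = 1, jmax = 190, phi_j = 0.36, theta_j = 0.9,
                            constants = kinetic_constants(),
                            noise_sd_a = 0, noise_sd_gsw = 0,
                            noise_sd_phi = 0) {
  stopifnot(inherits(constants, "kinetic_constants"))
  if (vcmax < 0 || j < 0 || rd < 0) abort("rates must be non-negative")
  if (gm <= 0 || gsw <= 0) abort("conductances must be strictly positive")
  if (noise_sd_a < 0 || noise_sd_gsw < 0 || noise_sd_phi < 0) {
    abort("noise SDs must be non-negative")
  }
  structure(list(vcmax = vcmax, j = j, gm = gm, gsw = gsw, rd = rd,
                 jmax = jmax, phi_j = phi_j, theta_j = theta_j,
                 constants = constants,
                 noise_sd_a = noise_sd_a, noise_sd_gsw = noise_sd_gsw,
                 noise_sd_phi = noise_sd_phi),
            class = "sim_leaf_params")
}

## nonrectangular hyperbola for J(PPFD) used by the light-curve simulator
.nrh_j <- function(ppfd, phi_j, jmax, theta_j) {
  u <- phi_j * ppfd
  s <- u + jmax
  (s - sqrt(pmax(s^2 - 4 * theta_j * u * jmax, 0))) / (2 * theta_j)
}

## FvCB demand: gross = min(Rubisco-, RuBP-regeneration-limited), net = gross - rd
.fvcb_demand <- function(cc, vcmax, j, rd, gamma_star, km) {
  wc <- vcmax * (cc - gamma_star) / (cc + km)
  wj <- j * (cc - gamma_star) / (4 * cc + 8 * gamma_star)
  pmin(wc, wj) - rd
}

.limitation_at <- function(cc, vcmax, j, gamma_star, km) {
  wc <- vcmax * (cc - gamma_star) / (cc + km)
  wj <- j * (cc - gamma_star) / (4 * cc + 8 * gamma_star)
  if (wj < wc) "RuBP" else "rubisco"
}

#' Solve the coupled FvCB / diffusion leaf model
#'
#' Finds the steady state of the coupled system: biochemical demand
#' `A = min(Wc, Wj) - Rd` with
#' `Wc = Vcmax (Cc - Gamma*)/(Cc + Km)` and
#' `Wj = J (Cc - Gamma*)/(4 Cc + 8 Gamma*)`, against the two diffusion
#' supply equations `A = gsc (Ca - Ci) = gm (Ci - Cc)` with
#' `gsc = gsw / 1.6`.  The default solver brackets the root in Cc on
#' `(Gamma*, Ca]`; `method = "fixed_point"` is an independent damped
#' fixed-point iteration on `Cc <- Ca - A(Cc)/g_tot` used as a
#' cross-check.  When no assimilatory solution exists in the bracket
#' (e.g. `Vcmax = J = 0`) the dark state `A = -Rd` is returned with
#' consistent diffusion fluxes and the flag `"no_solution"`.
#'
#' @param params A [sim_leaf_params()] object.
#' @param ca Ambient CO2 mole fraction (umol mol-1), `> Gamma*`.
#' @param ppfd Optional PPFD; if supplied, J is taken from the leaf's
#'   J(PPFD) hyperbola instead of `params$j`.
#' @param method `"bisection"` (bracketed root) or `"fixed_point"`.
#' @return One-row tibble: `A`, `ci`, `cc`, `j`, `limitation`
#'   (`"rubisco"`, `"RuBP"` or `"none"`), `flag`.
#' @examples
#' solve_coupled(sim_leaf_params())
#' @export
solve_coupled <- function(params, ca = 400, ppfd = NULL,
                          method = c("bisection", "fixed_point")) {
  stopifnot(inherits(params, "sim_leaf_params"))
  method <- match.arg(method)
  kc <- params$constants
  gs <- kc$gamma_star
  if (ca <= gs) abort("ca must exceed gamma_star")
  km <- compute_km(kc)
  j <- if (is.null(ppfd)) params$j else .nrh_j(ppfd, params$phi_j,
                                               params$jmax, params$theta_j)
  gsc <- params$gsw / 1.6
  gtot <- 1 / (1 / gsc + 1 / params$gm)  # Inf if both conductances Inf

  demand <- function(cc) .fvcb_demand(cc, params$vcmax, j, params$rd, gs, km)

  done <- function(a, ci, cc, flag) {
    tibble(A = a, ci = ci, cc = cc, j = j,
           limitation = if (flag == "no_solution") "none"
                        else .limitation_at(cc, params$vcmax, j, gs, km),
           flag = flag)
  }

  if (!is.finite(gtot)) {  # no diffusion resistance: Ci = Cc = Ca
    return(done(demand(ca), ca, ca, ""))
  }

  lo <- gs * (1 + 1e-9)
  h <- function(cc) demand(cc) - gtot * (ca - cc)
  if (h(ca) <= 0) {  # no assimilatory solution: dark state
    a <- -params$rd
    ci <- ca - a / gsc
    cc <- ci - a / params$gm
    return(done(a, ci, cc, "no_solution"))
  }

  if (method == "bisection") {
    cc <- uniroot(h, c(lo, ca), tol = 1e-12)$root
  } else {
    ## damped fixed point on cc <- ca - demand(cc)/gtot; damping chosen
    ## from the local demand slope so the map contracts
    cc <- (lo + ca) / 2
    eps <- 1e-4
    dprime <- (demand(cc + eps) - demand(cc - eps)) / (2 * eps)
    lambda <- gtot / (gtot + max(dprime, 0))
    for (it in 1:50000) {
      target <- ca - demand(cc) / gtot
      cc_new <- (1 - lambda) * cc + lambda * target
      cc_new <- min(max(cc_new, lo), ca)
      if (abs(cc_new - cc) < 1e-13 * max(1, cc)) { cc <- cc_new; break }
      cc <- cc_new
    }
  }
  a <- demand(cc)
  ci <- ca - a / gsc
  done(a, ci, ci - a / params$gm, "")
}

#' Simulate one steady-state gas-exchange record
#'
#' Solves the coupled leaf model at the cuvette conditions and emits a
#' record in the canonical schema, with
#' `phi_psii = J / (PPFD * alpha_beta)` (the inverse of [compute_j()])
#' and optional seeded Gaussian noise on A, gsw and PhiPSII.  With all
#' noise SDs zero the record is exactly the deterministic solution.
#' Default cuvette setpoints: Ca 400 umol mol-1, PPFD 1500, RH 65%,
#' leaf temperature 28 degC.
#'
#' @param params A [sim_leaf_params()] object.
#' @param ca,ppfd,rh,tleaf Cuvette conditions.
#' @param record_id,line_id Identifiers for the emitted record.
#' @param seed Integer seed; mandatory when any noise SD is positive.
#' @return A one-row tibble in the canonical record schema plus
#'   `qc_flag` (`"phi_psii_gt_1"` if the back-computed efficiency is
#'   unphysical).
#' @export
simulate_record <- function(params, ca = 400, ppfd = 1500, rh = 65,
                            tleaf = 28, record_id = "r1", line_id = NA_character_,
                            seed = NULL) {
  stopifnot(inherits(params, "sim_leaf_params"))
  noisy <- params$noise_sd_a > 0 || params$noise_sd_gsw > 0 ||
    params$noise_sd_phi > 0
  if (noisy && is.null(seed)) abort("seed is required for noisy simulation")
  if (!is.null(seed)) withr::local_seed(seed)

  st <- solve_coupled(params, ca = ca)
  ab <- params$constants$alpha_beta
  phi <- if (ppfd > 0) params$j / (ppfd * ab) else NA_real_

  a_obs <- st$A + if (params$noise_sd_a > 0) rnorm(1, 0, params$noise_sd_a) else 0
  gsw_obs <- params$gsw +
    if (params$noise_sd_gsw > 0) rnorm(1, 0, params$noise_sd_gsw) else 0
  gsw_obs <- max(gsw_obs, 1e-4)
  phi_obs <- phi +
    if (params$noise_sd_phi > 0) rnorm(1, 0, params$noise_sd_phi) else 0
  phi_obs <- max(phi_obs, 0)
  flag <- if (!is.na(phi_obs) && phi_obs > 1) "phi_psii_gt_1" else ""
  ci_obs <- if (noisy) ca - a_obs / (gsw_obs / 1.6) else st$ci

  tibble(record_id = record_id, line_id = line_id,
         A = a_obs, gsw = gsw_obs, ci = ci_obs, ca = ca, ppfd = ppfd,
         phi_psii = min(phi_obs, 1), tleaf = tleaf, rh = rh,
         spad = NA_real_, timestamp = NA_character_, qc_flag = flag)
}

#' Simulate a light-response (AQ) curve
#'
#' Evaluates the coupled leaf model along a PPFD ladder, with electron
#' transport following the leaf's own J(PPFD) nonrectangular hyperbola
#' (`phi_j`, `jmax`, `theta_j`), plus optional Gaussian noise on A.
#' Noise-free curves are monotone non-decreasing in PPFD and start at
#' `A(0) = -rd`.
#'
#' @param params A [sim_leaf_params()] object.
#' @param ppfd_steps PPFD ladder (>= 4 values).
#' @param ca Ambient CO2.
#' @param curve_id,line_id Identifiers.
#' @param noise_sd Gaussian noise SD on A (0 = deterministic).
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return A tibble with columns `curve_id`, `line_id`, `ppfd`, `A`.
#' @export
simulate_light_curve <- function(params,
                                 ppfd_steps = c(0, 50, 100, 200, 400, 700,
                                                1000, 1500, 2000),
                                 ca = 400, curve_id = "c1",
                                 line_id = NA_character_,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "sim_leaf_params"))
  if (length(ppfd_steps) < 4) abort("at least 4 PPFD steps are required")
  if (noise_sd > 0 && is.null(seed)) abort("seed is required for noisy simulation")
  if (!is.null(seed)) withr::local_seed(seed)
  a <- vapply(ppfd_steps, function(q) solve_coupled(params, ca = ca,
                                                    ppfd = q)$A, numeric(1))
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  tibble(curve_id = curve_id, line_id = line_id,
         ppfd = as.numeric(ppfd_steps), A = a)
}

#' Simulate the approach of A to steady state
#'
#' Exponential relaxation of net assimilation towards the solved steady
#' state with time constant `tau` (seconds), emulating the settling of a
#' leaf after enclosure; feeds [detect_steady_state()].
#'
#' @param params A [sim_leaf_params()] object.
#' @param duration Total duration (s).
#' @param step Sampling interval (s).
#' @param tau Relaxation time constant (s), `> 0`.
#' @param ca,ppfd Cuvette conditions.
#' @param a0 Initial assimilation at t = 0.
#' @param noise_sd Optional Gaussian noise SD on A.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return A tibble with columns `t`, `A`.
#' @export
simulate_steady_approach <- function(params, duration = 300, step = 5,
                                     tau = 30, ca = 400, ppfd = 1500,
                                     a0 = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "sim_leaf_params"))
  if (tau <= 0) abort("tau must be positive")
  if (noise_sd > 0 && is.null(seed)) abort("seed is required for noisy simulation")
  if (!is.null(seed)) withr::local_seed(seed)
  a_ss <- solve_coupled(params, ca = ca)$A
  t <- seq(0, duration, by = step)
  a <- a_ss + (a0 - a_ss) * exp(-t / tau)
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  tibble(t = t, A = a)
}
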