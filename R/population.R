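#' Specification of a synthetic mapping population
#'
#' Describes the between-line distribution of true leaf parameters for an
#' F2-like population.  Marginals follow the shapes documented for such
#' populations — approximately normal maximum carboxylation rate and
#' electron transport, right-skewed (lognormal) stomatal and mesophyll
#' conductances — linked through a Gaussian copula with a configurable
#' latent correlation matrix (order: vcmax, j, gm, gsw, spad).
#'
#' Default anchors place the population at the documented centres:
#' vcmax ~ N(107.8, 26), gm lognormal with mean 0.21 (sdlog 0.45), gsw
#' lognormal with mean 0.69 (sdlog 0.5), SPAD ~ N(42, 3.5), rd fixed at
#' 1.  The electron-transport mean (J at the 1500 umol m-2 s-1
#' measurement light) is set so the coupled model's realized mean net
#' assimilation sits near 21 umol m-2 s-1 at the default cuvette
#' conditions; see the package vignette for the calibration rationale.
#' Measurement noise defaults: SD 0.5 on A, 0.03 on gsw, 0.005 on
#' PhiPSII (assumed values; no instrument noise magnitudes are published
#' for this protocol).
#'
#' @param n_lines Number of lines (>= 1).
#' @param vcmax_mean,vcmax_sd Normal marginal for vcmax (umol m-2 s-1).
#' @param j_mean,j_sd Normal marginal for J at measurement light.
#' @param gm_mean,gm_sdlog Lognormal marginal for gm (mol m-2 s-1);
#'   `gm_mean` is the arithmetic mean.
#' @param gsw_mean,gsw_sdlog Lognormal marginal for gsw (mol m-2 s-1).
#' @param spad_mean,spad_sd Normal marginal for the SPAD index.
#' @param rd Daytime respiration, identical across lines.
#' @param correlation 5x5 latent correlation matrix (must be positive
#'   semi-definite); rows/cols ordered vcmax, j, gm, gsw, spad.
#' @param noise_sd_a,noise_sd_gsw,noise_sd_phi Measurement noise SDs.
#' @param seed Default seed used by [generate_population()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_lines = 568,
                            vcmax_mean = 107.8, vcmax_sd = 26,
                            j_mean = 160, j_sd = 22,
                            gm_mean = 0.21, gm_sdlog = 0.45,
                            gsw_mean = 0.69, gsw_sdlog = 0.5,
                            spad_mean = 42, spad_sd = 3.5,
                            rd = 1,
                            correlation = default_population_correlation(),
                            noise_sd_a = 0.5, noise_sd_gsw = 0.03,
                            noise_sd_phi = 0.005,
                            seed = NULL) {
  if (n_lines < 1) abort("n_lines must be at least 1")
  correlation <- as.matrix(correlation)
  if (!identical(dim(correlation), c(5L, 5L)) ||
      !isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12)) {
    abort("correlation must be a symmetric 5x5 matrix with unit diagonal")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    abort("correlation matrix is not positive semi-definite")
  }
  structure(list(n_lines = as.integer(n_lines),
                 vcmax_mean = vcmax_mean, vcmax_sd = vcmax_sd,
                 j_mean = j_mean, j_sd = j_sd,
                 gm_mean = gm_mean, gm_sdlog = gm_sdlog,
                 gsw_mean = gsw_mean, gsw_sdlog = gsw_sdlog,
                 spad_mean = spad_mean, spad_sd = spad_sd,
                 rd = rd, correlation = correlation,
                 noise_sd_a = noise_sd_a, noise_sd_gsw = noise_sd_gsw,
                 noise_sd_phi = noise_sd_phi, seed = seed),
            class = "population_spec")
}

#' @rdname population_spec
#' @export
default_population_correlation <- function() {
  nm <- c("vcmax", "j", "gm", "gsw", "spad")
  r <- diag(5)
  dimnames(r) <- list(nm, nm)
  set <- function(r, a, b, v) { r[a, b] <- v; r[b, a] <- v; r }
  r <- set(r, "vcmax", "j", 0.6)
  r <- set(r, "vcmax", "gm", 0.4)
  r <- set(r, "vcmax", "gsw", 0.3)
  r <- set(r, "vcmax", "spad", 0.5)
  r <- set(r, "j", "gm", 0.4)
  r <- set(r, "j", "gsw", 0.3)
  r <- set(r, "j", "spad", 0.3)
  r <- set(r, "gm", "gsw", 0.4)
  r <- set(r, "gm", "spad", 0.2)
  r <- set(r, "gsw", "spad", 0.1)
  r
}

## eigen square root (handles PSD-but-singular correlation matrices)
.corr_sqrt <- function(r) {
  e <- eigen(r, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

#' Generate a synthetic gas-exchange population
#'
#' Draws per-line true leaf parameters from a [population_spec()],
#' solves the coupled FvCB/diffusion model for each line at the point
#' measurement conditions, and emits one gas-exchange record per line
#' (with seeded measurement noise) together with a truth table of the
#' underlying parameters and noise-free state — the ground truth against
#' which trait recovery is checked.  Fully reproducible from the seed;
#' global random state is untouched.
#'
#' @param spec A [population_spec()].
#' @param constants A [kinetic_constants()] object.
#' @param ca,ppfd,rh,tleaf Point-measurement protocol settings.
#' @param seed Integer seed; defaults to `spec$seed` and is mandatory.
#' @return A list with elements `records` (tibble, canonical schema, one
#'   row per line) and `truth` (tibble of per-line true parameters and
#'   noise-free A/Ci/Cc/limitation).
#' @export
generate_population <- function(spec = population_spec(),
                                constants = kinetic_constants(),
                                ca = 400, ppfd = 1500, rh = 65, tleaf = 28,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(seed)) abort("a seed is required to generate a population")
  withr::local_seed(seed)

  n <- spec$n_lines
  z <- matrix(rnorm(n * 5), n, 5) %*% .corr_sqrt(spec$correlation)
  vcmax <- pmax(spec$vcmax_mean + spec$vcmax_sd * z[, 1], 10)
  j <- pmax(spec$j_mean + spec$j_sd * z[, 2], 25)
  gm <- exp(log(spec$gm_mean) - spec$gm_sdlog^2 / 2 + spec$gm_sdlog * z[, 3])
  gsw <- exp(log(spec$gsw_mean) - spec$gsw_sdlog^2 / 2 + spec$gsw_sdlog * z[, 4])
  spad <- spec$spad_mean + spec$spad_sd * z[, 5]

  noise_a <- if (spec$noise_sd_a > 0) rnorm(n, 0, spec$noise_sd_a) else numeric(n)
  noise_g <- if (spec$noise_sd_gsw > 0) rnorm(n, 0, spec$noise_sd_gsw) else numeric(n)
  noise_p <- if (spec$noise_sd_phi > 0) rnorm(n, 0, spec$noise_sd_phi) else numeric(n)
  noisy <- spec$noise_sd_a > 0 || spec$noise_sd_gsw > 0 || spec$noise_sd_phi > 0

  ab <- constants$alpha_beta
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- sim_leaf_params(vcmax = vcmax[i], j = j[i], gm = gm[i],
                            gsw = gsw[i], rd = spec$rd,
                            constants = constants)
    st <- solve_coupled(pars, ca = ca)
    phi <- j[i] / (ppfd * ab)
    a_obs <- st$A + noise_a[i]
    gsw_obs <- max(gsw[i] + noise_g[i], 1e-4)
    phi_obs <- min(max(phi + noise_p[i], 0), 1)
    ci_obs <- if (noisy) ca - a_obs / (gsw_obs / 1.6) else st$ci
    lid <- sprintf("L%03d", i)
    rows[[i]] <- tibble(record_id = lid, line_id = lid,
                        A = a_obs, gsw = gsw_obs, ci = ci_obs, ca = ca,
                        ppfd = ppfd, phi_psii = phi_obs, tleaf = tleaf,
                        rh = rh, spad = spad[i], timestamp = NA_character_,
                        qc_flag = st$flag)
    truth[[i]] <- tibble(line_id = lid, vcmax_true = vcmax[i],
                         j_true = j[i], gm_true = gm[i], gsw_true = gsw[i],
                         rd_true = spec$rd, spad_true = spad[i],
                         a_true = st$A, ci_true = st$ci, cc_true = st$cc,
                         limitation = st$limitation)
  }
  list(records = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
}
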