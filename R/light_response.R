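#' Nonrectangular hyperbola light-response model
#'
#' Net assimilation as a function of incident light Q (PPFD) under the
#' four-parameter nonrectangular hyperbola: apparent quantum yield `phi`
#' (initial slope at Q = 0), maximum gross rate `agmax`, convexity
#' `theta` in (0, 1\], and dark respiration `rn`:
#' \deqn{A(Q) = \frac{\phi Q + A_{gmax} -
#'   \sqrt{(\phi Q + A_{gmax})^2 - 4\theta\,\phi Q\,A_{gmax}}}{2\theta} - R_n}
#'
#' `denominator_mode` selects the denominator of the closing fraction:
#' `"standard2theta"` (default) uses `2 theta`, under which `A(0) = -rn`,
#' `dA/dQ -> phi` as `Q -> 0`, `A -> agmax - rn` as `Q -> Inf`, and
#' `theta = 1` gives the Blackman limit `min(phi Q, agmax) - rn`;
#' `"printed4theta"` evaluates the same expression over `4 theta`
#' (a variant seen in print whose limits are half those above), retained
#' for exact reproduction of published parameterisations.  `theta = 0`
#' is handled by the rectangular-hyperbola limit
#' `phi Q agmax / (phi Q + agmax) - rn`, not by division by zero.
#'
#' @param ppfd Incident PPFD (umol m-2 s-1), vectorised, `>= 0`.
#' @param phi Apparent quantum yield (mol mol-1), `> 0`.
#' @param agmax Maximum gross photosynthetic rate (umol m-2 s-1), `> 0`.
#' @param theta Convexity factor in \[0, 1\].
#' @param rn Dark respiration (umol m-2 s-1), `>= 0`.
#' @param denominator_mode `"standard2theta"` or `"printed4theta"`.
#' @return Net assimilation A (umol m-2 s-1).
#' @examples
#' nrh_evaluate(c(0, 200, 2000), phi = 0.05, agmax = 30, theta = 0.8, rn = 1)
#' @export
nrh_evaluate <- function(ppfd, phi, agmax, theta, rn,
                         denominator_mode = c("standard2theta", "printed4theta")) {
  denominator_mode <- match.arg(denominator_mode)
  if (any(ppfd < 0, na.rm = TRUE)) abort("ppfd must be non-negative")
  u <- phi * ppfd
  if (theta < 1e-12) {
    gross <- ifelse(u + agmax > 0, u * agmax / (u + agmax), 0)
    if (denominator_mode == "printed4theta") gross <- gross / 2
    return(gross - rn)
  }
  s <- u + agmax
  disc <- pmax(s^2 - 4 * theta * u * agmax, 0)
  den <- if (denominator_mode == "standard2theta") 2 * theta else 4 * theta
  (s - sqrt(disc)) / den - rn
}

## analytic dA/dQ of the standard-2theta model (used for ODR foot points
## and the quantum-yield initialisation); equals phi at Q = 0
.nrh_slope <- function(ppfd, phi, agmax, theta) {
  u <- phi * ppfd
  if (theta < 1e-12) return(phi * agmax^2 / (u + agmax)^2)
  s <- u + agmax
  disc <- pmax(s^2 - 4 * theta * u * agmax, 1e-300)
  phi / (2 * theta) * (1 - (s - 2 * theta * agmax) / sqrt(disc))
}

.nrh_start <- function(q, a) {
  rn0 <- max(-min(a), 0.1)
  agmax0 <- max(a) + rn0
  o <- order(q)
  q2 <- q[o][1:2]; a2 <- a[o][1:2]
  phi0 <- if (diff(q2) > 0) (a2[2] - a2[1]) / (q2[2] - q2[1]) else NA_real_
  if (!is.finite(phi0) || phi0 <= 0) phi0 <- 0.05
  c(phi = min(phi0, 0.2), agmax = agmax0, theta = 0.8, rn = rn0)
}

.nrh_lower <- c(phi = 1e-5, agmax = 1e-3, theta = 1e-6, rn = 0)
.nrh_upper <- c(phi = 1, agmax = 1e4, theta = 1, rn = 100)

## ordinary least squares fit (Levenberg-Marquardt on vertical residuals);
## multi-started over the convexity since box-constrained LM can stall on
## the theta boundary for near-Blackman curves
.nrh_fit_ols <- function(q, a, start, denominator_mode) {
  res_fn <- function(p) {
    nrh_evaluate(q, p[1], p[2], p[3], p[4], denominator_mode) - a
  }
  best <- NULL
  for (theta0 in unique(c(start[["theta"]], 0.3, 0.6, 0.9, 0.99))) {
    st <- start
    st[["theta"]] <- theta0
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = .nrh_lower, upper = .nrh_upper,
                         fn = res_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = setNames(coef(fit), names(start)),
                 rss = sum(res_fn(coef(fit))^2),
                 converged = fit$info %in% 1:4)
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  if (is.null(best)) stop("ols fit failed")
  best
}

## orthogonal (total) least squares: joint Levenberg-Marquardt over the
## four curve parameters and one foot-point abscissa per observation,
## with both axes scaled so PPFD (0-2000) does not dominate A (0-40)
.nrh_fit_onls <- function(q, a, start, denominator_mode) {
  sx <- max(q, 1); sy <- max(abs(a), 1)
  n <- length(q)
  par0 <- c(start, delta = rep(0, n))
  den_fac <- if (denominator_mode == "standard2theta") 2 else 4
  ## raw evaluator: foot points may extrapolate to Q < 0 (clamping them at
  ## zero traps the dark point on a kink and biases the respiration term)
  feval <- function(Q, phi, agmax, theta, rn) {
    u <- phi * Q
    s <- u + agmax
    (s - sqrt(pmax(s^2 - 4 * theta * u * agmax, 0))) / (den_fac * theta) - rn
  }
  res_fn <- function(p) {
    delta <- p[-(1:4)]
    c((feval(q + delta, p[1], p[2], p[3], p[4]) - a) / sy, delta / sx)
  }
  lower <- c(.nrh_lower, rep(-max(q), n))
  upper <- c(.nrh_upper, rep(max(q), n))
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-12, ptol = 1e-12))
  p <- coef(fit)
  list(par = setNames(p[1:4], names(start)),
       delta = unname(p[-(1:4)]),
       rss = sum(res_fn(p)^2),
       converged = fit$info %in% 1:4)
}

#' Fit a nonrectangular hyperbola to a light-response curve
#'
#' Fits the four NRH parameters to an (PPFD, A) curve.  The default
#' method `"onls"` minimises orthogonal (total) least-squares distance —
#' each observation is allowed a foot point along the curve, with the
#' PPFD and A axes scaled by their data ranges so both contribute
#' comparably — via joint Levenberg-Marquardt over the parameters and
#' foot abscissae, warm-started from an ordinary least-squares fit.
#' `"ols"` performs the ordinary (vertical-residual) fit only.
#'
#' Initial values unless supplied: `rn = max(-min(A), 0.1)`,
#' `agmax = max(A) + rn`, `phi` from the slope of the two lowest-PPFD
#' points, `theta = 0.8`.  Curves with fewer than 4 points are returned
#' unfitted and flagged `"insufficient_points"`; curves lacking a
#' near-dark (PPFD < 100) or near-saturating (PPFD >= 1000) point are
#' fitted but flagged `"poor_identifiability"`.  Non-convergence yields a
#' flagged result with the last iterate, never an error.
#'
#' @param curve A data frame with columns `ppfd` and `A` (a single
#'   curve; see [fit_light_curves()] for batches).
#' @param init Optional named numeric vector `c(phi, agmax, theta, rn)`.
#' @param method `"onls"` (orthogonal, default) or `"ols"`.
#' @param denominator_mode Passed to [nrh_evaluate()].
#' @return An object of class `nrh_fit`: parameters, derived `asat`
#'   (fitted maximum net rate), `lcp` (light compensation point) and
#'   `lsp` (PPFD at 75% of `asat`), residual sum of squares (orthogonal,
#'   scaled, for `"onls"`), convergence flag and QC flags.  Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance], `autoplot()`,
#'   `print()`.
#' @examples
#' q <- c(0, 50, 100, 200, 400, 700, 1000, 1500, 2000)
#' a <- nrh_evaluate(q, 0.05, 30, 0.8, 1)
#' fit <- nrh_fit(data.frame(ppfd = q, A = a))
#' glance(fit)
#' @export
nrh_fit <- function(curve, init = NULL, method = c("onls", "ols"),
                    denominator_mode = c("standard2theta", "printed4theta")) {
  method <- match.arg(method)
  denominator_mode <- match.arg(denominator_mode)
  curve <- as_tibble(curve)
  stopifnot(all(c("ppfd", "A") %in% names(curve)))
  curve <- dplyr::arrange(curve, ppfd)
  q <- curve$ppfd; a <- curve$A
  flags <- character(0)

  blank <- function(flags) {
    structure(list(par = c(phi = NA_real_, agmax = NA_real_,
                           theta = NA_real_, rn = NA_real_),
                   asat = NA_real_, lcp = NA_real_, lsp = NA_real_,
                   rss = NA_real_, converged = FALSE, flags = flags,
                   method = method, denominator_mode = denominator_mode,
                   data = curve, fitted = rep(NA_real_, length(q)),
                   n = length(q)),
              class = "nrh_fit")
  }
  if (length(q) < 4) return(blank("insufficient_points"))
  if (min(q) >= 100 || max(q) < 1000) flags <- c(flags, "poor_identifiability")

  start <- init %||% .nrh_start(q, a)
  start <- pmin(pmax(start, .nrh_lower + 1e-8), .nrh_upper - 1e-8)

  ols <- tryCatch(.nrh_fit_ols(q, a, start, denominator_mode),
                  error = function(e) NULL)
  if (method == "ols") {
    res <- ols
  } else {
    warm <- if (!is.null(ols)) ols$par else start
    warm <- pmin(pmax(warm, .nrh_lower + 1e-10), .nrh_upper)
    res <- tryCatch(.nrh_fit_onls(q, a, warm, denominator_mode),
                    error = function(e) NULL)
  }
  if (is.null(res)) return(blank(c(flags, "fit_failed")))
  if (!res$converged) flags <- c(flags, "not_converged")

  p <- res$par
  der <- nrh_derived(p, denominator_mode)
  structure(list(par = p,
                 asat = der$asat, lcp = der$lcp, lsp = der$lsp,
                 rss = res$rss, converged = res$converged, flags = flags,
                 method = method, denominator_mode = denominator_mode,
                 data = curve,
                 fitted = nrh_evaluate(q, p[1], p[2], p[3], p[4],
                                       denominator_mode),
                 n = length(q)),
            class = "nrh_fit")
}

#' Derived light-response quantities: Asat, LCP, LSP
#'
#' From NRH parameters computes the fitted maximum net rate
#' `asat` (the asymptote `agmax - rn` in standard mode, `agmax/2 - rn`
#' under the printed-4theta variant), the light compensation point `lcp`
#' (PPFD where net A crosses zero) and the saturating light `lsp` (PPFD
#' where net A reaches 75% of `asat`).  Roots are found by a bracketing
#' solver on \[0, 1e5\] and verified to `|A - target| < 1e-8`; absent
#' roots yield `NA`.
#'
#' @param fit An `nrh_fit` object or a named parameter vector
#'   `c(phi, agmax, theta, rn)`.
#' @param denominator_mode Used when `fit` is a bare parameter vector.
#' @return A tibble with columns `asat`, `lcp`, `lsp`.
#' @export
nrh_derived <- function(fit, denominator_mode = c("standard2theta",
                                                  "printed4theta")) {
  if (inherits(fit, "nrh_fit")) {
    p <- fit$par
    denominator_mode <- fit$denominator_mode
  } else {
    p <- fit
    denominator_mode <- match.arg(denominator_mode)
  }
  if (any(is.na(p))) return(tibble(asat = NA_real_, lcp = NA_real_, lsp = NA_real_))
  asat <- if (denominator_mode == "standard2theta") {
    unname(p["agmax"] - p["rn"])
  } else {
    unname(p["agmax"] / 2 - p["rn"])
  }
  f <- function(q, target = 0) {
    nrh_evaluate(q, p["phi"], p["agmax"], p["theta"], p["rn"],
                 denominator_mode) - target
  }
  root <- function(target) {
    lo <- 0; hi <- 1e5
    if (f(lo, target) * f(hi, target) > 0) return(NA_real_)
    r <- uniroot(f, c(lo, hi), target = target, tol = 1e-12)$root
    if (abs(f(r, target)) < 1e-8) r else NA_real_
  }
  tibble(asat = asat, lcp = root(0), lsp = root(0.75 * asat))
}

#' Fit light-response curves in batch
#'
#' Applies [nrh_fit()] to every curve in a long-format table and returns
#' one row per curve — the tidy interface used by the pipeline.
#'
#' @param curves A data frame with columns `curve_id`, `ppfd`, `A`
#'   (e.g. from [read_light_curves()] or [simulate_light_curve()]).
#' @inheritParams nrh_fit
#' @return A tibble with one row per `curve_id`: the four parameters,
#'   `asat`, `lcp`, `lsp`, `rss`, `converged`, `flags` and `n_points`.
#' @export
fit_light_curves <- function(curves, method = c("onls", "ols"),
                             denominator_mode = c("standard2theta",
                                                  "printed4theta")) {
  method <- match.arg(method)
  denominator_mode <- match.arg(denominator_mode)
  curves <- as_tibble(curves)
  stopifnot(all(c("curve_id", "ppfd", "A") %in% names(curves)))
  curves |>
    dplyr::group_by(curve_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- nrh_fit(df, method = method, denominator_mode = denominator_mode)
      tibble(phi = fit$par[["phi"]], agmax = fit$par[["agmax"]],
             theta = fit$par[["theta"]], rn = fit$par[["rn"]],
             asat = fit$asat, lcp = fit$lcp, lsp = fit$lsp,
             rss = fit$rss, converged = fit$converged,
             flags = paste(fit$flags, collapse = ";"), n_points = fit$n)
    }) |>
    dplyr::ungroup()
}

#' @export
print.nrh_fit <- function(x, ...) {
  cat("<nrh_fit>", x$method, "/", x$denominator_mode,
      if (!x$converged) "(NOT converged)", "\n")
  print(round(x$par, 5))
  cat(sprintf("  asat %.3f  lcp %.2f  lsp %.1f  rss %.4g  n %d\n",
              x$asat, x$lcp, x$lsp, x$rss, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an NRH light-response fit
#'
#' @param x An `nrh_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`,
#'   `estimate`).
#' @export
tidy.nrh_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par))
}

#' One-row summary of an NRH light-response fit
#'
#' @param x An `nrh_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `asat`, `lcp`, `lsp`, `rss`, `converged`,
#'   `n`, `flags`.
#' @export
glance.nrh_fit <- function(x, ...) {
  tibble(asat = x$asat, lcp = x$lcp, lsp = x$lsp, rss = x$rss,
         converged = x$converged, n = x$n,
         flags = paste(x$flags, collapse = ";"))
}

#' Plot an NRH light-response fit
#'
#' Observed points with the fitted nonrectangular hyperbola overlaid.
#'
#' @param object An `nrh_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nrh_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(ppfd = seq(0, max(dat$ppfd), length.out = 200))
  p <- object$par
  grid$A <- nrh_evaluate(grid$ppfd, p["phi"], p["agmax"], p["theta"], p["rn"],
                         object$denominator_mode)
  ggplot2::ggplot(dat, ggplot2::aes(x = ppfd, y = A)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = expression(PPFD ~ (mu * mol ~ m^-2 ~ s^-1)),
                  y = expression(A ~ (mu * mol ~ m^-2 ~ s^-1)))
}
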