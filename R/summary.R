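#' Summarize trait distributions across a population
#'
#' Per-trait descriptive statistics (n, mean, SD, SE, min, max,
#' skewness) plus a Shapiro-Wilk normality test, computed over the
#' QC-passing, non-missing values of each requested trait column.
#' QC-failed records (where a `qc_pass` column is present and `FALSE`)
#' are excluded by default and their count reported — never silently
#' dropped.  A trait is flagged non-normal at `shapiro_p <
#' normality_alpha` (default 0.01).
#'
#' @param derived A tibble from [derive_traits()] (or any table holding
#'   the trait columns, optionally with `qc_pass`).
#' @param traits Character vector of trait column names to summarise.
#' @param use_qc Exclude rows with `qc_pass == FALSE` (default `TRUE`).
#' @param normality_alpha Threshold on the Shapiro-Wilk p-value below
#'   which the distribution is flagged non-normal.
#' @return A tibble with one row per trait: `trait`, `n`, `n_excluded`,
#'   `mean`, `sd`, `se`, `min`, `max`, `skewness`, `shapiro_w`,
#'   `shapiro_p`, `normal`.  Degenerate traits (constant or `n < 3`)
#'   carry `NA` for skewness/normality.
#' @export
summarize_traits <- function(derived, traits = c("A", "gsw", "gm", "vcmax",
                                                 "iwue", "gsc"),
                             use_qc = TRUE, normality_alpha = 0.01) {
  derived <- as_tibble(derived)
  missing <- setdiff(traits, names(derived))
  if (length(missing)) {
    abort(paste0("unknown trait column(s): ", paste(missing, collapse = ", ")))
  }
  keep <- if (use_qc && "qc_pass" %in% names(derived)) derived$qc_pass else
    rep(TRUE, nrow(derived))
  purrr::map_dfr(traits, function(tr) {
    v_all <- derived[[tr]]
    v <- v_all[keep & !is.na(v_all)]
    n <- length(v)
    sw <- if (n >= 3 && n <= 5000 && sd(v) > 0) {
      tryCatch(shapiro.test(v), error = function(e) NULL)
    } else NULL
    skew <- if (n >= 3 && sd(v) > 0) e1071::skewness(v) else NA_real_
    tibble(trait = tr, n = n, n_excluded = length(v_all) - n,
           mean = if (n) mean(v) else NA_real_,
           sd = if (n) sd(v) else NA_real_,
           se = if (n) sd(v) / sqrt(n) else NA_real_,
           min = if (n) min(v) else NA_real_,
           max = if (n) max(v) else NA_real_,
           skewness = skew,
           shapiro_w = if (!is.null(sw)) unname(sw$statistic) else NA_real_,
           shapiro_p = if (!is.null(sw)) sw$p.value else NA_real_,
           normal = if (!is.null(sw)) sw$p.value >= normality_alpha else NA)
  })
}

#' Pairwise trait correlations with regression lines
#'
#' Pearson correlation (with its test p-value) and the ordinary
#' least-squares line `y = slope * x + intercept` for each pair of trait
#' columns.  Rows are dropped pairwise (not listwise) over missing
#' values and QC failures, and the per-pair n is reported.
#'
#' @param derived A tibble from [derive_traits()].
#' @param traits Character vector of trait columns; all unordered pairs
#'   are evaluated.
#' @param pairs Optional two-column data frame (or list of length-2
#'   character vectors) of explicit (x, y) pairs, overriding `traits`.
#' @param use_qc Exclude rows with `qc_pass == FALSE` (default `TRUE`).
#' @return A tibble with `trait_x`, `trait_y`, `n`, `r`, `p`, `slope`,
#'   `intercept`.
#' @export
correlate_traits <- function(derived, traits = c("A", "gsw", "gm", "vcmax",
                                                 "iwue", "gsc"),
                             pairs = NULL, use_qc = TRUE) {
  derived <- as_tibble(derived)
  if (is.null(pairs)) {
    missing <- setdiff(traits, names(derived))
    if (length(missing)) {
      abort(paste0("unknown trait column(s): ", paste(missing, collapse = ", ")))
    }
    cmb <- utils::combn(traits, 2)
    pairs <- tibble(trait_x = cmb[1, ], trait_y = cmb[2, ])
  } else if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- tibble(trait_x = vapply(pairs, `[`, "", 1),
                    trait_y = vapply(pairs, `[`, "", 2))
  } else {
    pairs <- as_tibble(pairs)
    names(pairs)[1:2] <- c("trait_x", "trait_y")
  }
  keep <- if (use_qc && "qc_pass" %in% names(derived)) derived$qc_pass else
    rep(TRUE, nrow(derived))
  purrr::pmap_dfr(pairs, function(trait_x, trait_y, ...) {
    x <- derived[[trait_x]]; y <- derived[[trait_y]]
    ok <- keep & !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || sd(y) == 0) {
      return(tibble(trait_x = trait_x, trait_y = trait_y, n = n,
                    r = if (identical(trait_x, trait_y) && n >= 1) 1 else NA_real_,
                    p = NA_real_, slope = NA_real_, intercept = NA_real_))
    }
    ct <- cor.test(x, y)
    fit <- lm(y ~ x)
    tibble(trait_x = trait_x, trait_y = trait_y, n = n,
           r = unname(ct$estimate), p = ct$p.value,
           slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  })
}

#' Compare a fitted light-curve parameter between two groups
#'
#' Welch (unequal-variance) two-sample comparison of a named fitted
#' parameter between two groups of light-curve fits — e.g. curves
#' measured on excised tillers versus in situ leaves.  Identical groups
#' return a difference of zero with p = 1; degenerate (constant,
#' identical) groups are handled without error.
#'
#' @param fits_a,fits_b Tibbles from [fit_light_curves()] (>= 2 rows
#'   each); only converged fits are used.
#' @param parameter Column to compare (default `"asat"`).
#' @return A one-row tibble: `parameter`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `difference` (a - b), `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(fits_a, fits_b, parameter = "asat") {
  fits_a <- as_tibble(fits_a); fits_b <- as_tibble(fits_b)
  for (f in list(fits_a, fits_b)) {
    if (!parameter %in% names(f)) {
      abort(paste0("parameter column not found: ", parameter))
    }
  }
  pick <- function(f) {
    v <- f[[parameter]]
    if ("converged" %in% names(f)) v <- v[f$converged]
    v[!is.na(v)]
  }
  a <- pick(fits_a); b <- pick(fits_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 usable fits")
  }
  tt <- tryCatch(t.test(a, b), error = function(e) NULL)
  if (is.null(tt)) {  # both groups constant: Welch undefined
    diff <- mean(a) - mean(b)
    return(tibble(parameter = parameter, n_a = length(a), n_b = length(b),
                  mean_a = mean(a), mean_b = mean(b), difference = diff,
                  statistic = NA_real_, df = NA_real_,
                  p_value = if (abs(diff) < 1e-12) 1 else NA_real_))
  }
  tibble(parameter = parameter, n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b), difference = mean(a) - mean(b),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Histograms of trait distributions
#'
#' Frequency distributions of the requested traits over QC-passing
#' records, one facet per trait with free scales.
#'
#' @inheritParams summarize_traits
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_trait_distributions <- function(derived, traits = c("A", "gsw", "gm",
                                                         "vcmax", "iwue",
                                                         "gsc"),
                                     use_qc = TRUE, bins = 30) {
  derived <- as_tibble(derived)
  keep <- if (use_qc && "qc_pass" %in% names(derived)) derived$qc_pass else
    rep(TRUE, nrow(derived))
  long <- derived[keep, intersect(traits, names(derived))] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "trait",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = NULL, y = "count")
}
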