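#' Construct a cumulative dose-volume histogram curve
#'
#' A `dvh_curve` holds a cumulative whole-body DVH: for each dose level
#' (percent of the prescription dose) the absolute volume in cm^3 receiving
#' at least that dose. Dose levels must be strictly increasing and volumes
#' non-increasing.
#'
#' @param pct numeric vector of dose levels in percent of prescription.
#' @param volume_cc numeric vector of covered volumes in cm^3.
#' @param prescription_dose_gy optional prescription dose in Gy (metadata).
#' @return An object of class `dvh_curve` with a data frame `points`.
#' @export
dvh_curve <- function(pct, volume_cc, prescription_dose_gy = NA_real_) {
  if (length(pct) != length(volume_cc))
    stop("`pct` and `volume_cc` must have equal length", call. = FALSE)
  if (length(pct) < 2L)
    stop("a DVH curve needs at least 2 points", call. = FALSE)
  if (anyNA(pct) || anyNA(volume_cc))
    stop("DVH points must not contain missing values", call. = FALSE)
  ord <- order(pct)
  pct <- as.numeric(pct[ord]); volume_cc <- as.numeric(volume_cc[ord])
  if (any(duplicated(pct)))
    stop("duplicate dose levels in DVH curve", call. = FALSE)
  if (any(volume_cc < 0))
    stop("DVH volumes must be non-negative", call. = FALSE)
  bad <- which(diff(volume_cc) > 1e-9)
  if (length(bad) > 0)
    stop("not a cumulative DVH: volume increases from ", pct[bad[1]],
         "% to ", pct[bad[1] + 1], "% (row ", bad[1] + 1, ")", call. = FALSE)
  structure(list(points = data.frame(pct = pct, volume_cc = volume_cc),
                 prescription_dose_gy = prescription_dose_gy),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("dvh_curve:", nrow(x$points), "points,",
      min(x$points$pct), "-", max(x$points$pct), "% of prescription\n")
  invisible(x)
}

#' Read a cumulative DVH from a two-column CSV
#'
#' Expects a header naming the columns `dose_pct` (percent of prescription
#' dose) and `volume_cc` (absolute covered volume in cm^3), one curve per
#' file. Absolute-dose exports must be normalised to percent upstream.
#'
#' @param path path to the CSV file.
#' @return A validated [dvh_curve()].
#' @seealso [write_dvh()]
#' @export
read_dvh <- function(path) {
  if (!file.exists(path))
    stop("DVH file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  need <- c("dose_pct", "volume_cc")
  if (!all(need %in% names(tab)))
    stop("DVH file ", path, " must have columns dose_pct, volume_cc",
         call. = FALSE)
  if (nrow(tab) < 2L)
    stop("DVH file ", path, " has fewer than 2 rows", call. = FALSE)
  tryCatch(dvh_curve(tab$dose_pct, tab$volume_cc),
           error = function(e) stop("in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a DVH curve as a two-column CSV
#'
#' @param curve a [dvh_curve()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  utils::write.csv(
    data.frame(dose_pct = curve$points$pct,
               volume_cc = curve$points$volume_cc),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Covered volume at a dose level
#'
#' Linear interpolation of the cumulative DVH; exact at the stored knots.
#' No extrapolation: levels outside the curve span are an error.
#'
#' @param curve a [dvh_curve()].
#' @param pct dose level(s) in percent of prescription, within the span.
#' @return Covered volume(s) in cm^3.
#' @export
volume_at_pct <- function(curve, pct) {
  stopifnot(inherits(curve, "dvh_curve"))
  lo <- min(curve$points$pct); hi <- max(curve$points$pct)
  if (any(pct < lo - 1e-9 | pct > hi + 1e-9))
    stop("dose level outside the DVH span [", lo, ", ", hi,
         "]%; no extrapolation", call. = FALSE)
  stats::approx(curve$points$pct, curve$points$volume_cc, xout = pct,
                rule = 1, ties = "ordered")$y
}

#' Equivalent-sphere radius of a volume
#'
#' The radius of the sphere with the same volume, `R = (3 V / (4 pi))^(1/3)`.
#' Summarises the spatial extent of an (irregular) isodose volume by its
#' spherical equivalent.
#'
#' @param V volume(s) in cm^3, `>= 0`.
#' @return Radius in cm; 0 for `V = 0`.
#' @examples
#' equivalent_radius(4 * pi / 3)  # 1
#' @export
equivalent_radius <- function(V) {
  if (!is.numeric(V) || anyNA(V) || any(V < 0))
    stop("`V` must be non-negative (cm^3)", call. = FALSE)
  (3 * V / (4 * pi))^(1 / 3)
}

#' Dose fall-off distances from a cumulative DVH
#'
#' For each requested dose level, the covered volume, its equivalent-sphere
#' radius, and the mean dose fall-off distance
#' `d_PCT = R_PCT - R_100%` — the average distance over which the dose
#' drops from the prescription level to PCT percent. `d` is 0 at the 100%
#' level by construction.
#'
#' @param curve a [dvh_curve()] whose span includes 100%.
#' @param levels dose levels in percent, all within the span.
#' @return A data frame with columns `pct`, `V_PCT`, `R_PCT`, `d_PCT`.
#' @export
falloff_distances <- function(curve, levels) {
  stopifnot(inherits(curve, "dvh_curve"))
  span <- range(curve$points$pct)
  if (100 < span[1] - 1e-9 || 100 > span[2] + 1e-9)
    stop("the 100% level is outside the DVH span; d_PCT is undefined",
         call. = FALSE)
  v <- volume_at_pct(curve, levels)
  r <- equivalent_radius(v)
  r100 <- equivalent_radius(volume_at_pct(curve, 100))
  d <- r - r100
  d[abs(levels - 100) < 1e-9] <- 0
  data.frame(pct = levels, V_PCT = v, R_PCT = r, d_PCT = d)
}

#' Fit the linear dose-gradient model to a DVH
#'
#' Samples the curve at regular dose levels over the rapid fall-off range,
#' computes the fall-off distance of each level, and fits the linear model
#' `PCT = B0 + B1 * d_PCT` by ordinary least squares. `B1` (%/cm, negative)
#' is the dose gradient used to justify the linear distance penalty of the
#' equivalent-volume model.
#'
#' The 100% level anchors the distance origin (`d_100% = 0` by definition)
#' and is therefore excluded from the regression sample: its distance is
#' definitional rather than measured, and including it would bias the
#' intercept toward 100 on any curve whose trend breaks at the prescription
#' plateau. Standard errors depend on the sampling step and should be read
#' as descriptive.
#'
#' @param curve a [dvh_curve()] spanning the fit range and 100%.
#' @param fit_range dose range in percent over which the fall-off is
#'   approximately linear. Default `c(48, 100)`, the rapid fall-off region
#'   of VMAT whole-body DVHs.
#' @param step sampling step in percent. Default 2.
#' @return An object of class `gradient_fit`: `B0`, `B1`, `se_B0`, `se_B1`,
#'   `R2`, `fit_range`, `step`, and the sampled `levels` data frame.
#' @examples
#' dvh <- synthesize_dvh(dvh_generator_spec(B0 = 101.637, B1 = -28.369,
#'                                          R100 = 2.0))
#' fit_gradient(dvh)
#' @export
fit_gradient <- function(curve, fit_range = c(48, 100), step = 2) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    stop("`fit_range` must be (low, high) with low < high", call. = FALSE)
  if (!is.numeric(step) || step <= 0)
    stop("`step` must be positive", call. = FALSE)
  span <- range(curve$points$pct)
  if (fit_range[1] < span[1] - 1e-9 || fit_range[2] > span[2] + 1e-9)
    stop("`fit_range` outside the DVH span [", span[1], ", ", span[2], "]%",
         call. = FALSE)
  levels <- seq(fit_range[1], fit_range[2], by = step)
  levels <- levels[abs(levels - 100) > 1e-9]  # anchor level excluded
  if (length(levels) < 3L)
    stop("fewer than 3 dose levels in the fit range", call. = FALSE)
  tab <- falloff_distances(curve, levels)
  if (stats::sd(tab$d_PCT) < 1e-12)
    stop("zero variance in fall-off distances; cannot fit gradient",
         call. = FALSE)
  fit <- stats::lm(pct ~ d_PCT, data = tab)
  # a noiseless synthetic curve fits exactly; the perfect-fit warning from
  # summary.lm is expected there, not actionable
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  r2 <- sm$r.squared
  structure(list(B0 = unname(co[1, 1]), B1 = unname(co[2, 1]),
                 se_B0 = unname(co[1, 2]), se_B1 = unname(co[2, 2]),
                 R2 = r2, fit_range = fit_range, step = step,
                 levels = tab), class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("gradient_fit: PCT = %.3f %+.3f * d_PCT  (R^2 = %.4f)\n",
              x$B0, x$B1, x$R2))
  cat(sprintf("  SE(B0) = %.3f, SE(B1) = %.3f; fit over [%g, %g]%% step %g%%\n",
              x$se_B0, x$se_B1, x$fit_range[1], x$fit_range[2], x$step))
  invisible(x)
}

#' Evaluate the linear dose-gradient model
#'
#' `PCT = B0 + B1 * d` — the percent of prescription dose expected at
#' distance `d` cm from the 100% isodose surface.
#'
#' @param B0 intercept in percent.
#' @param B1 slope in percent per cm (negative for a fall-off).
#' @param d distance(s) in cm.
#' @return Percent of prescription dose.
#' @examples
#' evaluate_model(101.637, -28.369, seq(0.2, 1, 0.2))
#' # 96.0 90.3 84.6 78.9 73.3 (to one decimal)
#' @export
evaluate_model <- function(B0, B1, d) {
  B0 + B1 * d
}

#' Summarise a cohort of dose-gradient fits
#'
#' Arithmetic means of the per-case coefficients, the inter-case coefficient
#' of variation of the slope (sample standard deviation over the absolute
#' mean, in percent), and the Pearson correlation of the signed slope with
#' PTV volume (larger targets have shallower gradients, so the signed
#' correlation is positive).
#'
#' @param fits a list of [fit_gradient()] results, or a data frame with
#'   columns `B0` and `B1`.
#' @param ptv_volumes optional numeric vector of PTV volumes in cm^3,
#'   aligned with `fits`; required for the correlation.
#' @return An object of class `cohort_gradient_summary`: `mean_B0`,
#'   `mean_B1`, `cv_B1_pct` (`NA` with fewer than 2 cases),
#'   `pearson_r_B1_volume`, `abs_pearson_r_B1_volume`, `n_cases`.
#' @export
summarize_cohort <- function(fits, ptv_volumes = NULL) {
  if (is.data.frame(fits)) {
    if (!all(c("B0", "B1") %in% names(fits)))
      stop("data-frame input needs columns B0 and B1", call. = FALSE)
    b0 <- fits$B0; b1 <- fits$B1
  } else {
    ok <- vapply(fits, inherits, logical(1), what = "gradient_fit")
    if (!all(ok))
      stop("`fits` must be gradient_fit objects or a B0/B1 data frame",
           call. = FALSE)
    b0 <- vapply(fits, `[[`, numeric(1), "B0")
    b1 <- vapply(fits, `[[`, numeric(1), "B1")
  }
  n <- length(b1)
  if (n < 1L) stop("empty cohort", call. = FALSE)
  if (!is.null(ptv_volumes) && length(ptv_volumes) != n)
    stop("`ptv_volumes` length (", length(ptv_volumes),
         ") does not match the number of fits (", n, ")", call. = FALSE)
  cv <- if (n >= 2L) 100 * stats::sd(b1) / abs(mean(b1)) else NA_real_
  r <- if (!is.null(ptv_volumes) && n >= 2L) {
    stats::cor(b1, ptv_volumes)
  } else NA_real_
  structure(list(mean_B0 = mean(b0), mean_B1 = mean(b1), cv_B1_pct = cv,
                 pearson_r_B1_volume = r,
                 abs_pearson_r_B1_volume = abs(r), n_cases = n),
            class = "cohort_gradient_summary")
}

#' @export
print.cohort_gradient_summary <- function(x, ...) {
  cat(sprintf("cohort of %d gradient fits\n", x$n_cases))
  cat(sprintf("  mean model: PCT = %.3f %+.3f * d_PCT\n", x$mean_B0, x$mean_B1))
  if (is.na(x$cv_B1_pct)) {
    cat("  CV(B1): undefined (single case)\n")
  } else {
    cat(sprintf("  CV(B1) = %.2f%%\n", x$cv_B1_pct))
  }
  if (!is.na(x$pearson_r_B1_volume))
    cat(sprintf("  Pearson r(B1, PTV volume) = %.3f\n", x$pearson_r_B1_volume))
  invisible(x)
}
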