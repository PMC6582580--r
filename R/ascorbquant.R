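# Chromatogram-based L-ascorbate quantitation: baseline estimation, peak
# detection and integration, linear calibration from standards, ascorbate-
# oxidase identity confirmation, unit conversion, two-group comparison.

.rolling_min <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i)
    min(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Detect and integrate peaks in a chromatogram
#'
#' The baseline is estimated by a rolling minimum (window much wider than a
#' peak) and subtracted; local maxima of the corrected trace with
#' prominence at or above `min_prominence` are reported, with trapezoidal
#' areas integrated between the points where the corrected signal falls to
#' a small fraction of the peak height (or the saddle towards a
#' neighbouring peak).
#'
#' @param chrom A `chrom_truth` from [synth_chromatogram()] or any list
#'   with numeric `times` and `signal` of equal length (>= 10 samples).
#' @param min_prominence Minimum peak prominence in a.u. (default 0.1).
#' @param baseline_window Rolling-minimum window in samples (odd).
#' @return Data frame: `rt`, `height`, `prominence`, `area`, `left`,
#'   `right` (bound times in s), sorted by retention time.
#' @export
detect_peaks <- function(chrom, min_prominence = 0.1, baseline_window = 201L) {
  times <- chrom$times
  x <- chrom$signal
  stopifnot(length(times) == length(x), length(x) >= 10L,
            all(diff(times) > 0))
  y <- x - .rolling_min(x, baseline_window)
  n <- length(y)
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(cand) == 0L) {
    return(data.frame(rt = numeric(0), height = numeric(0),
                      prominence = numeric(0), area = numeric(0),
                      left = numeric(0), right = numeric(0)))
  }
  peaks <- list()
  for (p in cand) {
    h <- y[p]
    # saddles: minimum between the peak and the nearest higher point
    i <- p; lmin <- h
    while (i > 1L && y[i] <= h) { i <- i - 1L; lmin <- min(lmin, y[i]) }
    lsad <- i
    i <- p; rmin <- h
    while (i < n && y[i] <= h) { i <- i + 1L; rmin <- min(rmin, y[i]) }
    rsad <- i
    prom <- h - max(if (lsad == 1L && y[1] <= h) min(y[1:p]) else lmin,
                    if (rsad == n && y[n] <= h) min(y[p:n]) else rmin)
    if (prom < min_prominence) next
    thr <- 0.002 * h
    lb <- p
    while (lb > lsad && y[lb - 1L] > thr) lb <- lb - 1L
    rb <- p
    while (rb < rsad && y[rb + 1L] > thr) rb <- rb + 1L
    area <- pracma::trapz(times[lb:rb], y[lb:rb])
    peaks[[length(peaks) + 1L]] <- data.frame(
      rt = times[p], height = h, prominence = prom, area = area,
      left = times[lb], right = times[rb])
  }
  if (length(peaks) == 0L) {
    return(data.frame(rt = numeric(0), height = numeric(0),
                      prominence = numeric(0), area = numeric(0),
                      left = numeric(0), right = numeric(0)))
  }
  res <- do.call(rbind, peaks)
  res <- res[order(res$rt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fit a linear calibration curve from standards
#'
#' Ordinary least squares of peak area on concentration, for standards such
#' as the published 25, 50 and 100 uM L-ascorbate levels.
#'
#' @param standards Data frame with `conc` (uM) and `area` (a.u.*s), one
#'   row per standard injection; at least 2 distinct concentrations.
#' @return A `calibration_curve` list: `slope` (a.u.*s per uM),
#'   `intercept`, `r_squared`, `standards`.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("conc", "area") %in% names(standards)))
  if (length(unique(standards$conc)) < 2L)
    stop("need at least 2 distinct standard concentrations")
  fit <- stats::lm(area ~ conc, data = standards)
  sst <- sum((standards$area - mean(standards$area))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, standards = standards),
            class = "calibration_curve")
}

#' Quantify L-ascorbate in a sample chromatogram
#'
#' The largest detected peak inside the retention-time window is converted
#' to a concentration via `(area - intercept) / slope`, clipped at zero.
#'
#' @param chrom Sample chromatogram (see [detect_peaks()]).
#' @param curve A [fit_calibration()] curve with positive slope.
#' @param rt_window Numeric length-2 window (s) in which the analyte
#'   elutes.
#' @param ... Passed to [detect_peaks()].
#' @return List: `conc_uM`, `detected`, `peak` (one-row data frame or
#'   NULL).
#' @export
quantify <- function(chrom, curve, rt_window, ...) {
  stopifnot(inherits(curve, "calibration_curve"), curve$slope > 0,
            length(rt_window) == 2L)
  pk <- detect_peaks(chrom, ...)
  pk <- pk[pk$rt >= rt_window[1] & pk$rt <= rt_window[2], , drop = FALSE]
  if (nrow(pk) == 0L) {
    return(list(conc_uM = 0, detected = FALSE, peak = NULL))
  }
  best <- pk[which.max(pk$area), , drop = FALSE]
  conc <- (best$area - curve$intercept) / curve$slope
  if (conc < 0) {
    warning("peak area below calibration intercept; clipping to 0 uM")
    conc <- 0
  }
  list(conc_uM = conc, detected = TRUE, peak = best)
}

#' Confirm peak identity by ascorbate-oxidase treatment
#'
#' The analyte peak is confirmed as L-ascorbate iff its area in the
#' retention-time window drops by at least `min_reduction` (default 90%)
#' after ascorbate-oxidase treatment — the published criterion being the
#' "extinction" of the peak.
#'
#' @param sample,ao_treated Untreated and AO-treated chromatograms on
#'   comparable time grids.
#' @param rt_window Numeric length-2 retention-time window (s).
#' @param min_reduction Required fractional area reduction (default 0.9).
#' @param ... Passed to [detect_peaks()].
#' @return List: `confirmed`, `area_before`, `area_after`, `reduction`.
#' @export
confirm_identity_ao <- function(sample, ao_treated, rt_window,
                                min_reduction = 0.9, ...) {
  area_in <- function(chrom) {
    pk <- detect_peaks(chrom, ...)
    pk <- pk[pk$rt >= rt_window[1] & pk$rt <= rt_window[2], , drop = FALSE]
    if (nrow(pk) == 0L) 0 else max(pk$area)
  }
  a0 <- area_in(sample)
  a1 <- area_in(ao_treated)
  red <- if (a0 > 0) 1 - a1 / a0 else 0
  list(confirmed = a0 > 0 && red >= min_reduction,
       area_before = a0, area_after = a1, reduction = red)
}

#' Convert a homogenate concentration to an amount per individual
#'
#' For homogenates of `individuals_per_ml` individuals per millilitre of
#' extraction buffer: conc uM x molar mass / 1000 / individuals_per_ml
#' gives ug per individual.  `recovery` exposes an extraction-efficiency
#' factor (default 1, i.e. naive dimensional analysis).
#'
#' @param conc_uM Concentration in uM (>= 0).
#' @param individuals_per_ml Individuals homogenised per ml (> 0).
#' @param molar_mass Analyte molar mass in g/mol (L-ascorbate: 176.12).
#' @param recovery Fractional extraction recovery applied multiplicatively.
#' @return Micrograms per individual.
#' @export
per_individual_amount <- function(conc_uM, individuals_per_ml,
                                  molar_mass = 176.12, recovery = 1) {
  stopifnot(individuals_per_ml > 0, conc_uM >= 0)
  conc_uM * molar_mass / 1000 / individuals_per_ml * recovery
}

#' Two-group comparison of concentrations (unpaired t-test)
#'
#' Two-tailed unpaired t-test, pooled variance by default (Welch behind
#' `var_equal = FALSE`), as used for the published male/female and
#' treatment comparisons.
#'
#' @param a,b Numeric vectors of per-sample values, each of length >= 2.
#' @param var_equal Pooled variance (default TRUE).
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf, df = length(a) + length(b) - 2L,
                p = if (eq) 1 else 0, mean_a = mean(a), mean_b = mean(b),
                sd_a = 0, sd_b = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b))
}
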