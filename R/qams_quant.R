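# QAMS quantitation: calibration fitting, slope-ratio relative correction
# factors (RCF), relative-retention-time peak location, external-standard
# (ESM) and single-marker (QAMS) content calculation, and method-validation
# statistics.
#
# Content formula: for a prepared solution of `mass` g in `volume` ml at a
# further dilution factor d, an analyte at C ug/ml corresponds to
#   W (w/w %) = C * volume * d / (mass * 1e6) * 100.
# QAMS uses the slope-only conversion C = f * A / F_s, where f = F_s / F_k
# is the ratio of reference to analyte calibration slopes.

#' Serial dilution concentration levels
#'
#' Descending geometric series starting at `top`, dividing by `factor` at
#' each of `n` levels, as used for 2-fold calibration series.
#'
#' @param top Highest concentration (ug/ml), > 0.
#' @param factor Dilution factor per step, >= 1.
#' @param n Number of levels, >= 1.
#' @return Numeric vector of `n` concentrations, descending.
#' @examples
#' serial_dilution_levels(365, 2, 6)
#' @export
serial_dilution_levels <- function(top, factor = 2, n = 6) {
  if (!is.numeric(top) || top <= 0) stop("top concentration must be > 0")
  if (factor < 1) stop("dilution factor must be >= 1")
  if (n < 1) stop("n must be >= 1")
  top / factor^(seq_len(n) - 1)
}

#' Fit a calibration curve
#'
#' Ordinary least-squares line `area = F * conc + a`; the coefficient of
#' determination is the squared Pearson correlation of concentration and
#' area.
#'
#' @param conc Concentrations (ug/ml) or a two-column data.frame
#'   `(conc, area)`.
#' @param area Peak areas (same length as `conc`).
#' @param analyte Analyte name carried on the result.
#' @return A `calibration_curve`: list with `analyte`, `slope`,
#'   `intercept`, `r2`, `range_low`, `range_high`, `n`.
#' @examples
#' cc <- fit_calibration(c(1, 2, 4), c(5.2, 10.1, 20.3))
#' cc$slope
#' @export
fit_calibration <- function(conc, area = NULL, analyte = NA_character_) {
  if (is.data.frame(conc)) {
    area <- conc[[2]]
    conc <- conc[[1]]
  }
  stopifnot(length(conc) == length(area), length(conc) >= 2)
  if (length(unique(conc)) < 2) stop("need at least 2 distinct concentrations")
  fit <- stats::lm.fit(cbind(1, conc), area)
  r2 <- if (stats::var(area) == 0) 1 else stats::cor(conc, area)^2
  structure(
    list(analyte = analyte,
         slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r2 = r2,
         range_low = min(conc), range_high = max(conc),
         n = length(conc)),
    class = "calibration_curve")
}

#' Construct a calibration curve from known parameters
#'
#' For curves whose regression parameters are already tabulated (rather
#' than refit from raw points with [fit_calibration()]).
#'
#' @param analyte Analyte name.
#' @param slope,intercept Line parameters (slope > 0).
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param range_low,range_high Calibrated concentration range (ug/ml).
#' @param n Number of calibration levels the parameters came from.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(analyte, slope, intercept, r2 = NA_real_,
                              range_low = -Inf, range_high = Inf, n = NA_integer_) {
  stopifnot(slope > 0, is.na(r2) || (r2 >= 0 && r2 <= 1),
            range_low < range_high)
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r2 = r2, range_low = range_low, range_high = range_high,
                 n = n),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration [%s]: area = %.4f * C %+.4f  (R2 = %.4f, %g-%g ug/ml, n = %d)\n",
              x$analyte, x$slope, x$intercept, x$r2,
              x$range_low, x$range_high, x$n))
  invisible(x)
}

#' Relative correction factor (slope method)
#'
#' `f = F_s / F_k`: the reference calibration slope over the analyte
#' calibration slope.
#'
#' @param reference,analyte `calibration_curve` objects (or bare slopes).
#' @return Unitless correction factor f, > 0.
#' @examples
#' compute_rcf(8.6962, 6.84) # 1.2714
#' @export
compute_rcf <- function(reference, analyte) {
  fs <- if (inherits(reference, "calibration_curve")) reference$slope else reference
  fk <- if (inherits(analyte, "calibration_curve")) analyte$slope else analyte
  if (!is.numeric(fs) || !is.numeric(fk) || fs <= 0 || fk <= 0)
    stop("calibration slopes must be > 0")
  fs / fk
}

#' RCF table for a set of calibration curves
#'
#' @param curves Named list of `calibration_curve`s.
#' @param reference Name of the reference analyte (must be in `curves`).
#' @param rrts Optional named relative retention times (reference = 1).
#' @return List with `reference`, `factors` (named, reference = 1), `rrts`.
#' @export
rcf_table <- function(curves, reference, rrts = NULL) {
  if (!reference %in% names(curves))
    stop("reference analyte not among curves: ", reference)
  ref <- curves[[reference]]
  factors <- vapply(curves, function(cc) compute_rcf(ref, cc), numeric(1))
  structure(list(reference = reference, factors = factors, rrts = rrts),
            class = "rcf_table")
}

#' Locate a peak by relative retention time
#'
#' Returns the peak whose retention-time ratio to the reference peak is
#' closest to `expected_rrt` and within `tol_pct` percent. Exact ties are
#' broken by earlier retention time.
#'
#' @param peaks data.frame with columns `rt_min` and `area`.
#' @param reference_rt Reference peak retention time (min), > 0.
#' @param expected_rrt Expected retention-time ratio, > 0.
#' @param tol_pct Relative tolerance in percent (default 3).
#' @return The matching row of `peaks`.
#' @export
locate_by_rrt <- function(peaks, reference_rt, expected_rrt, tol_pct = 3) {
  stopifnot(reference_rt > 0, tol_pct > 0)
  rrt <- peaks$rt_min / reference_rt
  dev <- abs(rrt - expected_rrt)
  within <- dev / expected_rrt * 100 <= tol_pct
  if (!any(within)) stop("no peak within ", tol_pct, "% of RRT ", expected_rrt)
  idx <- which(within)
  best <- idx[order(dev[idx], peaks$rt_min[idx])][1]
  peaks[best, , drop = FALSE]
}

#' Sample-preparation parameters
#'
#' @param mass_g Weighed sample mass (g).
#' @param volume_ml Volumetric-flask volume (ml).
#' @param dilution Further dilution factor (1 = none).
#' @param purity Optional standard purity fraction in (0, 1].
#' @return List of class `sample_prep`.
#' @export
sample_prep <- function(mass_g = 0.5, volume_ml = 100, dilution = 1,
                        purity = 1) {
  stopifnot(mass_g > 0, volume_ml > 0, dilution > 0,
            purity > 0, purity <= 1)
  structure(list(mass_g = mass_g, volume_ml = volume_ml,
                 dilution = dilution, purity = purity),
            class = "sample_prep")
}

conc_to_ww <- function(conc_ug_ml, prep) {
  conc_ug_ml * prep$volume_ml * prep$dilution / (prep$mass_g * 1e6) * 100
}

ww_to_conc <- function(ww_pct, prep) {
  ww_pct / 100 * prep$mass_g * 1e6 / (prep$volume_ml * prep$dilution)
}

#' External-standard content (w/w %)
#'
#' Inverts the analyte's own calibration line and converts to mass
#' fraction. Concentrations outside the calibrated range warn (they are
#' still reported, as out-of-range batch contents occur in practice);
#' negative back-calculated concentrations are an error.
#'
#' @param area Peak area, >= 0.
#' @param curve The analyte's `calibration_curve`.
#' @param prep A `sample_prep`.
#' @param apply_purity If `TRUE`, divide by `prep$purity`.
#' @return Content in w/w percent.
#' @export
esm_content <- function(area, curve, prep, apply_purity = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"), area >= 0)
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc < 0)) stop("back-calculated concentration < 0")
  out_of_range <- conc < curve$range_low | conc > curve$range_high
  if (any(out_of_range))
    warning(sum(out_of_range), " concentration(s) outside calibrated range [",
            curve$range_low, ", ", curve$range_high, "] ug/ml")
  w <- conc_to_ww(conc, prep)
  if (apply_purity) w <- w / prep$purity
  w
}

#' QAMS content from the reference curve (w/w %)
#'
#' Slope-only single-marker conversion `C = f * A / F_s` followed by the
#' same concentration-to-mass-fraction step as [esm_content()]. Setting
#' `subtract_intercept = TRUE` uses `C = f * (A - a_s) / F_s` instead, for
#' sensitivity analysis of the intercept-neglect assumption.
#'
#' @param area Peak area of the analyte, >= 0.
#' @param f Relative correction factor for the analyte, > 0.
#' @param reference_curve The reference analyte's `calibration_curve`.
#' @param prep A `sample_prep`.
#' @param subtract_intercept Subtract the reference intercept first.
#' @param apply_purity If `TRUE`, divide by `prep$purity`.
#' @return Content in w/w percent.
#' @export
qams_content <- function(area, f, reference_curve, prep,
                         subtract_intercept = FALSE, apply_purity = FALSE) {
  stopifnot(inherits(reference_curve, "calibration_curve"), f > 0, area >= 0)
  a0 <- if (subtract_intercept) reference_curve$intercept else 0
  conc <- f * (area - a0) / reference_curve$slope
  if (any(conc < 0)) stop("back-calculated concentration < 0")
  w <- conc_to_ww(conc, prep)
  if (apply_purity) w <- w / prep$purity
  w
}

#' Relative error between ESM and QAMS contents
#'
#' `RE = (w_esm - w_qams) / w_qams * 100`.
#'
#' @param w_esm,w_qams Contents in w/w percent; `w_qams` must be > 0.
#' @return Relative error in percent.
#' @export
relative_error <- function(w_esm, w_qams) {
  if (any(w_qams <= 0)) stop("QAMS content must be > 0")
  (w_esm - w_qams) / w_qams * 100
}

#' Spike recovery
#'
#' `(found - sample) / spiked * 100`, the fraction of a known spike
#' recovered on top of the native analyte amount.
#'
#' @param sample_amt Native amount in the unspiked sample (mg).
#' @param spiked_amt Spiked amount (mg), > 0.
#' @param found_amt Total amount found after spiking (mg).
#' @return Recovery in percent.
#' @export
recovery <- function(sample_amt, spiked_amt, found_amt) {
  if (any(spiked_amt <= 0)) stop("spiked amount must be > 0")
  (found_amt - sample_amt) / spiked_amt * 100
}

#' Relative standard deviation (percent)
#'
#' Sample standard deviation (n - 1 denominator) over the mean, times 100.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean")
  stats::sd(values) / m * 100
}

#' Quantify a batch peak table by ESM and QAMS
#'
#' For each batch and analyte, computes the external-standard content from
#' the analyte's own curve, the single-marker content from the reference
#' curve and RCF, and their relative error. The reference analyte is
#' quantified by ESM only (its QAMS content would be identical up to the
#' intercept) and gets `NA` QAMS/RE.
#'
#' @param peak_table data.frame with columns `batch_id`, `analyte`, `area`
#'   (optionally `rt_min`).
#' @param curves Named list of `calibration_curve`s covering every analyte.
#' @param reference Reference analyte name.
#' @param prep A `sample_prep`.
#' @param ... Passed to [qams_content()] (e.g. `subtract_intercept`).
#' @return data.frame `batch_id, analyte, w_esm_pct, w_qams_pct, re_pct`.
#' @export
quantify_batches <- function(peak_table, curves, reference, prep, ...) {
  stopifnot(all(c("batch_id", "analyte", "area") %in% names(peak_table)))
  missing <- setdiff(unique(peak_table$analyte), names(curves))
  if (length(missing))
    stop("no calibration curve for: ", paste(missing, collapse = ", "))
  if (!reference %in% names(curves))
    stop("reference analyte not among curves: ", reference)
  rcfs <- rcf_table(curves, reference)
  n <- nrow(peak_table)
  w_esm <- w_qams <- re <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    an <- peak_table$analyte[i]
    a <- peak_table$area[i]
    w_esm[i] <- suppressWarnings(esm_content(a, curves[[an]], prep))
    if (an != reference) {
      w_qams[i] <- qams_content(a, rcfs$factors[[an]], curves[[reference]],
                                prep, ...)
      re[i] <- relative_error(w_esm[i], w_qams[i])
    }
  }
  data.frame(batch_id = peak_table$batch_id, analyte = peak_table$analyte,
             w_esm_pct = w_esm, w_qams_pct = w_qams, re_pct = re,
             stringsAsFactors = FALSE)
}

#' Method-validation summary
#'
#' Aggregates the standard HPLC validation experiments into one report:
#' precision / repeatability / stability RSDs of repeated peak areas,
#' spike-recovery statistics, and durability (mean and RSD of RCF and RRT
#' across instrument or condition sets).
#'
#' @param precision_runs,repeatability_runs,stability_runs Named lists
#'   (per analyte) of repeated peak areas.
#' @param recovery_rows data.frame with columns `analyte`, `sample_mg`,
#'   `spiked_mg`, `found_mg`.
#' @param durability_sets Named list of condition sets; each a data.frame
#'   with columns `analyte`, `rcf` and optionally `rrt`.
#' @return List of class `validation_report` with per-analyte RSDs,
#'   recovery rows plus means/RSDs, and per-set durability statistics.
#' @export
validation_summary <- function(precision_runs = NULL,
                               repeatability_runs = NULL,
                               stability_runs = NULL,
                               recovery_rows = NULL,
                               durability_sets = NULL) {
  rsd_block <- function(runs) {
    if (is.null(runs)) return(NULL)
    if (!length(runs)) stop("empty run list")
    vapply(runs, rsd, numeric(1))
  }
  rec <- NULL
  if (!is.null(recovery_rows)) {
    if (!nrow(recovery_rows)) stop("empty recovery table")
    recovery_rows$recovery_pct <- recovery(recovery_rows$sample_mg,
                                           recovery_rows$spiked_mg,
                                           recovery_rows$found_mg)
    stats_tab <- do.call(rbind, lapply(
      split(recovery_rows, recovery_rows$analyte), function(d)
        data.frame(analyte = d$analyte[1],
                   recovery_mean = mean(d$recovery_pct),
                   recovery_rsd = rsd(d$recovery_pct))))
    rownames(stats_tab) <- NULL
    rec <- list(rows = recovery_rows, stats = stats_tab)
  }
  dur <- NULL
  if (!is.null(durability_sets)) {
    if (!length(durability_sets)) stop("empty durability list")
    dur <- lapply(durability_sets, function(d) {
      out <- do.call(rbind, lapply(split(d, d$analyte), function(x) {
        has_rrt <- !is.null(x$rrt) && !anyNA(x$rrt)
        data.frame(analyte = x$analyte[1],
                   rcf_mean = mean(x$rcf), rcf_rsd = rsd(x$rcf),
                   rrt_mean = if (has_rrt) mean(x$rrt) else NA_real_,
                   rrt_rsd = if (has_rrt) rsd(x$rrt) else NA_real_)
      }))
      rownames(out) <- NULL
      out
    })
  }
  structure(list(precision_rsd = rsd_block(precision_runs),
                 repeatability_rsd = rsd_block(repeatability_runs),
                 stability_rsd = rsd_block(stability_runs),
                 recovery = rec,
                 durability = dur),
            class = "validation_report")
}

#' Read a calibration CSV and fit all curves
#'
#' CSV columns: `analyte,conc_ug_ml,area`.
#'
#' @param path CSV path.
#' @return Named list of `calibration_curve`s.
#' @export
read_calibration_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "conc_ug_ml", "area")
  if (!all(need %in% names(tab)))
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$analyte), function(d)
    fit_calibration(d$conc_ug_ml, d$area, analyte = d$analyte[1]))
}
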