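#' Per-interval clearance from basolateral signals
#'
#' The clearance of one sampling interval is the donor-equivalent volume
#' (uL) that crossed into the receiver compartment during that interval:
#' at the first time point `A_baso[1] * V_baso / A_stock`. Because the
#' receiver is fully replaced with fresh media at every sampling, each
#' basolateral sample reflects a single interval's transport. Three modes
#' handle the later time points:
#'
#' * `per_interval` (default): `A_baso[n] * V_baso / A_stock` with no
#'   correction — each interval's receiver starts fresh, so no carried-over
#'   mass has to be subtracted.
#' * `literal`: the published correction term, subtracting from interval
#'   *n* the summed excess clearance of the previous time points over the
#'   first one, scaled by the volume factor:
#'   `clr[n] = base[n] - vf * sum(base[1:(n-1)] - base[1])`.
#'   Retained for fidelity comparisons; the simulator quantifies its bias.
#' * `donor_corrected`: per-interval clearance against the depleted donor,
#'   `A_baso[n] * V_baso / (A_stock - vf * sum(A_baso[1:(n-1)]))`, where
#'   `vf * A_baso` is the apical-equivalent signal removed by sampling.
#'
#' @param series A [well_series()].
#' @param geometry An [experiment_geometry()].
#' @param mode Correction mode, see above.
#' @return An object of class `clearance_curve`: list with `clearance`
#'   (uL per interval), `cumulative` (running sum, uL), `times` (min) and
#'   `mode`.
#' @examples
#' geom <- default_geometry()
#' w <- well_series("w1", "cells", "ibuprofen", channel = "mAU_min",
#'                  baso_signal = c(100, 100, 100, 100), stock_signal = 1000)
#' interval_clearance(w, geom)$clearance  # 90 uL each interval
#' @export
interval_clearance <- function(series, geometry,
                               mode = c("per_interval", "literal",
                                        "donor_corrected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "well_series"),
            inherits(geometry, "experiment_geometry"))
  A <- series$baso_signal
  As <- series$stock_signal
  if (As <= 0) stop("stock signal must be positive", call. = FALSE)
  if (length(A) != length(geometry$sampling_times)) {
    stop("series length does not match the sampling schedule", call. = FALSE)
  }
  vb <- geometry$basolateral_volume
  vf <- geometry$volume_factor
  base <- A * vb / As
  clr <- switch(mode,
    per_interval = base,
    literal = {
      out <- base
      for (n in seq_along(base)[-1]) {
        out[n] <- base[n] - vf * sum(base[seq_len(n - 1)] - base[1])
      }
      out
    },
    donor_corrected = {
      donor <- As - vf * c(0, cumsum(A))[seq_along(A)]
      if (any(donor <= 0)) {
        stop("donor signal depleted to zero; donor_corrected mode invalid",
             call. = FALSE)
      }
      A * vb / donor
    }
  )
  structure(
    list(clearance = clr, cumulative = cumsum(clr),
         times = geometry$sampling_times, mode = mode),
    class = "clearance_curve"
  )
}

#' Fit the cleared-volume slope PS
#'
#' Ordinary least-squares fit of cumulative cleared volume (uL) against
#' time (min), with a free intercept and the origin (0, 0) included as a
#' data point. The slope is the permeability-surface-area product PS in
#' uL/min; its reciprocal enters the series-resistance blank correction.
#'
#' @param curve A [interval_clearance()] result, or a numeric vector of
#'   cumulative cleared volumes (uL).
#' @param sampling_times Sampling times in minutes (taken from `curve` when
#'   it is a `clearance_curve`).
#' @return Object of class `permeability_slope`: list with `ps` (uL/min),
#'   `intercept` (uL), `r_squared`, `n_points`, and `flag`
#'   (`"ok"` or `"excluded"` for non-positive slopes).
#' @export
fit_ps <- function(curve, sampling_times = NULL) {
  if (inherits(curve, "clearance_curve")) {
    y <- curve$cumulative
    x <- curve$times
  } else {
    y <- as.numeric(curve)
    x <- as.numeric(sampling_times)
  }
  if (length(y) != length(x)) {
    stop("cumulative values and sampling times differ in length", call. = FALSE)
  }
  if (length(y) < 2) stop("need at least 2 time points", call. = FALSE)
  x0 <- c(0, x)
  y0 <- c(0, y)
  fit <- stats::lm(y0 ~ x0)
  ps <- unname(stats::coef(fit)[2])
  # R^2 computed directly; summary.lm() warns on exact lines
  ss_tot <- sum((y0 - mean(y0))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(
    list(ps = ps, intercept = unname(stats::coef(fit)[1]), r_squared = r2,
         n_points = length(y0),
         flag = if (is.finite(ps) && ps > 0) "ok" else "excluded"),
    class = "permeability_slope"
  )
}

#' Series-resistance blank correction
#'
#' A cell-covered insert is two barriers in series: cell layer and bare
#' membrane. The cell-layer PS follows from
#' `1/PS_cell = 1/PS_all - 1/PS_blank`. `ps_blank` is normally the mean
#' fitted PS of the matched blank group for the same compound and inhibitor.
#'
#' @param ps_all Fitted PS of the cell-covered insert (uL/min, > 0).
#' @param ps_blank Fitted PS of the matched bare-membrane group (uL/min, > 0).
#' @return `PS_cell` in uL/min. When `ps_all >= ps_blank` the correction is
#'   non-physical (noise artifact, blank-dominated) and `NA` is returned;
#'   callers flag such wells `blank_dominated`. Vectorised.
#' @examples
#' correct_blank(1, 2)  # 2
#' @export
correct_blank <- function(ps_all, ps_blank) {
  if (any(ps_all <= 0, na.rm = TRUE) || any(ps_blank <= 0, na.rm = TRUE)) {
    stop("'ps_all' and 'ps_blank' must be positive", call. = FALSE)
  }
  out <- 1 / (1 / ps_all - 1 / ps_blank)
  out[ps_all >= ps_blank] <- NA_real_
  out
}

#' Apparent permeability coefficient from PS_cell
#'
#' `Papp = 10 * PS_cell / area`: dividing PS (uL/min) by the insert area
#' (cm^2) gives uL min^-1 cm^-2 = 1e-3 cm/min; the factor 10 converts to
#' um/min.
#'
#' @param ps_cell Cell-layer PS in uL/min (>= 0).
#' @param insert_area Insert membrane area in cm^2.
#' @return Papp in um/min. Vectorised; `NA` propagates.
#' @examples
#' papp(0.336, 0.336)  # 10 um/min
#' @export
papp <- function(ps_cell, insert_area) {
  if (!is.numeric(insert_area) || any(insert_area <= 0)) {
    stop("'insert_area' must be positive", call. = FALSE)
  }
  if (any(ps_cell < 0, na.rm = TRUE)) {
    stop("'ps_cell' must be non-negative", call. = FALSE)
  }
  10 * ps_cell / insert_area
}

#' Normalise compound Papp to the paracellular marker
#'
#' Carboxyfluorescein (CF) is co-applied on every insert; expressing each
#' compound's Papp as a fold of its matched CF Papp factors out
#' insert-to-insert variation in paracellular tightness. The default is the
#' per-insert ratio (each compound well divided by the CF value of the same
#' insert, then averaged within group); `group_mean` divides the group
#' means instead, which generally differs from the mean of per-insert
#' ratios.
#'
#' @param papp_compound Compound Papp value(s), um/min.
#' @param papp_cf_matched Matched CF Papp value(s): per-insert values for
#'   `mode = "per_insert"` (recycled pairwise), or the CF group mean for
#'   `mode = "group_mean"`.
#' @param mode `"per_insert"` or `"group_mean"`.
#' @return Fold value(s), dimensionless.
#' @export
normalize_to_cf <- function(papp_compound, papp_cf_matched,
                            mode = c("per_insert", "group_mean")) {
  mode <- match.arg(mode)
  if (!length(papp_cf_matched) || all(is.na(papp_cf_matched))) {
    stop("missing matched CF partner", call. = FALSE)
  }
  if (mode == "per_insert") {
    papp_compound / papp_cf_matched
  } else {
    mean(papp_compound, na.rm = TRUE) / mean(papp_cf_matched, na.rm = TRUE)
  }
}

#' Fold change between treated and reference group means
#'
#' @param papp_treated Papp values (or mean) of the treated group.
#' @param papp_reference Papp values (or mean) of the reference group.
#' @return List with `fold` (ratio of group means) and `ratios` (each
#'   treated value over the reference mean).
#' @examples
#' fold_change(6.66, 3.64)$fold  # 1.83
#' @export
fold_change <- function(papp_treated, papp_reference) {
  ref <- mean(papp_reference, na.rm = TRUE)
  if (!is.finite(ref) || ref == 0) {
    stop("reference group mean must be non-zero", call. = FALSE)
  }
  list(fold = mean(papp_treated, na.rm = TRUE) / ref,
       ratios = papp_treated / ref)
}

#' Cumulated basolateral amount per membrane area
#'
#' Converts each interval's basolateral signal to a concentration via the
#' stock-signal/stock-concentration linearity, sums the transported amount
#' over all intervals and normalises by the membrane area:
#' `sum(A_baso/A_stock * C_stock[nmol/uL] * V_baso[uL]) / area[mm^2]`.
#'
#' @param series A [well_series()].
#' @param geometry An [experiment_geometry()].
#' @param stock_concentration Donor concentration in uM (1 uM = 1e-3
#'   nmol/uL).
#' @return Cumulated amount in nmol/mm^2.
#' @export
cumulated_amount <- function(series, geometry, stock_concentration) {
  stopifnot(inherits(series, "well_series"),
            inherits(geometry, "experiment_geometry"))
  if (series$stock_signal <= 0) stop("stock signal must be positive",
                                     call. = FALSE)
  if (stock_concentration <= 0) stop("'stock_concentration' must be positive",
                                     call. = FALSE)
  conc_nmol_ul <- stock_concentration * 1e-3
  area_mm2 <- geometry$insert_area * 100
  sum(series$baso_signal / series$stock_signal * conc_nmol_ul *
        geometry$basolateral_volume) / area_mm2
}
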