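#' Area-corrected TEER
#'
#' Transepithelial electrical resistance, blank-corrected and normalised
#' to the membrane area: `(raw - blank) * area`. Negative values (raw
#' below the bare-insert resistance) are returned as computed so callers
#' can flag them; [filter_teer_threshold()] never includes them.
#'
#' @param raw Measured resistance of the cell-covered insert, Ohm.
#' @param blank Resistance of a bare insert, Ohm.
#' @param area Membrane area, cm^2.
#' @return TEER in Ohm x cm^2. Vectorised.
#' @examples
#' teer_area_corrected(350, 120, 0.336)  # 77.28
#' @export
teer_area_corrected <- function(raw, blank, area) {
  if (any(area <= 0)) stop("'area' must be positive", call. = FALSE)
  (raw - blank) * area
}

#' Barrier-integrity inclusion filter
#'
#' Keeps records whose start-of-experiment TEER meets the inclusion
#' threshold (boundary inclusive: a layer at exactly the threshold is
#' included). The default threshold of 100 Ohm x cm^2 is the study's
#' reproducibility criterion.
#'
#' @param records Data frame with columns `well_id` and `teer_start`
#'   (Ohm x cm^2).
#' @param threshold Minimum start TEER, Ohm x cm^2.
#' @return The included rows, with the excluded rows attached as attribute
#'   `"excluded"` (the exclusion log).
#' @export
filter_teer_threshold <- function(records, threshold = 100) {
  if (!nrow(records)) {
    attr(records, "excluded") <- records
    return(records)
  }
  keep <- !is.na(records$teer_start) & records$teer_start >= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded") <- records[!keep, , drop = FALSE]
  out
}

#' TEER table processing
#'
#' Computes area-corrected TEER from raw/blank resistances, reshapes to
#' one row per insert with `teer_start` and `teer_48h`, and applies the
#' inclusion filter on the start value.
#'
#' @param teer_table Data frame as produced by [simulate_teer_study()]:
#'   columns `well_id, treatment, timepoint` (`"start"`/`"48h"`),
#'   `raw_resistance, blank_resistance, area`.
#' @param threshold Inclusion threshold in Ohm x cm^2.
#' @return Included per-insert rows (columns `well_id, treatment,
#'   teer_start, teer_48h`) with the exclusion log as attribute
#'   `"excluded"`.
#' @export
process_teer <- function(teer_table, threshold = 100) {
  teer_table$teer <- teer_area_corrected(
    teer_table$raw_resistance, teer_table$blank_resistance, teer_table$area)
  wide <- stats::reshape(
    teer_table[, c("well_id", "treatment", "timepoint", "teer")],
    direction = "wide", idvar = c("well_id", "treatment"),
    timevar = "timepoint")
  names(wide) <- sub("^teer\\.48h$", "teer_48h",
                     sub("^teer\\.start$", "teer_start", names(wide)))
  rownames(wide) <- NULL
  filter_teer_threshold(wide, threshold)
}

#' Relative qPCR expression (2^-dCt, normalised to a reference group)
#'
#' Per sample, `2^-(Ct_target - Ct_reference)`; each target's values are
#' then divided by the mean of that quantity in the reference treatment
#' group (the cytokine-treated group in the inflammation study), so the
#' reference group averages exactly 1 per target.
#'
#' @param samples Data frame with columns `target, treatment, ct_target,
#'   ct_reference` (and optionally `sample_id`).
#' @param reference_group Treatment label used as normaliser.
#' @return The input with added columns `expr_2dct` (2^-dCt) and
#'   `expr_rel` (normalised to the reference-group mean).
#' @export
relative_expression <- function(samples, reference_group = "INF") {
  need <- c("target", "treatment", "ct_target", "ct_reference")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(samples$ct_target)) ||
      any(!is.finite(samples$ct_reference))) {
    stop("Ct values must be finite (missing 18S rRNA pairing?)",
         call. = FALSE)
  }
  samples$expr_2dct <- 2^(-(samples$ct_target - samples$ct_reference))
  samples$expr_rel <- NA_real_
  for (tg in unique(samples$target)) {
    sel <- samples$target == tg
    ref <- samples$expr_2dct[sel & samples$treatment == reference_group]
    if (!length(ref)) {
      stop("reference group '", reference_group, "' is empty for target ",
           tg, call. = FALSE)
    }
    samples$expr_rel[sel] <- samples$expr_2dct[sel] / mean(ref)
  }
  samples
}
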