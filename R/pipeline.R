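#' Run the clearance-to-Papp pipeline over a study
#'
#' For every well series: interval clearance, cleared-volume slope
#' (`PS_all`). Blank inserts are averaged per compound x inhibitor x
#' channel group; each cells well is then blank-corrected to `PS_cell`
#' (series-resistance), converted to Papp (um/min) and normalised to the
#' carboxyfluorescein series of the same insert. Wells with non-positive
#' slopes are flagged `excluded`, wells whose `PS_all` reaches the blank
#' mean are flagged `blank_dominated`; neither contributes to group means,
#' and both are counted in the exclusion log.
#'
#' @param study A [study_table()].
#' @param mode Clearance correction mode (see [interval_clearance()]).
#' @param cf_normalize `"per_insert"` (default) or `"group_mean"`.
#' @param stock_concentrations Named numeric vector of donor
#'   concentrations in uM per compound, used for cumulated amounts
#'   (default: 10 for `CF`, 100 otherwise).
#' @return List of class `perm_report`: `per_well`, `groups` (means +/- SD
#'   and SEM, n), `folds` (inhibitor vs. no-inhibitor ratios of group
#'   means per compound), `exclusions`.
#' @export
run_permeability <- function(study, mode = "per_interval",
                             cf_normalize = c("per_insert", "group_mean"),
                             stock_concentrations = NULL) {
  cf_normalize <- match.arg(cf_normalize)
  stopifnot(inherits(study, "study_table"))
  if (!length(study$wells)) {
    warning("empty study: nothing to compute", call. = FALSE)
    empty <- data.frame()
    return(structure(list(per_well = empty, groups = empty, folds = empty,
                          exclusions = empty), class = "perm_report"))
  }
  geom <- study$geometry

  per_well <- do.call(rbind, lapply(unname(study$wells), function(w) {
    cc <- interval_clearance(w, geom, mode)
    fit <- fit_ps(cc)
    conc <- if (!is.null(stock_concentrations) &&
                w$compound %in% names(stock_concentrations)) {
      stock_concentrations[[w$compound]]
    } else if (w$compound == "CF") 10 else 100
    data.frame(
      well_id = w$well_id, channel = w$channel, role = w$role,
      compound = w$compound, inhibitor = w$inhibitor,
      treatment = w$treatment,
      ps_all = fit$ps, intercept = fit$intercept, r_squared = fit$r_squared,
      cumulated_nmol_mm2 = cumulated_amount(w, geom, conc),
      flag = fit$flag, stringsAsFactors = FALSE
    )
  }))

  # mean blank PS per compound x inhibitor x channel (ok wells only)
  bl <- per_well[per_well$role == "blank" & per_well$flag == "ok", ]
  blank_key <- function(df) paste(df$compound, df$inhibitor, df$channel,
                                  sep = "|")
  blank_means <- tapply(bl$ps_all, blank_key(bl), mean)

  per_well$ps_blank <- NA_real_
  per_well$ps_cell <- NA_real_
  per_well$papp <- NA_real_
  is_cells <- per_well$role == "cells"
  keys <- blank_key(per_well)
  for (i in which(is_cells & per_well$flag == "ok")) {
    pb <- blank_means[[keys[i]]]
    if (is.null(pb) || is.na(pb)) {
      per_well$flag[i] <- "no_blank"
      next
    }
    per_well$ps_blank[i] <- pb
    pc <- correct_blank(per_well$ps_all[i], pb)
    if (is.na(pc)) {
      per_well$flag[i] <- "blank_dominated"
    } else {
      per_well$ps_cell[i] <- pc
      per_well$papp[i] <- papp(pc, geom$insert_area)
    }
  }

  # per-insert CF normalisation
  per_well$papp_normalized <- NA_real_
  cf_rows <- per_well[per_well$compound == "CF" & is_cells, ]
  cf_lookup <- stats::setNames(cf_rows$papp, cf_rows$well_id)
  cf_group_mean <- mean(cf_rows$papp, na.rm = TRUE)
  for (i in which(is_cells & per_well$flag == "ok")) {
    if (per_well$compound[i] == "CF") {
      per_well$papp_normalized[i] <- 1
    } else if (cf_normalize == "per_insert") {
      cf <- unname(cf_lookup[per_well$well_id[i]])
      if (length(cf) == 1 && !is.na(cf)) {
        per_well$papp_normalized[i] <- per_well$papp[i] / cf
      }
    } else if (is.finite(cf_group_mean)) {
      per_well$papp_normalized[i] <- per_well$papp[i] / cf_group_mean
    }
  }

  ok_cells <- per_well[is_cells & per_well$flag == "ok", ]
  gkey <- paste(ok_cells$compound, ok_cells$inhibitor, ok_cells$treatment,
                sep = "|")
  groups <- do.call(rbind, lapply(split(ok_cells, gkey), function(d) {
    n <- nrow(d)
    data.frame(
      compound = d$compound[1], inhibitor = d$inhibitor[1],
      treatment = d$treatment[1], n = n,
      ps_all_mean = mean(d$ps_all), ps_cell_mean = mean(d$ps_cell),
      papp_mean = mean(d$papp), papp_sd = stats::sd(d$papp),
      papp_sem = stats::sd(d$papp) / sqrt(n),
      papp_norm_mean = mean(d$papp_normalized, na.rm = TRUE),
      papp_norm_sd = stats::sd(d$papp_normalized, na.rm = TRUE),
      cumulated_mean = mean(d$cumulated_nmol_mm2),
      cumulated_sd = stats::sd(d$cumulated_nmol_mm2),
      stringsAsFactors = FALSE
    )
  }))
  rownames(groups) <- NULL

  folds <- do.call(rbind, lapply(
    split(groups, paste(groups$compound, groups$treatment)), function(d) {
      ref <- d[d$inhibitor == "none", ]
      trt <- d[d$inhibitor != "none", ]
      if (!nrow(ref) || !nrow(trt)) return(NULL)
      data.frame(
        compound = trt$compound, treatment = trt$treatment,
        inhibitor = trt$inhibitor,
        fold = trt$papp_mean / ref$papp_mean[1],
        stringsAsFactors = FALSE
      )
    }))
  if (is.null(folds)) folds <- data.frame()
  rownames(folds) <- NULL

  exclusions <- per_well[per_well$flag != "ok",
                         c("well_id", "channel", "compound", "inhibitor",
                           "treatment", "role", "flag")]
  rownames(exclusions) <- NULL

  structure(list(per_well = per_well, groups = groups, folds = folds,
                 exclusions = exclusions, mode = mode),
            class = "perm_report")
}

#' @export
print.perm_report <- function(x, ...) {
  cat("Permeability report (", x$mode, " mode): ",
      nrow(x$per_well), " wells, ", nrow(x$groups), " groups, ",
      nrow(x$exclusions), " excluded\n", sep = "")
  if (nrow(x$groups)) {
    print(x$groups[, c("compound", "inhibitor", "treatment", "n",
                       "papp_mean", "papp_sd")], row.names = FALSE)
  }
  invisible(x)
}

#' Simulate a study and write its tables
#'
#' Generates a synthetic study ([generate_study()]) and writes the
#' measurement table (long schema, raw technical replicates), the
#' ground-truth table and a geometry/design echo under `out_dir`.
#'
#' @param design Design data frame (see [paper_mimic_design()]).
#' @param geometry An [experiment_geometry()].
#' @param seed Integer master seed (mandatory for reproducibility).
#' @param out_dir Output directory, created if needed. `NULL` skips
#'   writing.
#' @return The [generate_study()] bundle, with a `paths` element when
#'   files were written.
#' @export
run_simulate <- function(design, geometry = default_geometry(), seed,
                         out_dir = NULL) {
  sim <- generate_study(design, geometry, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      measurements = file.path(out_dir, "measurements.csv"),
      truth = file.path(out_dir, "truth.csv"),
      design = file.path(out_dir, "design.csv"),
      geometry = file.path(out_dir, "geometry.yaml")
    )
    utils::write.csv(sim$replicates, paths$measurements, row.names = FALSE,
                     na = "")
    utils::write.csv(sim$truth, paths$truth, row.names = FALSE)
    utils::write.csv(design, paths$design, row.names = FALSE)
    yaml::write_yaml(list(
      apical_volume = geometry$apical_volume,
      basolateral_volume = geometry$basolateral_volume,
      insert_area = geometry$insert_area,
      sampling_times = geometry$sampling_times,
      seed = seed
    ), paths$geometry)
    sim$paths <- paths
  }
  sim
}

#' Inflammation-study readouts: TEER, CF permeability context and qPCR
#'
#' Applies the TEER inclusion filter, runs the one-way ANOVA with
#' Holm-Sidak post hoc tests on the 48 h TEER values, computes relative
#' qPCR expression normalised to the cytokine-treated group, and runs the
#' two-way (treatment x target) ANOVA on the normalised expression.
#'
#' @param teer_table TEER table (see [process_teer()] for columns).
#' @param qpcr_table Ct table (see [relative_expression()] for columns).
#' @param threshold TEER inclusion threshold, Ohm x cm^2.
#' @param reference_group qPCR normaliser treatment group.
#' @return List with `teer` (included records + exclusion log attribute),
#'   `teer_anova`, `expression`, `expression_anova`.
#' @export
run_inflammation <- function(teer_table, qpcr_table, threshold = 100,
                             reference_group = "INF") {
  teer <- process_teer(teer_table, threshold)
  teer_anova <- group_anova(teer$teer_48h, teer$treatment, "one_way")
  expr <- relative_expression(qpcr_table, reference_group)
  expr_anova <- group_anova(expr$expr_rel,
                            list(expr$treatment, expr$target), "two_way")
  list(teer = teer, teer_anova = teer_anova,
       expression = expr, expression_anova = expr_anova)
}
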