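#!/usr/bin/env Rscript
# Clearance -> cleared-volume slope -> blank-corrected PS_cell -> Papp
# pipeline over the simulated study written by 01_simulate_study.R,
# with recovery of the known ground truth, inhibitor fold-changes,
# CF-normalised permeabilities and a comparison of the three interval
# correction modes.

library(clearperm)

in_dir <- "results/sim_study"
out_dir <- "results/permeability"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
if (!file.exists(file.path(in_dir, "measurements.csv"))) {
  stop("run analysis/01_simulate_study.R first")
}

geom <- read_experiment_config(file.path(in_dir, "geometry.yaml"))
study <- read_timecourse_table(file.path(in_dir, "measurements.csv"), geom)
truth <- read.csv(file.path(in_dir, "truth.csv"))

report <- run_permeability(study, mode = "per_interval")
write_results_table(report, file.path(out_dir, "results.csv"))
write.csv(report$folds, file.path(out_dir, "fold_changes.csv"),
          row.names = FALSE)

truth_groups <- aggregate(papp_true ~ compound + inhibitor,
                          truth[truth$role == "cells", ], mean)
recov <- merge(report$groups, truth_groups, by = c("compound", "inhibitor"))
recov$rel_err_pct <- 100 * (recov$papp_mean - recov$papp_true) /
  recov$papp_true
write.csv(recov, file.path(out_dir, "recovery.csv"), row.names = FALSE)

cat("Papp group means (um/min, mean +/- SD) vs truth:\n")
print(recov[order(recov$compound, recov$inhibitor),
            c("compound", "inhibitor", "n", "papp_mean", "papp_sd",
              "papp_true", "rel_err_pct")], row.names = FALSE, digits = 3)
cat(sprintf("\nmax |relative error| %.1f%%; %d wells excluded\n",
            max(abs(recov$rel_err_pct)), nrow(report$exclusions)))

ni <- recov[recov$inhibitor == "none" &
              recov$compound %in% c("celecoxib", "diclofenac", "ibuprofen",
                                    "piroxicam"), ]
cat("NSAID transport ranking:",
    paste(ni$compound[order(-ni$papp_mean)], collapse = " > "), "\n")
cat("\nInhibitor fold-changes (ratio of group means):\n")
print(report$folds[report$folds$compound != "CF", ], row.names = FALSE,
      digits = 3)

# correction-mode comparison: bias of each mode against ground truth
mode_bias <- do.call(rbind, lapply(
  c("per_interval", "literal", "donor_corrected"), function(md) {
    g <- run_permeability(study, mode = md)$groups
    r <- merge(g, truth_groups, by = c("compound", "inhibitor"))
    data.frame(mode = md,
               mean_bias_pct = mean(100 * (r$papp_mean - r$papp_true) /
                                      r$papp_true),
               max_abs_bias_pct = max(abs(100 * (r$papp_mean - r$papp_true) /
                                            r$papp_true)))
  }))
write.csv(mode_bias, file.path(out_dir, "mode_bias.csv"), row.names = FALSE)
cat("\nInterval-correction mode bias (all groups):\n")
print(mode_bias, row.names = FALSE, digits = 3)

# figures: cleared-volume curves (ibuprofen) and group Papp bars
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create(file.path(out_dir, "figures"), showWarnings = FALSE)
  ibu <- Filter(function(w) w$compound == "ibuprofen" &&
                  w$inhibitor == "none", study$wells)
  curves <- do.call(rbind, lapply(ibu, function(w) {
    cc <- interval_clearance(w, geom)
    data.frame(well_id = w$well_id, role = w$role, time = cc$times,
               cleared = cc$cumulative)
  }))
  p1 <- ggplot(curves, aes(time, cleared, group = well_id, colour = role)) +
    geom_line() + geom_point() +
    labs(x = "time [min]", y = "cleared volume [uL]",
         title = "Ibuprofen cleared-volume curves (cells vs. blank)") +
    theme_minimal()
  ggsave(file.path(out_dir, "figures", "cleared_volume_ibuprofen.png"),
         p1, width = 6, height = 4, dpi = 150)

  g <- report$groups[report$groups$compound != "CF", ]
  p2 <- ggplot(g, aes(compound, papp_mean, fill = inhibitor)) +
    geom_col(position = position_dodge()) +
    geom_errorbar(aes(ymin = papp_mean - papp_sem,
                      ymax = papp_mean + papp_sem),
                  position = position_dodge(0.9), width = 0.3) +
    labs(y = "Papp [um/min]", x = NULL,
         title = "Group permeability coefficients (mean +/- SEM)") +
    theme_minimal()
  ggsave(file.path(out_dir, "figures", "papp_groups.png"),
         p2, width = 7, height = 4, dpi = 150)
  cat("\nwrote figures under", file.path(out_dir, "figures"), "\n")
}
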