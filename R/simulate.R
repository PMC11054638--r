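#' Simulation parameters for one replicate group
#'
#' Transport across a cell-covered insert is modelled as two linear
#' barriers in series: the cell layer with an effective PS
#' `inflammation_scaler * ps_cell_passive + ps_active * (1 - inhibitor_efficacy * inhibited)`
#' and the bare membrane with `ps_blank`. `ps_active` is a linear
#' carrier-mediated term (negative values model net apical efflux) that an
#' inhibitor abolishes by the fraction `inhibitor_efficacy`; a saturable
#' Michaelis-Menten option is deliberately not modelled since only one
#' donor concentration is in scope. Blank inserts transport with
#' `ps_blank` alone.
#'
#' @param ps_cell_passive Passive cell-layer PS, uL/min (>= 0).
#' @param ps_active Carrier-mediated PS term, uL/min (sign allows efflux).
#' @param inhibitor_efficacy Fraction of `ps_active` abolished when an
#'   inhibitor is present, in \[0, 1\].
#' @param ps_blank Bare-membrane PS, uL/min (> 0).
#' @param donor_concentration Applied apical concentration, uM.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (Gaussian on CV, truncated at zero).
#' @param signal_per_concentration Detector response, signal units per uM.
#' @param inflammation_scaler Multiplier on the passive (paracellular)
#'   term for cytokine-treated wells (> 1 models barrier breakdown).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(ps_cell_passive, ps_active = 0, inhibitor_efficacy = 1,
                       ps_blank, donor_concentration = 100, noise_cv = 0.03,
                       signal_per_concentration = 10,
                       inflammation_scaler = 1) {
  stopifnot(ps_cell_passive >= 0, ps_blank > 0,
            inhibitor_efficacy >= 0, inhibitor_efficacy <= 1,
            noise_cv >= 0, donor_concentration > 0,
            signal_per_concentration > 0, inflammation_scaler > 0)
  structure(list(
    ps_cell_passive = ps_cell_passive, ps_active = ps_active,
    inhibitor_efficacy = inhibitor_efficacy, ps_blank = ps_blank,
    donor_concentration = donor_concentration, noise_cv = noise_cv,
    signal_per_concentration = signal_per_concentration,
    inflammation_scaler = inflammation_scaler
  ), class = "sim_params")
}

#' Compose cell-layer and membrane PS into a whole-insert PS
#'
#' The composition direction of the blank correction:
#' `1/PS_all = 1/ps_cell_effective + 1/ps_blank`.
#'
#' @param ps_cell_effective Cell-layer PS, uL/min (> 0).
#' @param ps_blank Bare-membrane PS, uL/min (> 0).
#' @return `PS_all` in uL/min. Vectorised.
#' @export
series_ps <- function(ps_cell_effective, ps_blank) {
  if (any(ps_cell_effective <= 0) || any(ps_blank <= 0)) {
    stop("both PS values must be positive", call. = FALSE)
  }
  1 / (1 / ps_cell_effective + 1 / ps_blank)
}

#' Exact one-interval solution of the two-compartment model
#'
#' Solves `dCa/dt = -(PS/Va)(Ca - Cb)`, `dCb/dt = +(PS/Vb)(Ca - Cb)` in
#' closed form. With `k = PS (Va + Vb) / (Va Vb)` the concentration
#' difference decays as `exp(-k t)` while total mass is conserved, so both
#' compartments relax exponentially to the equilibrium partition
#' `(Ca0 Va + Cb0 Vb) / (Va + Vb)`.
#'
#' @param Ca0,Cb0 Start-of-interval apical/basolateral concentrations (uM).
#'   The protocol resets `Cb0 = 0` at each sampling (fresh receiver).
#' @param ps_all Whole-insert PS, uL/min (>= 0).
#' @param geometry An [experiment_geometry()].
#' @param dt Interval length in minutes (> 0).
#' @return Named numeric vector `c(Ca = , Cb = )` at the end of the interval.
#' @export
simulate_interval <- function(Ca0, Cb0, ps_all, geometry, dt) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (ps_all < 0) stop("'ps_all' must be non-negative", call. = FALSE)
  va <- geometry$apical_volume
  vb <- geometry$basolateral_volume
  ceq <- (Ca0 * va + Cb0 * vb) / (va + vb)
  k <- ps_all * (va + vb) / (va * vb)
  decay <- exp(-k * dt)
  c(Ca = ceq + (Ca0 - ceq) * decay, Cb = ceq + (Cb0 - ceq) * decay)
}

#' Simulate one insert's full sampling schedule
#'
#' Chains [simulate_interval()] over the sampling schedule, resetting the
#' receiver concentration to zero at every sampling (full basolateral media
#' replacement) while the donor concentration carries over. Concentrations
#' are converted to detector signals and measured as noisy technical
#' replicates (triplicate basolateral and stock, duplicate end-of-run
#' apical samples); the emitted [well_series()] holds the replicate means,
#' mirroring what a plate export would contain.
#'
#' @param params A [sim_params()].
#' @param geometry An [experiment_geometry()].
#' @param labels List with `well_id`, `role` (`"cells"`/`"blank"`),
#'   `compound`, `inhibitor`, `treatment`, `channel`.
#' @param seed Integer seed for this well's noise draws.
#' @return List of class `simulated_well` with elements `series` (the
#'   [well_series()]), `replicates` (long-format data frame of raw
#'   replicate rows), `trajectory` (true concentrations per interval),
#'   `truth` (list: `ps_cell_effective`, `ps_all`, `papp_true` in um/min —
#'   `NA` for blanks — and `mass_error`, the relative mass-balance error).
#' @export
simulate_well <- function(params, geometry, labels, seed) {
  stopifnot(inherits(params, "sim_params"),
            inherits(geometry, "experiment_geometry"))
  inhibited <- !is.null(labels$inhibitor) && labels$inhibitor != "none"
  if (identical(labels$role, "blank")) {
    ps_cell_eff <- NA_real_
    ps_all <- params$ps_blank
  } else {
    ps_cell_eff <- params$inflammation_scaler * params$ps_cell_passive +
      params$ps_active * (1 - params$inhibitor_efficacy * inhibited)
    if (ps_cell_eff <= 0) {
      stop("effective cell PS must be positive (check ps_active sign)",
           call. = FALSE)
    }
    ps_all <- series_ps(ps_cell_eff, params$ps_blank)
  }

  times <- geometry$sampling_times
  dts <- diff(c(0, times))
  va <- geometry$apical_volume
  vb <- geometry$basolateral_volume
  ca <- params$donor_concentration
  cb_end <- numeric(length(times))
  ca_end <- numeric(length(times))
  removed <- 0
  for (i in seq_along(dts)) {
    st <- simulate_interval(ca, 0, ps_all, geometry, dts[i])
    ca <- unname(st["Ca"])
    cb_end[i] <- unname(st["Cb"])
    ca_end[i] <- ca
    removed <- removed + cb_end[i] * vb
  }
  total0 <- params$donor_concentration * va
  mass_error <- abs(ca * va + removed - total0) / total0

  spc <- params$signal_per_concentration
  noisy <- function(true_signal, n_rep) {
    true_signal * pmax(0, 1 + stats::rnorm(n_rep, 0, params$noise_cv))
  }
  set.seed(seed)
  rep_rows <- list()
  add_rows <- function(sample_type, time_min, values) {
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      well_id = labels$well_id, role = labels$role,
      compound = labels$compound, inhibitor = labels$inhibitor,
      treatment = labels$treatment, channel = labels$channel,
      sample_type = sample_type, time_min = time_min,
      replicate = seq_along(values), signal = values,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(times)) {
    add_rows("baso", times[i], noisy(cb_end[i] * spc, 3))
  }
  add_rows("stock", NA, noisy(params$donor_concentration * spc, 3))
  add_rows("apical_end", NA, noisy(ca * spc, 2))
  replicates <- do.call(rbind, rep_rows)

  mean_of <- function(type, tt = NULL) {
    sel <- replicates$sample_type == type
    if (!is.null(tt)) sel <- sel & replicates$time_min == tt
    mean(replicates$signal[sel])
  }
  series <- well_series(
    well_id = labels$well_id, role = labels$role, compound = labels$compound,
    inhibitor = labels$inhibitor, treatment = labels$treatment,
    channel = labels$channel,
    baso_signal = vapply(times, function(tt) mean_of("baso", tt), numeric(1)),
    stock_signal = mean_of("stock"),
    apical_end_signal = mean_of("apical_end")
  )
  structure(list(
    series = series, replicates = replicates,
    trajectory = data.frame(time = times, Ca_end = ca_end, Cb_end = cb_end),
    truth = list(
      ps_cell_effective = ps_cell_eff, ps_all = ps_all,
      papp_true = if (is.na(ps_cell_eff)) NA_real_
                  else 10 * ps_cell_eff / geometry$insert_area,
      mass_error = mass_error
    )
  ), class = "simulated_well")
}

# deterministic seed below 2^31 from a master seed and a well identity
# (polynomial rolling hash; doubles stay exact well below 2^53)
well_seed <- function(master, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  (h + (as.numeric(master) %% 2147483647) * 48271) %% 2147483646 + 1
}

#' Study design mimicking the published transport experiment
#'
#' One row per assay group. The four NSAIDs are crossed with
#' {none, verapamil, probenecid}; the paracellular marker
#' carboxyfluorescein (CF) and transcellular marker diazepam are run
#' without inhibitor, giving 14 groups. Effective cell-layer PS values are
#' set so the ground-truth Papp equals the published group means (um/min):
#' CF 4.63, diazepam 11.90; celecoxib 0.44/2.10/12.74,
#' diclofenac 3.64/3.54/6.66, ibuprofen 5.77/7.13/7.87,
#' piroxicam 4.86/6.00/5.81 for none/verapamil/probenecid. CF is
#' additionally co-applied on every insert (10 uM, RFU channel) at the
#' control CF permeability.
#'
#' @param n_cells Cell-covered inserts per group.
#' @param n_blank Blank inserts per group.
#' @param blank_factor Bare-membrane PS as a multiple of the group's cell
#'   PS.
#' @param noise_cv Measurement noise CV passed to every group.
#' @return A data frame, one row per group, consumable by
#'   [generate_study()].
#' @export
paper_mimic_design <- function(n_cells = 6, n_blank = 3, blank_factor = 3,
                               noise_cv = 0.03) {
  papp_tab <- rbind(
    data.frame(compound = "CF", inhibitor = "none", papp = 4.63,
               channel = "RFU", donor = 10, spc = 100),
    data.frame(compound = "diazepam", inhibitor = "none", papp = 11.90,
               channel = "mAU_min", donor = 100, spc = 0.5),
    expand.grid(compound = c("celecoxib", "diclofenac", "ibuprofen",
                             "piroxicam"),
                inhibitor = c("none", "verapamil", "probenecid"),
                stringsAsFactors = FALSE) |>
      transform(papp = c(0.44, 3.64, 5.77, 4.86,     # none
                         2.10, 3.54, 7.13, 6.00,     # verapamil
                         12.74, 6.66, 7.87, 5.81),   # probenecid
                channel = "mAU_min", donor = 100, spc = 0.5)
  )
  area <- default_geometry()$insert_area
  ps_cell <- papp_tab$papp * area / 10
  cf_ps_cell <- 4.63 * area / 10
  data.frame(
    compound = papp_tab$compound, inhibitor = papp_tab$inhibitor,
    treatment = "n/a", channel = papp_tab$channel,
    n_cells = n_cells, n_blank = n_blank,
    ps_cell_passive = ps_cell, ps_active = 0, inhibitor_efficacy = 0,
    ps_blank = blank_factor * ps_cell,
    donor_concentration = papp_tab$donor,
    signal_per_concentration = papp_tab$spc,
    noise_cv = noise_cv, inflammation_scaler = 1,
    cf_ps_cell = ifelse(papp_tab$compound == "CF", NA, cf_ps_cell),
    cf_ps_blank = ifelse(papp_tab$compound == "CF", NA,
                         blank_factor * cf_ps_cell),
    stringsAsFactors = FALSE
  )
}

design_defaults <- function(design) {
  defaults <- list(treatment = "n/a", channel = "mAU_min",
                   n_cells = 6L, n_blank = 3L,
                   ps_active = 0, inhibitor_efficacy = 0,
                   donor_concentration = 100, signal_per_concentration = 0.5,
                   noise_cv = 0.03, inflammation_scaler = 1,
                   cf_ps_cell = NA_real_, cf_ps_blank = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(design[[nm]])) design[[nm]] <- defaults[[nm]]
  }
  design
}

#' Generate a full synthetic study with known ground truth
#'
#' Simulates every group of `design` (cells and matched blank inserts;
#' carboxyfluorescein co-applied on each insert when `cf_ps_cell` is set)
#' with per-well seeds drawn once from `seed`, so the output is
#' deterministic and independent of generation order.
#'
#' @param design Data frame, one row per group, with columns
#'   `compound, inhibitor, ps_cell_passive, ps_blank` and optionally
#'   `treatment, channel, n_cells, n_blank, ps_active, inhibitor_efficacy,
#'   donor_concentration, signal_per_concentration, noise_cv,
#'   inflammation_scaler, cf_ps_cell, cf_ps_blank` (see
#'   [paper_mimic_design()] for the defaults).
#' @param geometry An [experiment_geometry()].
#' @param seed Integer master seed.
#' @return List with `study` (a [study_table()]), `truth` (data frame of
#'   per-well ground truth: `papp_true`, `ps_all_true`, `mass_error`),
#'   and `replicates` (raw replicate rows in the long measurement schema).
#' @export
generate_study <- function(design, geometry = default_geometry(), seed = 1) {
  design <- design_defaults(design)
  # enumerate every well series up-front so seeds attach to positions
  specs <- list()
  for (g in seq_len(nrow(design))) {
    row <- design[g, ]
    grp_id <- paste(row$compound, row$inhibitor, row$treatment, sep = "_")
    grp_id <- gsub("[^A-Za-z0-9_+]+", "-", grp_id)
    for (role in c("cells", "blank")) {
      n <- if (role == "cells") row$n_cells else row$n_blank
      for (i in seq_len(n)) {
        wid <- paste(grp_id, role, i, sep = "_")
        specs[[length(specs) + 1L]] <- list(
          row = row, role = role, well_id = wid, cf = FALSE)
        if (!is.na(row$cf_ps_cell)) {
          specs[[length(specs) + 1L]] <- list(
            row = row, role = role, well_id = wid, cf = TRUE)
        }
      }
    }
  }
  if (!length(specs)) stop("empty design", call. = FALSE)
  ids <- vapply(specs, function(s)
    paste(s$well_id, if (s$cf) "RFU" else s$row$channel), character(1))
  if (anyDuplicated(ids)) stop("duplicate well ids in design", call. = FALSE)

  # per-well seeds derive from the master seed and the well identity, so
  # wells are independent and generation order is irrelevant
  well_seeds <- vapply(ids, function(id) well_seed(seed, id), numeric(1))

  sims <- lapply(seq_along(specs), function(j) {
    s <- specs[[j]]
    row <- s$row
    if (s$cf) {
      p <- sim_params(
        ps_cell_passive = row$cf_ps_cell, ps_active = 0,
        inhibitor_efficacy = 0, ps_blank = row$cf_ps_blank,
        donor_concentration = 10, noise_cv = row$noise_cv,
        signal_per_concentration = 100,
        inflammation_scaler = row$inflammation_scaler
      )
      labels <- list(well_id = s$well_id, role = s$role, compound = "CF",
                     inhibitor = row$inhibitor, treatment = row$treatment,
                     channel = "RFU")
    } else {
      p <- sim_params(
        ps_cell_passive = row$ps_cell_passive, ps_active = row$ps_active,
        inhibitor_efficacy = row$inhibitor_efficacy, ps_blank = row$ps_blank,
        donor_concentration = row$donor_concentration,
        noise_cv = row$noise_cv,
        signal_per_concentration = row$signal_per_concentration,
        inflammation_scaler = row$inflammation_scaler
      )
      labels <- list(well_id = s$well_id, role = s$role,
                     compound = row$compound, inhibitor = row$inhibitor,
                     treatment = row$treatment, channel = row$channel)
    }
    simulate_well(p, geometry, labels, seed = well_seeds[j])
  })

  truth <- do.call(rbind, lapply(sims, function(sw) {
    w <- sw$series
    data.frame(well_id = w$well_id, channel = w$channel, role = w$role,
               compound = w$compound, inhibitor = w$inhibitor,
               treatment = w$treatment,
               ps_cell_true = sw$truth$ps_cell_effective,
               ps_all_true = sw$truth$ps_all,
               papp_true = sw$truth$papp_true,
               mass_error = sw$truth$mass_error,
               stringsAsFactors = FALSE)
  }))
  replicates <- do.call(rbind, lapply(sims, function(sw) sw$replicates))
  rownames(truth) <- rownames(replicates) <- NULL
  list(study = study_table(geometry, lapply(sims, function(sw) sw$series)),
       truth = truth, replicates = replicates)
}

#' Synthetic TEER table for the inflammation study
#'
#' Emulates the 48 h cytokine-treatment experiment: start-of-experiment
#' TEER around 130 +/- 20 Ohm x cm^2 for every group, and 48 h TEER at the
#' published group means (control 77.10 +/- 15.25, Ibu 69.65 +/- 9.10,
#' INF 45.30 +/- 5.10, INF+Ibu 49.16 +/- 14.51 Ohm x cm^2). Rows carry the
#' raw and blank-insert resistances from which the area-corrected TEER is
#' recomputed downstream.
#'
#' @param n Inserts per treatment group.
#' @param seed Integer seed.
#' @param blank_resistance Bare-insert resistance in Ohm.
#' @param area Insert area in cm^2.
#' @return Data frame with columns `well_id, treatment, timepoint,
#'   raw_resistance, blank_resistance, area`.
#' @export
simulate_teer_study <- function(n = 15, seed = 1, blank_resistance = 120,
                                area = 0.336) {
  groups <- c(control = 77.10, Ibu = 69.65, INF = 45.30, `INF+Ibu` = 49.16)
  sds <- c(control = 15.25, Ibu = 9.10, INF = 5.10, `INF+Ibu` = 14.51)
  set.seed(seed)
  rows <- list()
  for (g in names(groups)) {
    start_teer <- stats::rnorm(n, 130, 20)
    end_teer <- pmax(stats::rnorm(n, groups[[g]], sds[[g]]), 1)
    for (i in seq_len(n)) {
      wid <- paste0(gsub("[^A-Za-z]+", "", g), "_", i)
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = wid, treatment = g,
        timepoint = c("start", "48h"),
        raw_resistance = c(start_teer[i], end_teer[i]) / area +
          blank_resistance,
        blank_resistance = blank_resistance, area = area,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic qPCR Ct table for the inflammation study
#'
#' Generates Ct values for the inflammation targets (JAK1 transcript
#' variants a/b/c, TRAF2 b/c, RELA) against the 18S rRNA reference in the
#' four treatment groups. Cytokine groups (INF, INF+Ibu) are upregulated
#' `inf_fold`-fold relative to control; for RELA the ibuprofen co-treatment
#' halves the upregulation, mirroring its partial block of the NF-kB arm.
#'
#' @param n Biological samples per group.
#' @param seed Integer seed.
#' @param inf_fold Fold upregulation of cytokine-treated groups.
#' @param sd_ct Gaussian Ct noise (cycles).
#' @return Data frame with columns `sample_id, target, treatment,
#'   ct_target, ct_reference`.
#' @export
simulate_qpcr_study <- function(n = 3, seed = 1, inf_fold = 4, sd_ct = 0.3) {
  targets <- c(JAK1tva = 14, JAK1tvb = 15, JAK1tvc = 16,
               TRAF2tvb = 13, TRAF2tvc = 14, RELA = 12)  # base dCt vs 18S
  groups <- c("control", "INF", "INF+Ibu", "Ibu")
  set.seed(seed)
  rows <- list()
  for (tg in names(targets)) {
    for (g in groups) {
      fold <- switch(g, control = 1, Ibu = 1, INF = inf_fold,
                     `INF+Ibu` = if (tg == "RELA") inf_fold / 2 else inf_fold)
      ct_ref <- stats::rnorm(n, 10, 0.2)
      dct <- targets[[tg]] - log2(fold) + stats::rnorm(n, 0, sd_ct)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(tg, "_", gsub("[^A-Za-z]+", "", g), "_",
                           seq_len(n)),
        target = tg, treatment = g,
        ct_target = ct_ref + dct, ct_reference = ct_ref,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
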