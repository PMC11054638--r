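#' One insert's time course in one detection channel
#'
#' Holds the per-interval basolateral signals of a single insert (one value
#' per sampling time, each measured in a fresh receiver compartment), the
#' signal of the applied apical stock solution, and the grouping labels.
#' Signals are relative fluorescence units (`RFU`, carboxyfluorescein) or
#' HPLC peak areas in mAU x min (`mAU_min`, NSAIDs and diazepam); the
#' clearance calculation only ever uses their ratio.
#'
#' @param well_id Insert identifier. The same insert may appear once per
#'   detection channel (carboxyfluorescein is co-applied on every insert).
#' @param role `"cells"` (cell-covered insert) or `"blank"` (bare membrane).
#' @param compound Compound label (e.g. `"CF"`, `"diazepam"`, `"ibuprofen"`).
#' @param inhibitor `"none"`, `"verapamil"` or `"probenecid"`.
#' @param treatment Treatment-group label (`"control"`, `"INF"`,
#'   `"INF+Ibu"`, `"Ibu"`, or `"n/a"` for the plain transport study).
#' @param channel `"RFU"` or `"mAU_min"`.
#' @param baso_signal Numeric vector of basolateral signals, one per
#'   sampling time, all non-negative.
#' @param stock_signal Positive signal of the applied apical stock solution.
#' @param apical_end_signal Optional end-of-run apical signal (stored for
#'   QC; not used by the default calculations).
#'
#' @return An object of class `well_series`.
#' @export
well_series <- function(well_id, role, compound, inhibitor = "none",
                        treatment = "n/a", channel, baso_signal, stock_signal,
                        apical_end_signal = NA_real_) {
  role <- match.arg(role, c("cells", "blank"))
  baso_signal <- as.numeric(baso_signal)
  if (anyNA(baso_signal) || any(baso_signal < 0)) {
    stop("'baso_signal' must be non-negative and complete (well ",
         well_id, ")", call. = FALSE)
  }
  if (!is.numeric(stock_signal) || length(stock_signal) != 1 ||
      is.na(stock_signal) || stock_signal <= 0) {
    stop("'stock_signal' must be a single positive number (well ",
         well_id, ")", call. = FALSE)
  }
  structure(
    list(
      well_id = as.character(well_id), role = role,
      compound = as.character(compound), inhibitor = as.character(inhibitor),
      treatment = as.character(treatment), channel = as.character(channel),
      baso_signal = baso_signal, stock_signal = as.numeric(stock_signal),
      apical_end_signal = as.numeric(apical_end_signal)
    ),
    class = "well_series"
  )
}

#' Assemble a study table from wells and a geometry
#'
#' Validates that every series has one basolateral signal per sampling time
#' and that every cells replicate group (compound x inhibitor x channel) has
#' a matching blank group, as required by the series-resistance blank
#' correction.
#'
#' @param geometry An [experiment_geometry()].
#' @param wells A list of [well_series()] objects.
#' @return An object of class `study_table`.
#' @export
study_table <- function(geometry, wells) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  if (!length(wells)) {
    return(structure(list(geometry = geometry, wells = list()),
                     class = "study_table"))
  }
  ok <- vapply(wells, inherits, logical(1), what = "well_series")
  if (!all(ok)) stop("all 'wells' must be well_series objects", call. = FALSE)
  nt <- length(geometry$sampling_times)
  for (w in wells) {
    if (length(w$baso_signal) != nt) {
      stop("well ", w$well_id, " [", w$channel, "] has ",
           length(w$baso_signal), " basolateral values but the schedule has ",
           nt, " sampling times", call. = FALSE)
    }
  }
  key <- vapply(wells, function(w)
    paste(w$compound, w$inhibitor, w$channel, sep = "|"), character(1))
  roles <- vapply(wells, function(w) w$role, character(1))
  cells_keys <- unique(key[roles == "cells"])
  blank_keys <- unique(key[roles == "blank"])
  missing <- setdiff(cells_keys, blank_keys)
  if (length(missing)) {
    stop("no matching blank group for cells group(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  names(wells) <- vapply(wells, function(w)
    paste(w$well_id, w$channel, sep = "."), character(1))
  if (anyDuplicated(names(wells))) {
    stop("duplicate well id/channel combination: ",
         paste(unique(names(wells)[duplicated(names(wells))]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(geometry = geometry, wells = wells), class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study table:", length(x$wells), "well series,",
      length(x$geometry$sampling_times), "sampling times\n")
  invisible(x)
}

# Long-format column dictionary for measurement tables:
#   well_id     insert identifier
#   role        cells | blank
#   compound    compound label
#   inhibitor   none | verapamil | probenecid
#   treatment   control | INF | INF+Ibu | Ibu | n/a
#   channel     RFU | mAU_min
#   sample_type baso | stock | apical_end
#   time_min    sampling time for baso rows, empty otherwise
#   replicate   technical replicate index (averaged on read)
#   signal      measured value (RFU or mAU x min)
TIMECOURSE_COLUMNS <- c("well_id", "role", "compound", "inhibitor",
                        "treatment", "channel", "sample_type", "time_min",
                        "replicate", "signal")

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a measurement table into a study table
#'
#' Reads a delimited text file (comma or tab, auto-detected). The canonical
#' layout is long format with the columns documented in the package source
#' (`well_id, role, compound, inhibitor, treatment, channel, sample_type,
#' time_min, replicate, signal`); technical replicates (triplicate
#' basolateral/stock, duplicate apical samples) are averaged to a single
#' value per cell, with the raw replicate table retained as the
#' `"replicates"` attribute for QC. A wide layout (one row per well with
#' columns `stock` and `t<minutes>`) is also accepted.
#'
#' @param path Path to a CSV/TSV file.
#' @param geometry An [experiment_geometry()] describing the schedule.
#' @return A [study_table()] (with attribute `"replicates"` in long format).
#' @export
read_timecourse_table <- function(path, geometry) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if ("signal" %in% names(df)) {
    parse_long_timecourse(df, geometry)
  } else {
    parse_wide_timecourse(df, geometry)
  }
}

parse_long_timecourse <- function(df, geometry) {
  need <- setdiff(TIMECOURSE_COLUMNS, c("replicate", "time_min"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("long table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$signal)) || any(df$signal < 0)) {
    bad <- df$well_id[is.na(df$signal) | df$signal < 0][1]
    stop("negative or missing signal value (well ", bad, ")", call. = FALSE)
  }
  times <- geometry$sampling_times
  wells <- list()
  for (id in unique(df$well_id)) {
    sub_w <- df[df$well_id == id, , drop = FALSE]
    for (ch in unique(sub_w$channel)) {
      sub <- sub_w[sub_w$channel == ch, , drop = FALSE]
      baso <- sub[sub$sample_type == "baso", , drop = FALSE]
      got <- sort(unique(as.numeric(baso$time_min)))
      if (!identical(got, as.numeric(times))) {
        missing_t <- setdiff(times, got)
        stop("well ", id, " [", ch, "] is missing basolateral sample(s) at ",
             "t = ", paste(missing_t, collapse = ", "), " min", call. = FALSE)
      }
      baso_mean <- vapply(times, function(tt)
        mean(baso$signal[as.numeric(baso$time_min) == tt]), numeric(1))
      stock <- sub$signal[sub$sample_type == "stock"]
      if (!length(stock)) {
        stop("well ", id, " [", ch, "] has no stock sample", call. = FALSE)
      }
      apical <- sub$signal[sub$sample_type == "apical_end"]
      wells[[length(wells) + 1L]] <- well_series(
        well_id = id, role = sub$role[1], compound = sub$compound[1],
        inhibitor = sub$inhibitor[1], treatment = sub$treatment[1],
        channel = ch, baso_signal = baso_mean, stock_signal = mean(stock),
        apical_end_signal = if (length(apical)) mean(apical) else NA_real_
      )
    }
  }
  out <- study_table(geometry, wells)
  attr(out, "replicates") <- df
  out
}

parse_wide_timecourse <- function(df, geometry) {
  tcols <- paste0("t", geometry$sampling_times)
  miss <- setdiff(c("well_id", "role", "compound", "channel", "stock", tcols),
                  names(df))
  if (length(miss)) {
    stop("wide table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wells <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    well_series(
      well_id = row$well_id, role = row$role, compound = row$compound,
      inhibitor = if (!is.null(row$inhibitor)) row$inhibitor else "none",
      treatment = if (!is.null(row$treatment)) row$treatment else "n/a",
      channel = row$channel,
      baso_signal = as.numeric(row[tcols]), stock_signal = row$stock
    )
  })
  study_table(geometry, wells)
}

#' Write a study table in the long measurement schema
#'
#' Inverse of [read_timecourse_table()]: emits one `baso` row per sampling
#' time, one `stock` row, and (when present) one `apical_end` row per well
#' series, with `replicate = 1`. Reading the file back reproduces all
#' signal values and labels exactly.
#'
#' @param study A [study_table()].
#' @param path Output file path (comma-separated).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(study, path) {
  stopifnot(inherits(study, "study_table"))
  times <- study$geometry$sampling_times
  rows <- lapply(unname(study$wells), function(w) {
    base <- data.frame(
      well_id = w$well_id, role = w$role, compound = w$compound,
      inhibitor = w$inhibitor, treatment = w$treatment, channel = w$channel,
      stringsAsFactors = FALSE
    )
    out <- cbind(base[rep(1L, length(times)), , drop = FALSE],
                 sample_type = "baso", time_min = times, replicate = 1L,
                 signal = w$baso_signal)
    out <- rbind(out, cbind(base, sample_type = "stock", time_min = NA,
                            replicate = 1L, signal = w$stock_signal))
    if (!is.na(w$apical_end_signal)) {
      out <- rbind(out, cbind(base, sample_type = "apical_end", time_min = NA,
                              replicate = 1L, signal = w$apical_end_signal))
    }
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  # full double precision so a read-back reproduces signals exactly
  df$signal <- formatC(df$signal, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write permeability results with unit-annotated headers
#'
#' Writes the per-well rows followed by the per-group summary rows (mean,
#' SD, SEM, n) of a [run_permeability()] result into a single CSV whose
#' leading comment lines record the units.
#'
#' @param results A result bundle from [run_permeability()], or a list with
#'   elements `per_well` and `groups` (either may be an empty data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  blocks <- list()
  if (!is.null(results$per_well) && nrow(results$per_well)) {
    blocks$well <- cbind(row_type = "well", results$per_well)
  }
  if (!is.null(results$groups) && nrow(results$groups)) {
    blocks$group <- cbind(row_type = "group", results$groups)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# clearperm results",
    "# units: PS fields uL/min; papp fields um/min; papp_normalized fold of matched CF; cumulated fields nmol/mm^2"
  ), con)
  if (!length(blocks)) {
    writeLines("row_type,well_id,value", con)
    return(invisible(path))
  }
  cols <- unique(unlist(lapply(blocks, names)))
  filled <- lapply(blocks, function(b) {
    b[setdiff(cols, names(b))] <- NA
    b[cols]
  })
  utils::write.csv(do.call(rbind, filled), con, row.names = FALSE, na = "")
  invisible(path)
}
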