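#' Measure per-cell compartment intensities for a field
#'
#' Computes, for every cell and each protein channel, the mean
#' background-corrected pixel intensity (sum of intensities divided by pixel
#' count) in nucleus, cytoplasm and nucleolus, plus the per-cell
#' nucleocytoplasmic (N/C) ratio. By default the nuclear mean covers the
#' whole DNA-stain-demarcated nucleus, nucleolar pixels included; set
#' `nucleus_excludes_nucleoli = TRUE` to restrict it to the nucleoplasm.
#'
#' @param field a [field_image()] whose protein channels are already
#'   background-corrected (see [segment_field()]).
#' @param masks a [compartment_masks()] for the same field.
#' @param channels protein channel names to measure (default `c("A", "B")`).
#' @param nucleus_excludes_nucleoli see above (default `FALSE`).
#' @param min_cells warn (not error) when fewer cells than this survive
#'   (default 35, a practical minimum per condition and replicate).
#' @return data.frame, one row per cell: identifiers, per-compartment areas
#'   (pixels and um^2), `<ch>_nucleus` / `<ch>_cytoplasm` / `<ch>_nucleolus`
#'   mean intensities (nucleolus `NA` when the cell has no detected
#'   nucleolar pixel) and `nc_<ch>` ratios (`NA` flagged when the cytoplasm
#'   mean is 0). Cells with an empty nucleus or cytoplasm are dropped; their
#'   IDs are in the `"dropped"` attribute.
#' @export
measure_field <- function(field, masks, channels = c("A", "B"),
                          nucleus_excludes_nucleoli = FALSE, min_cells = 35) {
  stopifnot(inherits(field, "field_image"), inherits(masks, "compartment_masks"))
  nuc <- masks$nucleus
  if (nucleus_excludes_nucleoli) nuc[masks$nucleolus > 0] <- 0L
  ids <- sort(unique(masks$nucleus[masks$nucleus > 0]))
  if (!length(ids)) {
    out <- empty_measurement(channels)
    attr(out, "dropped") <- integer(0)
    return(out)
  }
  nmax <- max(ids)
  area_nuc <- tabulate(nuc[nuc > 0], nmax)
  area_cyt <- tabulate(masks$cytoplasm[masks$cytoplasm > 0], nmax)
  area_nol <- tabulate(masks$nucleolus[masks$nucleolus > 0], nmax)
  keep <- ids[area_nuc[ids] > 0 & area_cyt[ids] > 0]
  dropped <- setdiff(ids, keep)
  if (length(dropped))
    message("dropped ", length(dropped),
            " cell(s) with empty nucleus or cytoplasm mask")
  out <- data.frame(field_id = field$field_id, condition = field$condition,
                    replicate = field$replicate, cell_id = keep,
                    area_nucleus_px = area_nuc[keep],
                    area_cytoplasm_px = area_cyt[keep],
                    area_nucleolus_px = area_nol[keep])
  out$area_nucleus_um2 <- out$area_nucleus_px * field$pixel_area
  out$area_cytoplasm_um2 <- out$area_cytoplasm_px * field$pixel_area
  for (ch in channels) {
    img <- field$channels[[ch]]
    if (is.null(img)) stop("field has no channel '", ch, "'")
    mnuc <- mean_by_label(img, nuc, nmax)
    mcyt <- mean_by_label(img, masks$cytoplasm, nmax)
    mnol <- mean_by_label(img, masks$nucleolus, nmax)
    out[[paste0(ch, "_nucleus")]] <- mnuc[keep]
    out[[paste0(ch, "_cytoplasm")]] <- mcyt[keep]
    out[[paste0(ch, "_nucleolus")]] <- mnol[keep]
    out[[paste0("nc_", ch)]] <- ifelse(mcyt[keep] > 0,
                                       mnuc[keep] / mcyt[keep], NA_real_)
  }
  if (nrow(out) < min_cells)
    warning("only ", nrow(out), " cells measured in field ", field$field_id,
            " (minimum recommended: ", min_cells, ")")
  attr(out, "dropped") <- dropped
  out
}

empty_measurement <- function(channels) {
  out <- data.frame(field_id = character(0), condition = character(0),
                    replicate = integer(0), cell_id = integer(0),
                    area_nucleus_px = integer(0), area_cytoplasm_px = integer(0),
                    area_nucleolus_px = integer(0),
                    area_nucleus_um2 = numeric(0), area_cytoplasm_um2 = numeric(0))
  for (ch in channels) {
    out[[paste0(ch, "_nucleus")]] <- numeric(0)
    out[[paste0(ch, "_cytoplasm")]] <- numeric(0)
    out[[paste0(ch, "_nucleolus")]] <- numeric(0)
    out[[paste0("nc_", ch)]] <- numeric(0)
  }
  out
}

#' Measure a single cell
#'
#' @inheritParams measure_field
#' @param cell_id cell to measure; must exist in `masks`.
#' @return one-row data.frame as in [measure_field()].
#' @export
measure_cell <- function(field, masks, cell_id, channels = c("A", "B"),
                         nucleus_excludes_nucleoli = FALSE) {
  if (!cell_id %in% masks$nucleus)
    stop("cell_id ", cell_id, " not present in masks")
  m <- measure_field(field, masks, channels = channels,
                     nucleus_excludes_nucleoli = nucleus_excludes_nucleoli,
                     min_cells = 0)
  m[m$cell_id == cell_id, , drop = FALSE]
}

# Measurement value columns of a table (intensities + N/C ratios).
measurement_columns <- function(measurements) {
  grep("^(A|B)_(nucleus|cytoplasm|nucleolus)$|^nc_(A|B)$",
       names(measurements), value = TRUE)
}

#' Normalize measurements to the unstressed control, per replicate
#'
#' Every measurement column (each channel x compartment mean and each N/C
#' ratio) is divided by the mean of that same quantity over the control cells
#' of the same replicate experiment. By construction the control-group mean
#' of every normalized quantity is exactly 1 within each replicate.
#'
#' @param measurements a measurement table from [measure_field()] (rows from
#'   several fields/conditions bound together).
#' @param control_condition the control condition label (default
#'   `"control"`).
#' @return the table with measurement columns normalized (dimensionless);
#'   carries attribute `normalized = TRUE` and the per-replicate control
#'   means in attribute `"control_means"`.
#' @export
normalize_to_control <- function(measurements, control_condition = "control") {
  if (!control_condition %in% measurements$condition)
    stop("control condition '", control_condition, "' absent from table")
  cols <- measurement_columns(measurements)
  out <- measurements
  ctrl_means <- list()
  for (rep_id in unique(measurements$replicate)) {
    in_rep <- measurements$replicate == rep_id
    in_ctrl <- in_rep & measurements$condition == control_condition
    if (!any(in_ctrl))
      stop("replicate ", rep_id, " has no cells in condition '",
           control_condition, "'")
    for (col in cols) {
      m <- mean(measurements[[col]][in_ctrl], na.rm = TRUE)
      if (!is.finite(m) || m == 0)
        stop("control mean of '", col, "' is zero or undefined in replicate ",
             rep_id)
      out[[col]][in_rep] <- measurements[[col]][in_rep] / m
      ctrl_means[[paste(rep_id, col, sep = ".")]] <- m
    }
  }
  attr(out, "normalized") <- TRUE
  attr(out, "control_means") <- unlist(ctrl_means)
  out
}

#' Single-cell values of one quantity, sorted ascending
#'
#' The ascending-order population profile: normalized per-cell values of one
#' channel and compartment under one condition, sorted ascending with ties
#' keeping their input order.
#'
#' @param measurements (normalized) measurement table.
#' @param channel `"A"` or `"B"`.
#' @param compartment `"nucleus"`, `"cytoplasm"`, `"nucleolus"` or `"nc"`
#'   (the N/C ratio).
#' @param condition condition label to profile.
#' @return numeric vector sorted ascending (`NA` values removed).
#' @export
ascending_profile <- function(measurements, channel, compartment, condition) {
  col <- if (compartment == "nc") paste0("nc_", channel)
         else paste0(channel, "_", compartment)
  if (!col %in% names(measurements)) stop("no column '", col, "'")
  v <- measurements[[col]][measurements$condition == condition]
  v <- v[!is.na(v)]
  v[order(v)]   # radix order: stable, ties keep input order
}

#' Mean and SEM per condition, channel and compartment
#'
#' `unit = "cell"` treats each cell as an observation. `unit = "replicate"`
#' (the three-independent-experiments convention) first averages cells within
#' each replicate, then reports mean and SEM across replicates, so n is the
#' number of experiments. SEM is `NA` (undefined) when fewer than two units
#' are available.
#'
#' @param measurements measurement table (normalized or raw).
#' @param unit `"cell"` or `"replicate"`.
#' @return long data.frame: `condition`, `quantity`, `n`, `mean`, `sem`.
#' @export
condition_summary <- function(measurements, unit = c("cell", "replicate")) {
  unit <- match.arg(unit)
  cols <- measurement_columns(measurements)
  rows <- list()
  for (cond in unique(measurements$condition)) {
    sub <- measurements[measurements$condition == cond, , drop = FALSE]
    for (col in cols) {
      if (unit == "replicate") {
        v <- tapply(sub[[col]], sub$replicate,
                    function(x) mean(x, na.rm = TRUE))
        v <- as.numeric(v[!is.na(v)])
      } else {
        v <- sub[[col]][!is.na(sub[[col]])]
      }
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, quantity = col, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
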