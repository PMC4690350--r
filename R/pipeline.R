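#' Run configuration for the full pipeline
#'
#' Either simulate an experiment (`simulate = TRUE`, using `sim` as the
#' generator configuration) or analyse existing images listed in a manifest
#' CSV (`manifest` with columns field_id, condition, replicate, channel,
#' path).
#'
#' @param simulate generate the input images with [generate_experiment()].
#' @param sim a [sim_config()] (required when simulating).
#' @param manifest path to a manifest CSV (required when not simulating).
#' @param control_condition control condition label (default `"control"`).
#' @param n_replicates replicates to simulate (default 3).
#' @param seed master seed; required when simulating.
#' @param threshold_method,threshold_values colocalization threshold policy,
#'   see [fix_thresholds()].
#' @param nucleus_excludes_nucleoli see [measure_field()].
#' @param segmentation named list of parameter lists (`nucleus`, `nucleolus`,
#'   `cytoplasm`) forwarded to [segment_field()].
#' @param summary_unit `"replicate"` (default) or `"cell"`, see
#'   [condition_summary()].
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(), manifest = NULL,
                       control_condition = "control", n_replicates = 3,
                       seed = 1L, threshold_method = "otsu",
                       threshold_values = NULL,
                       nucleus_excludes_nucleoli = FALSE,
                       segmentation = list(), summary_unit = "replicate") {
  if (simulate && is.null(seed)) stop("seed required when simulating")
  if (!simulate && is.null(manifest)) stop("manifest required when not simulating")
  structure(list(simulate = simulate, sim = sim, manifest = manifest,
                 control_condition = control_condition,
                 n_replicates = n_replicates, seed = seed,
                 threshold_method = threshold_method,
                 threshold_values = threshold_values,
                 nucleus_excludes_nucleoli = nucleus_excludes_nucleoli,
                 segmentation = segmentation, summary_unit = summary_unit),
            class = "run_config")
}

#' Run the full pipeline: images to statistics
#'
#' Stages, in order: acquire fields (simulate or read), validate that the
#' control condition is present (before any processing), per-field
#' background correction and segmentation, per-cell measurement,
#' colocalization thresholds frozen on the control fields then applied
#' everywhere, per-replicate control normalization, condition summaries,
#' correlation and regression grids, and ANOVA + Bonferroni tests of the N/C
#' ratios and nucleolar signals against the control. All tables, the
#' frozen thresholds and a provenance block are written to `out_dir`.
#' Identical config + seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return list of class `cq_run` with `measurements`, `normalized`,
#'   `summary`, `coloc`, `coloc_summary`, `correlation`, `regression`,
#'   `anova`, `thresholds`, `provenance` (invisibly).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")

  if (config$simulate) {
    manifest <- generate_experiment(config$sim, img_dir,
                                    n_replicates = config$n_replicates,
                                    master_seed = config$seed)
    manifest <- as.data.frame(manifest)
    pixel_area <- config$sim$pixel_area
  } else {
    manifest <- utils::read.csv(config$manifest)
    pixel_area <- if (!is.null(config$sim)) config$sim$pixel_area else 0.14
  }
  if (!config$control_condition %in% manifest$condition)
    stop("control condition '", config$control_condition,
         "' missing from manifest; aborting before processing")

  fields <- read_fields(manifest, pixel_area = pixel_area)
  # control fields first so that colocalization thresholds are frozen
  # before any non-control field is processed
  is_ctrl <- vapply(fields, function(f)
    f$condition == config$control_condition, logical(1))
  fields <- c(fields[is_ctrl], fields[!is_ctrl])

  seg <- list(); meas <- list(); dropped_log <- list()
  corrected_fields <- list()
  for (fid in names(fields)) {
    f <- fields[[fid]]
    res <- tryCatch(
      do.call(segment_field, c(list(f), stats::setNames(
        lapply(c("nucleus", "nucleolus", "cytoplasm"), function(nm)
          if (is.null(config$segmentation[[nm]])) list()
          else config$segmentation[[nm]]),
        c("nucleus_params", "nucleolus_params", "cytoplasm_params")))),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("field ", fid, " failed and was skipped: ", conditionMessage(res))
      dropped_log[[fid]] <- conditionMessage(res)
      next
    }
    seg[[fid]] <- res
    fc <- f; fc$channels <- res$corrected
    corrected_fields[[fid]] <- fc
    m <- suppressWarnings(measure_field(fc, res$masks,
        nucleus_excludes_nucleoli = config$nucleus_excludes_nucleoli))
    meas[[fid]] <- m
  }
  measurements <- do.call(rbind, meas)
  if (is.null(measurements) ||
      sum(measurements$condition == config$control_condition) == 0)
    stop("control condition yielded zero usable cells; run aborted")

  ctrl_corr <- corrected_fields[vapply(corrected_fields, function(f)
    f$condition == config$control_condition, logical(1))]
  thresholds <- fix_thresholds(ctrl_corr, method = config$threshold_method,
                               values = config$threshold_values)

  coloc <- do.call(rbind, lapply(corrected_fields, function(f)
    coloc_field(f, seg[[f$field_id]]$masks, thresholds)))
  coloc_summary <- coloc_condition_summary(
    coloc, control_condition = config$control_condition)

  normalized <- normalize_to_control(measurements,
                                     config$control_condition)
  summary_tab <- condition_summary(normalized, unit = config$summary_unit)
  correlation <- suppressWarnings(correlation_table(normalized))
  regression <- regression_table(normalized)

  anova_tabs <- list()
  for (col in c("nc_A", "nc_B", "A_nucleolus", "B_nucleolus")) {
    if (config$summary_unit == "replicate") {
      agg <- tapply(normalized[[col]],
                    list(normalized$condition, normalized$replicate),
                    function(x) mean(x, na.rm = TRUE))
      groups <- lapply(rownames(agg), function(cd) as.numeric(agg[cd, ]))
      names(groups) <- rownames(agg)
    } else {
      groups <- split(normalized[[col]], normalized$condition)
    }
    groups <- lapply(groups, function(v) v[is.finite(v)])
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (length(groups) >= 2 &&
        config$control_condition %in% names(groups)) {
      av <- one_way_anova(groups)
      bf <- bonferroni_vs_control(groups, config$control_condition)
      anova_tabs[[col]] <- data.frame(quantity = col, anova_f = av$f,
                                      anova_p = av$p, bf)
    }
  }
  anova_tab <- if (length(anova_tabs)) do.call(rbind, anova_tabs) else NULL

  cells_per_cond <- table(measurements$condition)
  provenance <- list(
    package_version = as.character(utils::packageVersion("compartquant")),
    seed = config$seed, simulate = config$simulate,
    control_condition = config$control_condition,
    thresholds = as.list(thresholds),
    cells_per_condition = as.list(cells_per_cond),
    dropped_fields = dropped_log,
    dropped_cells = lapply(meas, function(m) attr(m, "dropped")))

  utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(normalized, file.path(out_dir, "measurements_normalized.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_tab, file.path(out_dir, "condition_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(coloc, file.path(out_dir, "colocalization.csv"),
                   row.names = FALSE)
  utils::write.csv(coloc_summary$summary,
                   file.path(out_dir, "colocalization_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(correlation, file.path(out_dir, "correlation_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(regression, file.path(out_dir, "regression_table.csv"),
                   row.names = FALSE)
  if (!is.null(anova_tab))
    utils::write.csv(anova_tab, file.path(out_dir, "anova_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  stats_json <- list(correlation = correlation, regression = regression,
                     anova = anova_tab,
                     coloc_tests = coloc_summary$tests)
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(structure(
    list(measurements = measurements, normalized = normalized,
         summary = summary_tab, coloc = coloc,
         coloc_summary = coloc_summary, correlation = correlation,
         regression = regression, anova = anova_tab,
         thresholds = thresholds, provenance = provenance,
         segmentation = seg),
    class = "cq_run"))
}

#' Summarize a pipeline run, optionally with figures
#'
#' Reads the tables written by [run_pipeline()] and prints a human-readable
#' summary (cell counts, N/C ratio means with significance stars,
#' colocalization means, correlation grid). With `plots = TRUE` (requires
#' ggplot2) it also writes ascending-order profile plots, per-condition
#' scatter plots with trendlines, and mean + SEM bar charts to
#' `<out_dir>/plots/`.
#'
#' @param out_dir directory holding a completed run.
#' @param plots write figures (default `FALSE`).
#' @return list of the tables read, invisibly.
#' @export
report <- function(out_dir, plots = FALSE) {
  need <- c("condition_summary.csv", "colocalization_summary.csv",
            "correlation_grid.csv", "measurements_normalized.csv")
  missing_f <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing_f))
    stop("missing pipeline outputs: ", paste(missing_f, collapse = ", "))
  summary_tab <- utils::read.csv(file.path(out_dir, "condition_summary.csv"))
  coloc_sum <- utils::read.csv(file.path(out_dir, "colocalization_summary.csv"))
  corr <- utils::read.csv(file.path(out_dir, "correlation_grid.csv"))
  normalized <- utils::read.csv(file.path(out_dir,
                                          "measurements_normalized.csv"))
  anova_path <- file.path(out_dir, "anova_tests.csv")
  anova_tab <- if (file.exists(anova_path)) utils::read.csv(anova_path) else NULL

  cat("== compartquant run summary ==\n")
  cat("cells per condition:\n")
  print(table(normalized$condition))
  cat("\nnormalized N/C ratios (mean +/- SEM):\n")
  nc <- summary_tab[summary_tab$quantity %in% c("nc_A", "nc_B"), ]
  print(nc, row.names = FALSE)
  if (!is.null(anova_tab)) {
    cat("\nANOVA + Bonferroni vs control:\n")
    print(anova_tab[, c("quantity", "group", "p_adj", "stars")],
          row.names = FALSE)
  }
  cat("\ncolocalization (percent overlap, mean):\n")
  print(coloc_sum[, c("condition", "compartment", "direction", "n", "mean")],
        row.names = FALSE)
  cat("\ncorrelation grid (Pearson r, A vs B):\n")
  print(corr, row.names = FALSE)

  if (plots) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
      stop("plots = TRUE requires ggplot2")
    pdir <- file.path(out_dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    for (comp in c("nucleus", "cytoplasm")) {
      dat <- do.call(rbind, lapply(unique(normalized$condition), function(cd) {
        do.call(rbind, lapply(c("A", "B"), function(ch) {
          v <- ascending_profile(normalized, ch, comp, cd)
          if (!length(v)) return(NULL)
          data.frame(condition = cd, channel = ch, rank = seq_along(v),
                     value = v)
        }))
      }))
      p <- ggplot2::ggplot(dat, ggplot2::aes(x = rank, y = value,
                                             colour = channel)) +
        ggplot2::geom_point(size = 0.4) +
        ggplot2::facet_wrap(~condition, nrow = 1) +
        ggplot2::labs(y = paste("normalized", comp, "intensity"),
                      x = "cell rank (ascending)")
      ggplot2::ggsave(file.path(pdir, paste0("profile_", comp, ".pdf")), p,
                      width = 11, height = 3)
      p2 <- ggplot2::ggplot(normalized,
                            ggplot2::aes(x = .data[[paste0("A_", comp)]],
                                         y = .data[[paste0("B_", comp)]])) +
        ggplot2::geom_point(size = 0.5, alpha = 0.6) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
        ggplot2::facet_wrap(~condition, nrow = 1, scales = "free") +
        ggplot2::labs(x = paste("channel A,", comp),
                      y = paste("channel B,", comp))
      ggplot2::ggsave(file.path(pdir, paste0("scatter_", comp, ".pdf")), p2,
                      width = 11, height = 3)
    }
    nc_dat <- summary_tab[summary_tab$quantity %in% c("nc_A", "nc_B"), ]
    p3 <- ggplot2::ggplot(nc_dat, ggplot2::aes(x = condition, y = mean,
                                               fill = quantity)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                          ymax = mean + sem),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.3) +
      ggplot2::labs(y = "normalized N/C ratio (mean + SEM)")
    ggplot2::ggsave(file.path(pdir, "nc_ratio.pdf"), p3, width = 7,
                    height = 4)
  }
  invisible(list(summary = summary_tab, coloc_summary = coloc_sum,
                 correlation = corr, anova = anova_tab))
}
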