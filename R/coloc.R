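#' Threshold a channel into a binary mask
#'
#' Strict comparison: a pixel is positive when its intensity exceeds the
#' threshold.
#'
#' @param image numeric matrix.
#' @param threshold non-negative scalar.
#' @return logical matrix `image > threshold`.
#' @export
threshold_channel <- function(image, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("threshold must be a single non-negative number")
  image > threshold
}

#' Fix per-channel colocalization thresholds from control fields
#'
#' Computes one scalar threshold per protein channel from the pooled pixels
#' of the control fields, to be frozen and reused for every cell of every
#' condition. Methods: `"otsu"` (256-bin Otsu on the pooled histogram,
#' default), `"fixed"` (pass-through of supplied values), `"percentile"`
#' (pooled quantile).
#'
#' @param control_fields list of [field_image()] objects (background-
#'   corrected control fields).
#' @param method `"otsu"`, `"fixed"` or `"percentile"`.
#' @param values named numeric vector of thresholds for `method = "fixed"`.
#' @param prob quantile for `method = "percentile"` (default 0.95).
#' @param channels channels to threshold (default `c("A", "B")`).
#' @return named numeric vector of thresholds.
#' @export
fix_thresholds <- function(control_fields, method = c("otsu", "fixed",
                                                      "percentile"),
                           values = NULL, prob = 0.95,
                           channels = c("A", "B")) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(values) || !all(channels %in% names(values)))
      stop("method 'fixed' needs a named threshold per channel")
    return(values[channels])
  }
  stopifnot(length(control_fields) >= 1)
  out <- stats::setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    pool <- unlist(lapply(control_fields, function(f) {
      if (is.null(f$channels[[ch]])) stop("field lacks channel '", ch, "'")
      as.numeric(f$channels[[ch]])
    }))
    if (max(pool) == min(pool))
      stop("constant pooled intensities for channel '", ch,
           "': threshold undefined")
    out[ch] <- if (method == "otsu") otsu_level(pool)
               else stats::quantile(pool, prob, names = FALSE)
  }
  out
}

#' Percent-area colocalization for one cell
#'
#' Within the nuclear and cytoplasmic ROI of one cell, counts thresholded
#' channel-A pixels (`area_A`), channel-B pixels (`area_B`) and pixels
#' positive in both (`shared`), and reports the two asymmetric percentages:
#' `pct_A_in_B = 100 shared / area_A` (how much of the A area also contains
#' B) and `pct_B_in_A = 100 shared / area_B`. A zero denominator flags the
#' corresponding percentage as `NA` (undefined, not zero).
#'
#' @param mask_A,mask_B logical matrices from [threshold_channel()].
#' @param masks a [compartment_masks()].
#' @param cell_id cell to analyse; unknown IDs are an error.
#' @param pixel_area pixel area in um^2 (recorded in the output).
#' @return data.frame with two rows (nucleus, cytoplasm): `cell_id`,
#'   `compartment`, `area_A`, `area_B`, `shared`, `pct_A_in_B`,
#'   `pct_B_in_A`, `pixel_area`.
#' @export
coloc_per_cell <- function(mask_A, mask_B, masks, cell_id, pixel_area = 0.14) {
  stopifnot(identical(dim(mask_A), dim(mask_B)),
            identical(dim(mask_A), dim(masks$nucleus)))
  if (!cell_id %in% masks$nucleus)
    stop("unknown cell_id: ", cell_id)
  rows <- lapply(c("nucleus", "cytoplasm"), function(k) {
    roi <- masks[[k]] == cell_id
    a <- sum(mask_A & roi); b <- sum(mask_B & roi)
    s <- sum(mask_A & mask_B & roi)
    data.frame(cell_id = cell_id, compartment = k, area_A = a, area_B = b,
               shared = s,
               pct_A_in_B = if (a > 0) 100 * s / a else NA_real_,
               pct_B_in_A = if (b > 0) 100 * s / b else NA_real_,
               pixel_area = pixel_area)
  })
  do.call(rbind, rows)
}

#' Colocalization records for every cell of a field
#'
#' Thresholds the two protein channels at the frozen per-channel thresholds
#' and evaluates [coloc_per_cell()] for every cell of the field.
#'
#' @param field a [field_image()] (background-corrected protein channels).
#' @param masks a [compartment_masks()] for the field.
#' @param thresholds named numeric vector from [fix_thresholds()].
#' @return data.frame of [coloc_per_cell()] rows, with `field_id`,
#'   `condition` and `replicate` prepended.
#' @export
coloc_field <- function(field, masks, thresholds) {
  mA <- threshold_channel(field$channels$A, thresholds[["A"]])
  mB <- threshold_channel(field$channels$B, thresholds[["B"]])
  ids <- cell_ids(masks)
  recs <- lapply(ids, function(i)
    coloc_per_cell(mA, mB, masks, i, pixel_area = field$pixel_area))
  out <- do.call(rbind, recs)
  if (is.null(out)) return(NULL)
  data.frame(field_id = field$field_id, condition = field$condition,
             replicate = field$replicate, out)
}

#' Condition-level colocalization summary with significance vs control
#'
#' Mean and SEM of the two percent-overlap directions per condition and
#' compartment, flagging conditions with fewer analysed cells than
#' `min_cells`. Cells whose percentage is undefined (zero denominator) are
#' excluded from the mean, with the excluded count reported. When a control
#' condition is present and at least two conditions have enough cells, a
#' one-way ANOVA across conditions plus Bonferroni-adjusted comparisons
#' against the control is attached per compartment x direction.
#'
#' @param records row-bound [coloc_field()] output across fields.
#' @param control_condition control label for the post-hoc comparisons
#'   (default `"control"`; set `NULL` to skip testing).
#' @param min_cells minimum cells per condition (default 10).
#' @return list with `summary` (data.frame: condition, compartment,
#'   direction, n, n_undefined, mean, sem, below_min) and `tests`
#'   (data.frame of ANOVA p plus Bonferroni-adjusted p per condition, or
#'   `NULL`).
#' @export
coloc_condition_summary <- function(records, control_condition = "control",
                                    min_cells = 10) {
  dirs <- c(pct_A_in_B = "A_in_B", pct_B_in_A = "B_in_A")
  rows <- list(); tests <- list()
  for (k in unique(records$compartment)) {
    for (col in names(dirs)) {
      sub <- records[records$compartment == k, , drop = FALSE]
      groups <- split(sub[[col]], sub$condition)
      groups <- lapply(groups, function(v) v[!is.na(v)])
      for (cond in names(groups)) {
        v <- groups[[cond]]
        n_all <- sum(records$compartment == k & records$condition == cond)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, compartment = k, direction = dirs[[col]],
          n = length(v), n_undefined = n_all - length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
          below_min = length(v) < min_cells)
      }
      if (!is.null(control_condition) &&
          control_condition %in% names(groups)) {
        usable <- groups[vapply(groups, length, integer(1)) >= 2]
        if (length(usable) >= 2 && control_condition %in% names(usable)) {
          aov_res <- one_way_anova(usable)
          bf <- bonferroni_vs_control(usable, control_condition)
          tests[[length(tests) + 1]] <- data.frame(
            compartment = k, direction = dirs[[col]],
            anova_f = aov_res$f, anova_p = aov_res$p, bf)
        }
      }
    }
  }
  list(summary = do.call(rbind, rows),
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
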