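#' Estimate camera background from cell-free pixels
#'
#' Mean intensity over pixels outside the exclusion (cell) mask — the
#' automated analogue of picking a region devoid of cells.
#'
#' @param image numeric intensity matrix.
#' @param exclusion_mask logical matrix marking pixels to exclude (cells and
#'   their surroundings); `NULL` uses the whole image.
#' @return scalar background level (ADU).
#' @export
estimate_background <- function(image, exclusion_mask = NULL) {
  if (is.null(exclusion_mask)) exclusion_mask <- matrix(FALSE, nrow(image), ncol(image))
  stopifnot(identical(dim(image), dim(exclusion_mask)))
  free <- !exclusion_mask
  if (mean(free) < 0.01)
    stop("fewer than 1% of pixels are cell-free; supply a manual background ROI")
  mean(image[free])
}

#' Subtract a background level, clamping at zero
#'
#' @param image numeric intensity matrix.
#' @param background non-negative scalar background level.
#' @return corrected matrix, `max(image - background, 0)` pixelwise.
#' @export
correct_background <- function(image, background) {
  if (!is.numeric(background) || length(background) != 1 || background < 0)
    stop("background must be a single non-negative number")
  pmax(image - background, 0)
}

#' Segment nuclei from the DNA-stain channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling (so
#' dark nucleoli stay inside their nucleus), connected-component labeling,
#' minimum-area filtering, optional distance-transform watershed splitting of
#' touching nuclei, and removal of border-touching objects.
#'
#' @param dna_stain numeric matrix (DNA-stain channel, background-corrected
#'   or raw — the global threshold adapts either way).
#' @param threshold global intensity threshold; `NULL` (default) uses Otsu.
#' @param smooth_sigma Gaussian pre-smoothing SD in pixels (default 1).
#' @param min_area minimum nucleus area in pixels (default 50).
#' @param split_touching split touching nuclei by watershed on the distance
#'   transform (default `FALSE`).
#' @param exclude_border drop nuclei touching the image border (default
#'   `TRUE`).
#' @return list with `labels` (integer label matrix; 0 background),
#'   `border_excluded` (IDs removed at the border) and `threshold` used.
#'   Zero detected nuclei is reported with a warning, not an error.
#' @export
segment_nuclei <- function(dna_stain, threshold = NULL, smooth_sigma = 1,
                           min_area = 50, split_touching = FALSE,
                           exclude_border = TRUE) {
  if (max(dna_stain) == min(dna_stain))
    stop("constant DNA-stain image: nothing to segment")
  sm <- smooth_image(dna_stain, smooth_sigma)
  if (is.null(threshold)) threshold <- otsu_level(sm)
  mask <- sm > threshold
  if (!any(mask)) {
    warning("no nuclei found")
    return(list(labels = matrix(0L, nrow(dna_stain), ncol(dna_stain)),
                border_excluded = integer(0), threshold = threshold))
  }
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  if (split_touching) {
    d <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(EBImage::watershed(d, tolerance = 2))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  lab <- matrix(as.integer(lab), nrow(dna_stain))
  # minimum-area filter
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    drop <- which(areas > 0 & areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  border_excluded <- integer(0)
  if (exclude_border && max(lab) > 0) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_excluded <- sort(edge[edge > 0])
    if (length(border_excluded)) lab[lab %in% border_excluded] <- 0L
  }
  if (!any(lab > 0)) warning("no nuclei left after filtering")
  list(labels = lab, border_excluded = border_excluded, threshold = threshold)
}

#' Segment nucleoli as dark holes within each nucleus
#'
#' Within every nucleus, pixels whose smoothed DNA-stain intensity falls below
#' `dark_fraction` times the median nuclear intensity are candidate nucleolar
#' pixels; a morphological opening removes specks and a minimum-area filter
#' keeps real nucleoli. Each nucleolus inherits the cell ID of its nucleus.
#'
#' @param dna_stain numeric matrix (DNA-stain channel).
#' @param nucleus_labels integer nucleus label matrix.
#' @param dark_fraction fraction of the per-nucleus median DNA intensity used
#'   as the darkness cutoff (default 0.6).
#' @param smooth_sigma Gaussian smoothing SD in pixels (default 1).
#' @param min_area minimum nucleolus area in pixels (default 10).
#' @return integer label matrix with nucleolar pixels carrying their cell ID.
#'   Nuclei with no dark holes simply contribute no pixels.
#' @export
segment_nucleoli <- function(dna_stain, nucleus_labels, dark_fraction = 0.6,
                             smooth_sigma = 1, min_area = 10) {
  stopifnot(identical(dim(dna_stain), dim(nucleus_labels)))
  sm <- smooth_image(dna_stain, smooth_sigma)
  cand <- matrix(FALSE, nrow(dna_stain), ncol(dna_stain))
  ids <- unique(nucleus_labels[nucleus_labels > 0])
  for (id in ids) {
    inside <- nucleus_labels == id
    med <- stats::median(sm[inside])
    cand[inside & sm < dark_fraction * med] <- TRUE
  }
  if (!any(cand))
    return(matrix(0L, nrow(dna_stain), ncol(dna_stain)))
  cand <- EBImage::imageData(
    EBImage::opening(EBImage::Image(cand * 1), EBImage::makeBrush(3, "disc"))) > 0
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1)))
  comp <- matrix(as.integer(comp), nrow(dna_stain))
  out <- matrix(0L, nrow(dna_stain), ncol(dna_stain))
  if (max(comp) > 0) {
    areas <- tabulate(comp[comp > 0], max(comp))
    for (cc in which(areas >= min_area)) {
      pix <- comp == cc
      owner <- nucleus_labels[pix][1]   # components lie within one nucleus
      out[pix] <- owner
    }
  }
  out
}

#' Segment cell outlines and cytoplasm
#'
#' Default `"watershed"` strategy: the cell mask comes from thresholding the
#' smoothed sum of the two protein channels, and cells are partitioned among
#' nuclei by nucleus-seeded region growing (geodesic Voronoi propagation).
#' `"annulus"` strategy: a fixed-width ring around each nucleus. In both
#' cases the cytoplasm is the cell minus the nucleus dilated by a guard ring,
#' which keeps nuclear edge bleed out of cytoplasmic measurements.
#'
#' @param protein_channels list of numeric matrices (typically the two
#'   background-corrected protein channels); they are summed to form the cell
#'   signal. Ignored by the annulus strategy.
#' @param nucleus_labels integer nucleus label matrix.
#' @param strategy `"watershed"` (default) or `"annulus"`.
#' @param threshold cell-mask threshold; `NULL` uses Otsu on the summed
#'   signal.
#' @param annulus_width ring width in pixels for the annulus strategy
#'   (default 8).
#' @param guard_ring width in pixels of the nucleus-cytoplasm exclusion ring
#'   (default 1).
#' @param smooth_sigma smoothing applied to the summed protein signal.
#' @return list with integer label matrices `cell` and `cytoplasm` (shared
#'   cell IDs) and `dropped` (IDs of nuclei whose cell mask was empty).
#' @export
segment_cytoplasm <- function(protein_channels, nucleus_labels,
                              strategy = c("watershed", "annulus"),
                              threshold = NULL, annulus_width = 8,
                              guard_ring = 1, smooth_sigma = 1) {
  strategy <- match.arg(strategy)
  H <- nrow(nucleus_labels); W <- ncol(nucleus_labels)
  nucmask <- nucleus_labels > 0
  if (strategy == "watershed") {
    signal <- Reduce(`+`, protein_channels)
    stopifnot(identical(dim(signal), dim(nucleus_labels)))
    sm <- smooth_image(signal, smooth_sigma)
    if (is.null(threshold)) threshold <- otsu_level(sm)
    cellmask <- sm > threshold | nucmask
    cells <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(sm), seeds = EBImage::Image(nucleus_labels),
      mask = cellmask))
    cells <- matrix(as.integer(cells), H, W)
  } else {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!nucmask) * 1)))
    ring <- d > 0 & d <= annulus_width
    cells <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(matrix(0, H, W)), seeds = EBImage::Image(nucleus_labels),
      mask = ring | nucmask))
    cells <- matrix(as.integer(cells), H, W)
  }
  guard <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(nucmask * 1),
    EBImage::makeBrush(2 * guard_ring + 1, "disc"))) > 0
  cytoplasm <- cells
  cytoplasm[guard] <- 0L
  ids <- sort(unique(nucleus_labels[nucmask]))
  cyt_areas <- tabulate(cytoplasm[cytoplasm > 0],
                        nbins = max(c(ids, 0)))
  dropped <- ids[cyt_areas[ids] == 0]
  if (length(dropped)) {
    warning("cell mask does not cover a cytoplasm for cell(s) ",
            paste(dropped, collapse = ", "), "; dropped")
    cells[cells %in% dropped] <- 0L
    cytoplasm[cytoplasm %in% dropped] <- 0L
  }
  list(cell = cells, cytoplasm = cytoplasm, dropped = dropped)
}

#' Segment a whole field into compartment masks
#'
#' Orchestrates background estimation and correction, nucleus, nucleolus and
#' cytoplasm segmentation for one [field_image()], and assembles a validated
#' [compartment_masks()] object. Cells dropped at the border or lacking
#' cytoplasm are removed consistently across all layers.
#'
#' @param field a [field_image()].
#' @param nucleus_params,nucleolus_params,cytoplasm_params named lists of
#'   overrides passed to [segment_nuclei()], [segment_nucleoli()] and
#'   [segment_cytoplasm()].
#' @return list with `masks` ([compartment_masks()]), `background` (named
#'   per-channel levels), `corrected` (list of background-corrected channel
#'   matrices) and `dropped` (cell IDs removed for missing cytoplasm).
#' @export
segment_field <- function(field, nucleus_params = list(),
                          nucleolus_params = list(),
                          cytoplasm_params = list()) {
  stopifnot(inherits(field, "field_image"))
  # rough cell cover (raw images) for background estimation
  dna_sm <- smooth_image(field$channels$dna, 1)
  prot_sm <- smooth_image(field$channels$A + field$channels$B, 1)
  rough <- (dna_sm > otsu_level(dna_sm)) | (prot_sm > otsu_level(prot_sm))
  rough <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(rough * 1), EBImage::makeBrush(9, "disc"))) > 0
  background <- vapply(field$channels, estimate_background,
                       numeric(1), exclusion_mask = rough)
  corrected <- mapply(correct_background, field$channels, background,
                      SIMPLIFY = FALSE)
  nuc <- do.call(segment_nuclei, c(list(corrected$dna), nucleus_params))
  nol <- do.call(segment_nucleoli,
                 c(list(corrected$dna, nuc$labels), nucleolus_params))
  cyt <- do.call(segment_cytoplasm,
                 c(list(corrected[c("A", "B")], nuc$labels), cytoplasm_params))
  nucleus_labels <- nuc$labels
  if (length(cyt$dropped)) {
    nucleus_labels[nucleus_labels %in% cyt$dropped] <- 0L
    nol[nol %in% cyt$dropped] <- 0L
  }
  nol[nucleus_labels == 0L] <- 0L
  cell <- cyt$cell
  cell[nucleus_labels > 0] <- nucleus_labels[nucleus_labels > 0]
  cell[cell > 0 & nucleus_labels == 0 & cyt$cytoplasm == 0] <- 0L
  masks <- compartment_masks(cell, nucleus_labels, nol, cyt$cytoplasm,
                             border_excluded = nuc$border_excluded)
  list(masks = masks, background = background, corrected = corrected,
       dropped = cyt$dropped)
}

#' Dice coefficient between two binary masks
#'
#' `2 |X n Y| / (|X| + |Y|)`; 1 for identical non-empty masks, `NaN` when
#' both masks are empty.
#'
#' @param x,y logical matrices.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(x, y) {
  2 * sum(x & y) / (sum(x) + sum(y))
}

#' Match segmented labels to ground-truth labels and score Dice per object
#'
#' Each ground-truth object is matched to the segmented label with the
#' largest pixel overlap.
#'
#' @param labels segmented integer label matrix.
#' @param truth_labels ground-truth integer label matrix.
#' @return data.frame with `truth_id`, `matched_id` (0 if unmatched) and
#'   `dice` per ground-truth object.
#' @export
dice_by_object <- function(labels, truth_labels) {
  ids <- sort(unique(truth_labels[truth_labels > 0]))
  out <- data.frame(truth_id = ids, matched_id = 0L, dice = 0)
  for (i in seq_along(ids)) {
    tmask <- truth_labels == ids[i]
    cand <- labels[tmask]
    cand <- cand[cand > 0]
    if (!length(cand)) next
    m <- as.integer(names(which.max(table(cand))))
    out$matched_id[i] <- m
    out$dice[i] <- dice(labels == m, tmask)
  }
  out
}

# Gaussian smoothing that tolerates sigma = 0.
smooth_image <- function(image, sigma) {
  if (sigma <= 0) return(image)
  EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma = sigma))
}

# Otsu threshold of a numeric matrix/vector (256 bins over the data range).
otsu_level <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("constant intensities: Otsu threshold undefined")
  EBImage::otsu(EBImage::Image(matrix(as.numeric(x), ncol = 1)),
                range = rng, levels = 256)
}
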