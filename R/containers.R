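#' Multi-channel microscope field
#'
#' Bundles the channels of one imaged field with its acquisition metadata.
#' Channels are stored as numeric matrices in detector units (ADU), all with
#' the same dimensions. The canonical channel roles are `dna` (DNA stain used
#' for compartment demarcation), `A` and `B` (the two protein channels).
#'
#' @param channels named list of numeric matrices; must contain at least
#'   `dna`, `A` and `B`, all of identical dimensions and non-negative.
#' @param pixel_area physical area of one pixel in square micrometres
#'   (default 0.14).
#' @param condition experimental condition label (e.g. `"control"`).
#' @param replicate replicate (independent experiment) identifier.
#' @param field_id identifier for this field.
#' @return An object of class `field_image`.
#' @export
field_image <- function(channels, pixel_area = 0.14, condition = "control",
                        replicate = 1L, field_id = "field") {
  stopifnot(is.list(channels), !is.null(names(channels)))
  req <- c("dna", "A", "B")
  missing_ch <- setdiff(req, names(channels))
  if (length(missing_ch))
    stop("field_image: missing channel(s): ", paste(missing_ch, collapse = ", "))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop("field_image: all channels must share the same dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch) || any(!is.finite(ch)) || any(ch < 0))
      stop("field_image: channel '", nm, "' must be finite and non-negative")
  }
  if (!is.numeric(pixel_area) || pixel_area <= 0)
    stop("field_image: pixel_area must be > 0")
  structure(
    list(channels = channels, pixel_area = pixel_area,
         condition = condition, replicate = replicate, field_id = field_id),
    class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<field_image> ", x$field_id, " [", d[1], "x", d[2], "], ",
      length(x$channels), " channels (",
      paste(names(x$channels), collapse = ", "), ")\n", sep = "")
  cat("  condition: ", x$condition, "  replicate: ", x$replicate,
      "  pixel area: ", x$pixel_area, " um^2\n", sep = "")
  invisible(x)
}

#' Per-cell compartment label masks
#'
#' Integer label images sharing cell identifiers across layers: a pixel with
#' value `i` in `nucleus` belongs to the nucleus of cell `i`. Background is 0.
#' The nucleus layer covers the whole DNA-stain-demarcated nuclear area,
#' nucleolar pixels included; the nucleolus layer is a subset of it, and
#' cytoplasm is disjoint from the nucleus.
#'
#' @param cell,nucleus,nucleolus,cytoplasm integer label matrices of identical
#'   dimensions, sharing cell IDs (0 = background).
#' @param border_excluded integer vector of cell IDs removed because they
#'   touched the image border.
#' @param validate run the containment/disjointness invariant checks
#'   (default `TRUE`).
#' @return An object of class `compartment_masks`.
#' @export
compartment_masks <- function(cell, nucleus, nucleolus, cytoplasm,
                              border_excluded = integer(), validate = TRUE) {
  m <- structure(
    list(cell = cell, nucleus = nucleus, nucleolus = nucleolus,
         cytoplasm = cytoplasm,
         border_excluded = as.integer(border_excluded)),
    class = "compartment_masks")
  if (validate) validate_masks(m)
  m
}

#' Check compartment mask invariants
#'
#' Asserts, for every cell ID: nucleolus pixels lie inside the nucleus of the
#' same cell; cytoplasm and nucleus are disjoint; nucleus and cytoplasm lie
#' inside the cell outline; labels are non-negative integers.
#'
#' @param masks a [compartment_masks()] object.
#' @return `TRUE` invisibly; stops with a message on the first violated
#'   invariant.
#' @export
validate_masks <- function(masks) {
  layers <- masks[c("cell", "nucleus", "nucleolus", "cytoplasm")]
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop("compartment_masks: layers differ in dimension")
  for (nm in names(layers)) {
    if (any(layers[[nm]] < 0) || any(layers[[nm]] != round(layers[[nm]])))
      stop("compartment_masks: layer '", nm, "' must hold non-negative integers")
  }
  nol <- masks$nucleolus; nuc <- masks$nucleus
  cyt <- masks$cytoplasm; cel <- masks$cell
  idx <- which(nol > 0)
  if (any(nuc[idx] != nol[idx]))
    stop("compartment_masks: nucleolus pixels outside the matching nucleus")
  if (any(nuc > 0 & cyt > 0))
    stop("compartment_masks: nucleus and cytoplasm overlap")
  idx <- which(nuc > 0)
  if (any(cel[idx] != nuc[idx]))
    stop("compartment_masks: nucleus pixels outside the matching cell")
  idx <- which(cyt > 0)
  if (any(cel[idx] != cyt[idx]))
    stop("compartment_masks: cytoplasm pixels outside the matching cell")
  invisible(TRUE)
}

#' @export
print.compartment_masks <- function(x, ...) {
  ids <- cell_ids(x)
  cat("<compartment_masks> ", length(ids), " cells",
      if (length(x$border_excluded))
        paste0(" (", length(x$border_excluded), " border-excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' Cell IDs present in a mask set
#'
#' @param masks a [compartment_masks()] object.
#' @return sorted integer vector of cell IDs (nucleus layer).
#' @export
cell_ids <- function(masks) {
  sort(unique(masks$nucleus[masks$nucleus > 0]))
}

# Internal: 16-bit ADU scale used for TIFF serialization.
ADU_MAX <- 65535

#' Write a field as single-channel 16-bit TIFF files
#'
#' One file per channel, named `<field_id>_<channel>.tif`, intensities stored
#' on the 16-bit scale.
#'
#' @param field a [field_image()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths (by channel), invisibly.
#' @export
write_field_tiff <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(field$channels)) {
    p <- file.path(dir, paste0(field$field_id, "_", ch, ".tif"))
    img <- pmin(pmax(field$channels[[ch]], 0), ADU_MAX) / ADU_MAX
    EBImage::writeImage(EBImage::Image(img), p, type = "tiff",
                        bits.per.sample = 16L)
    paths[ch] <- p
  }
  invisible(paths)
}

#' Read one channel TIFF back to an ADU matrix
#'
#' @param path path to a 16-bit single-channel TIFF.
#' @return numeric matrix in ADU.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- EBImage::readImage(path)
  round(EBImage::imageData(img) * ADU_MAX)
}

#' Assemble field_image objects from a manifest table
#'
#' @param manifest data.frame with columns `field_id`, `condition`,
#'   `replicate`, `channel`, `path` (one row per channel file), as written by
#'   [generate_experiment()].
#' @param pixel_area pixel area in square micrometres.
#' @return list of [field_image()] objects, one per distinct `field_id`.
#' @export
read_fields <- function(manifest, pixel_area = 0.14) {
  stopifnot(all(c("field_id", "condition", "replicate", "channel", "path")
                %in% names(manifest)))
  out <- list()
  for (fid in unique(manifest$field_id)) {
    rows <- manifest[manifest$field_id == fid, , drop = FALSE]
    chans <- lapply(seq_len(nrow(rows)), function(i) read_channel_tiff(rows$path[i]))
    names(chans) <- rows$channel
    out[[fid]] <- field_image(chans, pixel_area = pixel_area,
                              condition = rows$condition[1],
                              replicate = rows$replicate[1], field_id = fid)
  }
  out
}
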