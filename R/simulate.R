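#' Simulation configuration for synthetic fluorescence fields
#'
#' Builds the configuration driving [generate_field()] and
#' [generate_experiment()]. The defaults encode a five-condition heat-shock
#' time course (control, heat shock, 1/2/3 h recovery) in which channel A
#' progressively enriches in the nucleus (with a nucleolar peak early in
#' recovery) while channel B stays essentially unchanged and excluded from
#' nucleoli — the redistribution pattern of a constitutive hsp70-family
#' chaperone versus its nucleotide-exchange co-chaperone. Three replicate
#' fields of 40 cells give >=115 cells per condition and >=35 per replicate.
#'
#' Intensity tables give the rendered mean `mu` (ADU) per channel and
#' compartment; `nucleus` is the nucleoplasm value (nucleolar pixels are
#' rendered at the `nucleolus` value inside the nucleus). Cell-to-cell
#' variability multiplies each cell x channel x compartment by a brightness
#' factor `1 + cv * z`, where the standard-normal `z` of channels A and B
#' share a latent component so that their correlation equals
#' `cross_cell_correlation` for that compartment.
#'
#' @param ... named overrides of any default field. Key fields:
#' \describe{
#'   \item{n_cells}{cells per field (default 40).}
#'   \item{field_size}{image height and width in pixels, default `c(560, 560)`.}
#'   \item{pixel_area}{um^2 per pixel, default 0.14.}
#'   \item{nucleus_radius_range, cell_radius_range, nucleolus_radius_range}{
#'     semi-axis / radius ranges in pixels.}
#'   \item{n_nucleoli_range}{nucleoli per nucleus, default `c(1, 3)`.}
#'   \item{intensity}{per-condition list of per-channel `mu` vectors
#'     (`nucleus`, `cytoplasm`, `nucleolus`).}
#'   \item{dispersion}{cell-to-cell coefficient of variation per channel,
#'     default `c(dna = 0.05, A = 0.2, B = 0.2)`.}
#'   \item{cross_cell_correlation}{latent A-B correlation in `[-1, 1]`:
#'     scalar, per-compartment vector, or per-condition list of such vectors.}
#'   \item{coloc_fraction}{`NULL` (no embedded puncta) or target fraction of
#'     channel-B-positive pixels that are also channel-A-positive, per
#'     compartment (`nucleus`, `cytoplasm`); scalar, vector or per-condition
#'     list.}
#'   \item{puncta_fraction}{fraction of compartment pixels rendered as bright
#'     puncta in each protein channel when colocalization is embedded
#'     (default 0.12).}
#'   \item{coloc_delta}{intensity added to puncta pixels; default 3x the
#'     brightest configured `mu`, so one global threshold separates puncta
#'     from diffuse signal in every cell.}
#'   \item{background_level}{camera background in ADU (default 40).}
#'   \item{noise_sd}{Gaussian read-noise SD; default 2% of the brightest
#'     configured `mu`. `poisson_noise = TRUE` adds shot noise.}
#'   \item{seed}{master random seed.}
#' }
#' @return object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_cells = 40L,
    field_size = c(560L, 560L),
    pixel_area = 0.14,
    nucleus_radius_range = c(10, 14),
    n_nucleoli_range = c(1L, 3L),
    nucleolus_radius_range = c(3, 5),
    cell_radius_range = c(17, 23),
    intensity = list(
      control     = list(dna = c(nucleus = 200, cytoplasm = 25, nucleolus = 80),
                         A   = c(nucleus = 110, cytoplasm = 130, nucleolus = 70),
                         B   = c(nucleus = 120, cytoplasm = 115, nucleolus = 45)),
      heat_shock  = list(dna = c(nucleus = 200, cytoplasm = 25, nucleolus = 80),
                         A   = c(nucleus = 150, cytoplasm = 118, nucleolus = 95),
                         B   = c(nucleus = 120, cytoplasm = 115, nucleolus = 45)),
      recovery_1h = list(dna = c(nucleus = 200, cytoplasm = 25, nucleolus = 80),
                         A   = c(nucleus = 175, cytoplasm = 105, nucleolus = 240),
                         B   = c(nucleus = 120, cytoplasm = 116, nucleolus = 45)),
      recovery_2h = list(dna = c(nucleus = 200, cytoplasm = 25, nucleolus = 80),
                         A   = c(nucleus = 205, cytoplasm = 96,  nucleolus = 205),
                         B   = c(nucleus = 120, cytoplasm = 117, nucleolus = 45)),
      recovery_3h = list(dna = c(nucleus = 200, cytoplasm = 25, nucleolus = 80),
                         A   = c(nucleus = 235, cytoplasm = 88,  nucleolus = 175),
                         B   = c(nucleus = 120, cytoplasm = 118, nucleolus = 45))),
    dispersion = c(dna = 0.05, A = 0.20, B = 0.20),
    cross_cell_correlation = list(
      control     = c(nucleus = 0.80, cytoplasm = 0.80, nucleolus = 0.50),
      heat_shock  = c(nucleus = 0.85, cytoplasm = 0.75, nucleolus = 0.50),
      recovery_1h = c(nucleus = 0.11, cytoplasm = 0.85, nucleolus = 0.30),
      recovery_2h = c(nucleus = 0.50, cytoplasm = 0.70, nucleolus = 0.40),
      recovery_3h = c(nucleus = 0.60, cytoplasm = 0.85, nucleolus = 0.50)),
    coloc_fraction = NULL,
    puncta_fraction = 0.12,
    coloc_delta = NULL,
    background_level = 40,
    noise_sd = NULL,
    poisson_noise = FALSE,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots   # replace whole fields, no recursive merge
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a [sim_config()] object (or plain list with the same fields).
#' @return `cfg` invisibly; stops on the first violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 1, length(cfg$field_size) == 2,
            all(cfg$field_size > 0), cfg$pixel_area > 0)
  rr <- function(x) length(x) == 2 && all(x > 0) && x[1] <= x[2]
  if (!rr(cfg$nucleus_radius_range)) stop("invalid nucleus_radius_range")
  if (!rr(cfg$nucleolus_radius_range)) stop("invalid nucleolus_radius_range")
  if (!rr(cfg$cell_radius_range)) stop("invalid cell_radius_range")
  if (cfg$nucleolus_radius_range[2] >= cfg$nucleus_radius_range[1])
    stop("nucleolus radius must be smaller than nucleus radius")
  if (cfg$cell_radius_range[1] <= cfg$nucleus_radius_range[2])
    stop("cell radius must exceed nucleus radius")
  for (cond in names(cfg$intensity)) {
    tab <- cfg$intensity[[cond]]
    for (ch in names(tab)) {
      mu <- tab[[ch]]
      if (!all(c("nucleus", "cytoplasm", "nucleolus") %in% names(mu)))
        stop("intensity table for ", cond, "/", ch, " lacks a compartment")
      if (any(mu < 0)) stop("negative mu in ", cond, "/", ch)
    }
  }
  if (any(cfg$dispersion < 0)) stop("dispersion must be >= 0")
  allrho <- unlist(cfg$cross_cell_correlation)
  if (any(allrho < -1 | allrho > 1))
    stop("cross_cell_correlation must lie in [-1, 1]")
  if (!is.null(cfg$coloc_fraction)) {
    f <- unlist(cfg$coloc_fraction)
    if (any(f < 0 | f > 1)) stop("coloc_fraction must lie in [0, 1]")
  }
  stopifnot(cfg$puncta_fraction >= 0, cfg$puncta_fraction < 1,
            cfg$background_level >= 0)
  invisible(cfg)
}

# Brightest configured mu over all conditions/channels/compartments.
max_mu <- function(cfg) max(unlist(cfg$intensity))

# Effective read-noise SD (default: 2% of the brightest mu).
sim_noise_sd <- function(cfg) {
  if (!is.null(cfg$noise_sd)) cfg$noise_sd else 0.02 * max_mu(cfg)
}

# Effective puncta increment (default: 3x the brightest mu).
sim_coloc_delta <- function(cfg) {
  if (!is.null(cfg$coloc_delta)) cfg$coloc_delta else 3 * max_mu(cfg)
}

# Resolve a per-condition/per-compartment parameter (scalar, vector or list).
resolve_by_condition <- function(x, condition,
                                 comps = c("nucleus", "cytoplasm", "nucleolus")) {
  if (is.list(x)) {
    if (is.null(x[[condition]]))
      stop("no entry for condition '", condition, "'")
    x <- x[[condition]]
  }
  if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, length(comps)), comps)
  out <- stats::setNames(numeric(length(comps)), comps)
  for (k in comps) out[k] <- if (k %in% names(x)) x[[k]] else 0
  out
}

# Rejection-sample non-overlapping cell centres.
place_cells <- function(n, field_size, radius, gap = 3, max_tries = 500L * n) {
  H <- field_size[1]; W <- field_size[2]
  min_d2 <- (2 * radius + gap)^2
  margin <- radius + 2
  if (H - 2 * margin <= 0 || W - 2 * margin <= 0)
    stop("field too crowded: field smaller than one cell")
  cx <- numeric(0); cy <- numeric(0); tries <- 0L
  while (length(cx) < n) {
    if (tries >= max_tries)
      stop("field too crowded: placed ", length(cx), " of ", n,
           " cells after ", tries, " tries")
    x <- stats::runif(1, margin, H - margin)
    y <- stats::runif(1, margin, W - margin)
    if (!length(cx) || all((cx - x)^2 + (cy - y)^2 >= min_d2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
    tries <- tries + 1L
  }
  cbind(row = cx, col = cy)
}

# Linear pixel indices of a rotated ellipse (row/col centre, semi-axes, angle).
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  ext <- max(a, b)
  r0 <- max(1L, floor(cr - ext)); r1 <- min(H, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(W, ceiling(cc + ext))
  rows <- r0:r1; cols <- c0:c1
  dr <- rep(rows - cr, times = length(cols))
  dc <- rep(cols - cc, each = length(rows))
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rows, times = length(cols))[inside]
  ccx <- rep(cols, each = length(rows))[inside]
  rr + (ccx - 1L) * H
}

# Correlated standard-normal draws: z_A, z_B with correlation rho via a
# shared latent factor at weight sqrt(|rho|).
correlated_z <- function(n, rho) {
  g <- stats::rnorm(n)
  s <- sqrt(abs(rho))
  zA <- s * g + sqrt(1 - abs(rho)) * stats::rnorm(n)
  zB <- (if (rho < 0) -s else s) * g + sqrt(1 - abs(rho)) * stats::rnorm(n)
  cbind(A = zA, B = zB)
}

#' Embed an asymmetric colocalization fraction into a pixel pool
#'
#' Draws two "positive" pixel sets A and B, uniformly placed within the given
#' compartment pixel pool, such that the fraction of B pixels that are also A
#' pixels equals `fraction` up to one pixel of rounding.
#'
#' @param pool integer vector of candidate pixel indices (one compartment).
#' @param n_a,n_b number of A-positive and B-positive pixels to draw.
#' @param fraction target `|A n B| / |B|` in `[0, 1]`.
#' @param compartment compartment name, used in error messages.
#' @return list with integer index vectors `a`, `b` and the realized
#'   `shared` count.
#' @export
embed_colocalization <- function(pool, n_a, n_b, fraction,
                                 compartment = "compartment") {
  stopifnot(fraction >= 0, fraction <= 1, n_a >= 0, n_b >= 0)
  shared <- floor(fraction * n_b + 0.5)
  if (shared > min(n_a, n_b))
    stop("infeasible colocalization fraction in ", compartment,
         ": need ", shared, " shared pixels but |A|=", n_a, ", |B|=", n_b)
  need <- n_a + n_b - shared
  if (need > length(pool))
    stop("infeasible colocalization fraction in ", compartment,
         ": pool of ", length(pool), " pixels cannot host ", need)
  idx <- if (need > 0) sample(pool, need) else integer(0)
  a <- idx[seq_len(n_a)]
  b <- c(idx[seq_len(shared)],
         if (n_b > shared) idx[n_a + seq_len(n_b - shared)] else integer(0))
  list(a = a, b = b, shared = shared)
}

#' Generate one synthetic multi-channel field with ground truth
#'
#' Places `n_cells` non-overlapping cells (elliptical cell outline, concentric
#' elliptical nucleus, disk nucleoli), draws per-cell brightness factors with
#' the configured cross-channel correlation, renders the DNA-stain and two
#' protein channels, optionally embeds colocalized puncta, then adds
#' background and noise. Identical `(config, condition, seed)` give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @param condition condition label; must have an intensity table in `config`.
#' @param seed random seed (default `config$seed`).
#' @param render if `FALSE`, skip image rendering and return geometry +
#'   per-cell true means only (fast path for population-level studies).
#' @return list with elements `field` (a [field_image()], or `NULL` when
#'   `render = FALSE`) and `truth` (class `ground_truth`: `masks`
#'   ([compartment_masks()]), `cells` data.frame of per-cell geometry,
#'   brightness factors and true compartment means, `realized_rho`,
#'   `coloc`/`puncta` when embedded, `condition`, `seed`, `saturated`).
#' @export
generate_field <- function(config, condition, seed = config$seed,
                           render = TRUE) {
  validate_sim_config(config)
  if (!condition %in% names(config$intensity))
    stop("unknown condition label: '", condition, "'")
  set.seed(seed)
  H <- config$field_size[1]; W <- config$field_size[2]
  n <- config$n_cells
  mu <- config$intensity[[condition]]
  channels <- names(mu)

  centres <- place_cells(n, config$field_size, config$cell_radius_range[2])
  cel <- matrix(0L, H, W); nuc <- matrix(0L, H, W); nol <- matrix(0L, H, W)
  geom <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- stats::runif(1, 0, pi)
    ca <- stats::runif(1, config$cell_radius_range[1], config$cell_radius_range[2])
    cb <- stats::runif(1, config$cell_radius_range[1], config$cell_radius_range[2])
    na_ <- stats::runif(1, config$nucleus_radius_range[1], config$nucleus_radius_range[2])
    nb_ <- stats::runif(1, config$nucleus_radius_range[1], config$nucleus_radius_range[2])
    cpix <- ellipse_pixels(centres[i, 1], centres[i, 2], ca, cb, theta, H, W)
    npix <- ellipse_pixels(centres[i, 1], centres[i, 2], na_, nb_, theta, H, W)
    cel[cpix] <- i; nuc[npix] <- i
    # nucleoli: disks fully inside the nucleus, pairwise separated
    k <- sample(seq(config$n_nucleoli_range[1], config$n_nucleoli_range[2]), 1)
    ncs <- matrix(numeric(0), ncol = 3)
    for (j in seq_len(k)) {
      r <- stats::runif(1, config$nucleolus_radius_range[1],
                        config$nucleolus_radius_range[2])
      placed <- FALSE
      for (try in 1:50) {
        u <- stats::runif(1, -(na_ - r - 2), na_ - r - 2)
        v <- stats::runif(1, -(nb_ - r - 2), nb_ - r - 2)
        if ((u / (na_ - r - 2))^2 + (v / (nb_ - r - 2))^2 > 1) next
        dr <- u * cos(theta) - v * sin(theta)
        dc <- u * sin(theta) + v * cos(theta)
        if (nrow(ncs) && any(sqrt((ncs[, 1] - (centres[i, 1] + dr))^2 +
                                  (ncs[, 2] - (centres[i, 2] + dc))^2) <
                             ncs[, 3] + r + 2)) next
        ncs <- rbind(ncs, c(centres[i, 1] + dr, centres[i, 2] + dc, r))
        placed <- TRUE; break
      }
      if (!placed) next
    }
    if (nrow(ncs)) for (j in seq_len(nrow(ncs))) {
      dpix <- ellipse_pixels(ncs[j, 1], ncs[j, 2], ncs[j, 3], ncs[j, 3], 0, H, W)
      nol[dpix] <- i
    }
    geom[[i]] <- c(row = centres[i, 1], col = centres[i, 2], theta = theta,
                   cell_a = ca, cell_b = cb, nucleus_a = na_, nucleus_b = nb_,
                   n_nucleoli = nrow(ncs))
  }
  cyt <- cel; cyt[nuc > 0] <- 0L
  masks <- compartment_masks(cel, nuc, nol, cyt)

  # per-cell brightness factors; A and B correlated per compartment
  comps <- c("nucleus", "cytoplasm", "nucleolus")
  rho <- resolve_by_condition(config$cross_cell_correlation, condition, comps)
  cv <- config$dispersion
  fac <- list()
  for (k in comps) {
    z <- correlated_z(n, rho[k])
    fac[[k]] <- list(A = pmax(1 + cv["A"] * z[, "A"], 0.05),
                     B = pmax(1 + cv["B"] * z[, "B"], 0.05),
                     dna = pmax(1 + cv["dna"] * stats::rnorm(n), 0.05))
  }

  cells <- data.frame(cell_id = seq_len(n), do.call(rbind, geom))
  for (ch in channels) for (k in comps)
    cells[[paste0("factor_", ch, "_", k)]] <- fac[[k]][[ch]]

  imgs <- NULL; puncta <- NULL; coloc_tab <- NULL; saturated <- FALSE
  f_target <- if (is.null(config$coloc_fraction)) NULL else
    resolve_by_condition(config$coloc_fraction, condition,
                         c("nucleus", "cytoplasm"))

  if (render) {
    imgs <- lapply(channels, function(ch) matrix(0, H, W))
    names(imgs) <- channels
    np_idx <- which(nuc > 0 & nol == 0)   # nucleoplasm
    no_idx <- which(nol > 0)
    cy_idx <- which(cyt > 0)
    for (ch in channels) {
      im <- imgs[[ch]]
      im[np_idx] <- mu[[ch]]["nucleus"]   * fac$nucleus[[ch]][nuc[np_idx]]
      im[no_idx] <- mu[[ch]]["nucleolus"] * fac$nucleolus[[ch]][nol[no_idx]]
      im[cy_idx] <- mu[[ch]]["cytoplasm"] * fac$cytoplasm[[ch]][cyt[cy_idx]]
      imgs[[ch]] <- im
    }
    if (!is.null(f_target)) {
      delta <- sim_coloc_delta(config)
      pA <- matrix(FALSE, H, W); pB <- matrix(FALSE, H, W)
      recs <- list()
      for (i in seq_len(n)) for (k in c("nucleus", "cytoplasm")) {
        pool <- if (k == "nucleus") which(nuc == i) else which(cyt == i)
        n_b <- floor(config$puncta_fraction * length(pool) + 0.5)
        n_a <- n_b
        emb <- embed_colocalization(pool, n_a, n_b, f_target[k], k)
        imgs$A[emb$a] <- imgs$A[emb$a] + delta
        imgs$B[emb$b] <- imgs$B[emb$b] + delta
        pA[emb$a] <- TRUE; pB[emb$b] <- TRUE
        recs[[length(recs) + 1]] <- data.frame(
          cell_id = i, compartment = k, n_a = n_a, n_b = n_b,
          shared = emb$shared,
          realized_fraction = if (n_b > 0) emb$shared / n_b else NA_real_)
      }
      coloc_tab <- do.call(rbind, recs)
      puncta <- list(A = pA, B = pB)
    }
    # per-cell true means from the clean rendering (exact, puncta included)
    for (ch in channels) {
      im <- imgs[[ch]]
      cells[[paste0("true_", ch, "_nucleoplasm")]] <-
        mean_by_label(im, ifelse(nol == 0, nuc, 0L), n)
      cells[[paste0("true_", ch, "_nucleolus")]]   <- mean_by_label(im, nol, n)
      cells[[paste0("true_", ch, "_cytoplasm")]]   <- mean_by_label(im, cyt, n)
      cells[[paste0("true_", ch, "_nucleus")]]     <- mean_by_label(im, nuc, n)
    }
    noise_sd <- sim_noise_sd(config)
    for (ch in channels) {
      im <- imgs[[ch]] + config$background_level
      if (isTRUE(config$poisson_noise)) im <- stats::rpois(length(im), pmax(im, 0))
      if (noise_sd > 0) im <- im + stats::rnorm(length(im), 0, noise_sd)
      im <- round(pmin(pmax(im, 0), ADU_MAX))
      if (any(im == ADU_MAX)) saturated <- TRUE
      imgs[[ch]] <- matrix(im, H, W)
    }
  } else {
    # analytic true means (no puncta possible without rendering)
    area_np <- tabulate(nuc[nuc > 0 & nol == 0], n)
    area_no <- tabulate(nol[nol > 0], n)
    for (ch in channels) {
      t_np <- mu[[ch]]["nucleus"] * fac$nucleus[[ch]]
      t_no <- mu[[ch]]["nucleolus"] * fac$nucleolus[[ch]]
      t_no[area_no == 0] <- NA_real_
      w <- area_no / pmax(area_np + area_no, 1)
      cells[[paste0("true_", ch, "_nucleoplasm")]] <- t_np
      cells[[paste0("true_", ch, "_nucleolus")]] <- t_no
      cells[[paste0("true_", ch, "_cytoplasm")]] <-
        mu[[ch]]["cytoplasm"] * fac$cytoplasm[[ch]]
      cells[[paste0("true_", ch, "_nucleus")]] <-
        (1 - w) * t_np + w * ifelse(is.na(t_no), 0, t_no)
    }
  }

  realized_rho <- vapply(comps, function(k)
    suppressWarnings(stats::cor(fac[[k]]$A, fac[[k]]$B)), numeric(1))

  truth <- structure(
    list(masks = masks, cells = cells, realized_rho = realized_rho,
         coloc = coloc_tab, puncta = puncta, condition = condition,
         seed = seed, config = config, saturated = saturated),
    class = "ground_truth")

  field <- NULL
  if (render)
    field <- field_image(imgs, pixel_area = config$pixel_area,
                         condition = condition, field_id = "sim")
  list(field = field, truth = truth)
}

# Mean image value per label (1..n); NA where a label has no pixels.
mean_by_label <- function(img, labels, n) {
  idx <- labels > 0
  s <- rep(NA_real_, n)
  if (!any(idx)) return(s)
  sums <- tapply(img[idx], labels[idx], sum)
  cnts <- tapply(rep(1, sum(idx)), labels[idx], sum)
  s[as.integer(names(sums))] <- sums / cnts
  s
}

# Deterministic per-(replicate, condition) seed derived from the master seed.
derive_seed <- function(master, replicate, cond_index) {
  as.integer((as.numeric(master) + 9973 * replicate + 409 * cond_index) %%
               2147483587)
}

#' Generate a full synthetic experiment on disk
#'
#' Writes one field per condition x replicate: three channel TIFFs, the
#' ground-truth label masks (16-bit TIFF), a per-cell truth CSV, plus a
#' manifest CSV (one row per channel file) and the realized simulation
#' parameters as JSON. Replicate seeds are derived deterministically from the
#' master seed, so a fixed master seed reproduces all files bit-identically.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param conditions ordered condition labels (default: all configured).
#' @param n_replicates number of independent replicate experiments
#'   (default 3).
#' @param master_seed master seed (default `config$seed`).
#' @return the manifest data.frame, invisibly. Ground-truth objects are
#'   returned in the `"truth"` attribute (named by field_id).
#' @export
generate_experiment <- function(config, out_dir,
                                conditions = names(config$intensity),
                                n_replicates = 3, master_seed = config$seed) {
  stopifnot(length(conditions) >= 1, n_replicates >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list(); truths <- list()
  for (r in seq_len(n_replicates)) {
    for (j in seq_along(conditions)) {
      cond <- conditions[j]
      seed <- derive_seed(master_seed, r, j)
      gf <- generate_field(config, cond, seed = seed)
      fid <- sprintf("r%02d_%s", r, cond)
      gf$field$field_id <- fid
      gf$field$replicate <- r
      paths <- write_field_tiff(gf$field, out_dir)
      for (ch in names(paths))
        rows[[length(rows) + 1]] <- data.frame(
          field_id = fid, condition = cond, replicate = r,
          channel = ch, path = unname(paths[ch]))
      write_mask_tiffs(gf$truth$masks, file.path(out_dir, paste0(fid, "_mask")))
      utils::write.csv(gf$truth$cells,
                       file.path(out_dir, paste0(fid, "_truth_cells.csv")),
                       row.names = FALSE)
      truths[[fid]] <- gf$truth
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  prov <- list(master_seed = master_seed, conditions = conditions,
               n_replicates = n_replicates, n_cells = config$n_cells,
               pixel_area = config$pixel_area)
  jsonlite::write_json(prov, file.path(out_dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "truth") <- truths
  invisible(manifest)
}

# Label masks as 16-bit TIFFs, one per layer.
write_mask_tiffs <- function(masks, prefix) {
  for (layer in c("cell", "nucleus", "nucleolus", "cytoplasm")) {
    EBImage::writeImage(EBImage::Image(masks[[layer]] / ADU_MAX),
                        paste0(prefix, "_", layer, ".tif"),
                        type = "tiff", bits.per.sample = 16L)
  }
  invisible(NULL)
}

#' Suggest fixed colocalization thresholds for a simulated condition
#'
#' For simulation studies with embedded puncta: returns, per protein channel,
#' the midpoint between an upper bound on the diffuse background-corrected
#' signal (brightest compartment mean times `1 + 4 cv`) and a lower bound on
#' the puncta intensity (dimmest compartment mean times `1 - 4 cv`, plus the
#' puncta increment). Any threshold in that gap separates puncta from diffuse
#' signal in every cell of every condition.
#'
#' @param config a [sim_config()] with `coloc_fraction` set.
#' @param conditions conditions the threshold must hold for (default: all).
#' @return named numeric vector `c(A = ..., B = ...)` in background-corrected
#'   ADU.
#' @export
coloc_threshold_suggest <- function(config,
                                    conditions = names(config$intensity)) {
  out <- c(A = NA_real_, B = NA_real_)
  delta <- sim_coloc_delta(config)
  for (ch in c("A", "B")) {
    cv <- config$dispersion[ch]
    mus <- unlist(lapply(conditions,
                         function(cd) config$intensity[[cd]][[ch]]))
    hi_diffuse <- max(mus) * (1 + 4 * cv)
    lo_puncta <- min(mus) * max(1 - 4 * cv, 0) + delta
    if (lo_puncta <= hi_diffuse)
      stop("puncta increment too small to separate channel ", ch,
           " puncta from diffuse signal with one global threshold")
    out[ch] <- (hi_diffuse + lo_puncta) / 2
  }
  out
}
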