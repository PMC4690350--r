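# Shared fixtures, built in code and memoized so expensive renderings are
# generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# 20-cell control field at default intensity/noise settings.
fixture_field <- function() {
  if (is.null(.fixtures$gf))
    .fixtures$gf <- generate_field(
      sim_config(n_cells = 20L, field_size = c(420L, 420L)),
      "control", seed = 99)
  .fixtures$gf
}

fixture_seg <- function() {
  if (is.null(.fixtures$seg))
    .fixtures$seg <- segment_field(fixture_field()$field)
  .fixtures$seg
}

# Noise-free, background-free, dispersion-free 6-cell field: rendered values
# equal the configured mu exactly.
fixture_clean <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- generate_field(clean_config(), "control", seed = 7)
  .fixtures$clean
}

clean_config <- function(...) {
  sim_config(n_cells = 6L, field_size = c(260L, 260L),
             dispersion = c(dna = 0, A = 0, B = 0),
             noise_sd = 0, background_level = 0, ...)
}

# Hand-built one-cell geometry: square nucleus inside a square cell.
toy_masks <- function(H = 40, W = 40) {
  cel <- matrix(0L, H, W); nuc <- matrix(0L, H, W)
  nol <- matrix(0L, H, W); cyt <- matrix(0L, H, W)
  cel[8:32, 8:32] <- 1L
  nuc[14:26, 14:26] <- 1L
  nol[18:20, 18:20] <- 1L
  cyt <- cel; cyt[nuc > 0] <- 0L
  compartment_masks(cel, nuc, nol, cyt)
}

toy_field <- function(vals = list(dna = 100, A = 20, B = 10),
                      masks = toy_masks(), condition = "control",
                      replicate = 1L) {
  chans <- lapply(vals, function(v) {
    img <- matrix(0, nrow(masks$cell), ncol(masks$cell))
    img[masks$cell > 0] <- v
    img
  })
  field_image(chans, condition = condition, replicate = replicate,
              field_id = paste0("toy_", condition, "_r", replicate))
}

# Measurement-like table straight from numbers (no imaging), for the
# normalization / statistics layers.
synth_measurements <- function(n_per = 20, conditions = c("control", "hs"),
                               replicates = 1:2, seed = 1, gen = NULL) {
  set.seed(seed)
  rows <- list()
  for (cond in conditions) for (r in replicates) {
    base <- if (is.null(gen)) NULL else gen(cond, r, n_per)
    df <- data.frame(field_id = paste0(cond, "_r", r), condition = cond,
                     replicate = r, cell_id = seq_len(n_per))
    if (is.null(base)) {
      for (col in c("A_nucleus", "A_cytoplasm", "A_nucleolus",
                    "B_nucleus", "B_cytoplasm", "B_nucleolus"))
        df[[col]] <- stats::rlnorm(n_per, log(100), 0.2)
      df$nc_A <- df$A_nucleus / df$A_cytoplasm
      df$nc_B <- df$B_nucleus / df$B_cytoplasm
    } else {
      df <- cbind(df, base)
    }
    rows[[length(rows) + 1]] <- df
  }
  do.call(rbind, rows)
}
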