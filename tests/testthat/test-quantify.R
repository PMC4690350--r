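test_that("constant compartments give exact means and ratios", {
  f <- toy_field(list(dna = 100, A = 20, B = 10))
  m <- measure_field(f, toy_masks(), min_cells = 0)
  expect_equal(m$A_nucleus, 20)
  expect_equal(m$A_cytoplasm, 20)
  expect_equal(m$nc_A, 1)
  # nucleus at 20, cytoplasm at 10: ratio 2
  f2 <- toy_field(list(dna = 100, A = 20, B = 10))
  f2$channels$A[toy_masks()$cytoplasm > 0] <- 10
  m2 <- measure_field(f2, toy_masks(), min_cells = 0)
  expect_equal(m2$A_nucleus, 20)
  expect_equal(m2$A_cytoplasm, 10)
  expect_equal(m2$nc_A, 2)
  # uniform image: every ratio 1
  expect_equal(m$nc_B, 1)
  # nucleolar mean reported, area bookkeeping in px and um^2
  expect_equal(m$area_nucleolus_px, 9)
  expect_equal(m$area_nucleus_um2, m$area_nucleus_px * 0.14)
})

test_that("measure_cell extracts one validated row", {
  f <- toy_field()
  row <- measure_cell(f, toy_masks(), 1)
  expect_equal(nrow(row), 1)
  expect_error(measure_cell(f, toy_masks(), 42), "not present")
})

test_that("measured means match ground truth within noise tolerance", {
  gf <- fixture_field()
  bg <- gf$truth$config$background_level
  fc <- gf$field
  fc$channels <- lapply(fc$channels, correct_background, background = bg)
  m <- measure_field(fc, gf$truth$masks, min_cells = 0)
  tr <- gf$truth$cells
  for (ch in c("A", "B")) {
    meas <- m[[paste0(ch, "_nucleus")]]
    truth <- tr[[paste0("true_", ch, "_nucleus")]][m$cell_id]
    se <- 4.8 / sqrt(m$area_nucleus_px)   # noise SD / sqrt(pixel count)
    expect_true(all(abs(meas - truth) < 6 * se + 0.05))
  }
})

test_that("control normalization yields unit control means per replicate", {
  meas <- synth_measurements(n_per = 30, conditions = c("control", "hs"),
                             replicates = 1:3, seed = 6)
  norm <- normalize_to_control(meas, "control")
  for (r in 1:3) {
    sel <- norm$condition == "control" & norm$replicate == r
    for (col in c("A_nucleus", "B_cytoplasm", "nc_A"))
      expect_equal(mean(norm[[col]][sel]), 1, tolerance = 1e-12)
  }
  # pooled control mean is 1 as well
  expect_equal(mean(norm$A_nucleus[norm$condition == "control"]), 1,
               tolerance = 1e-12)
  # linearity: a cell at twice the control mean normalizes to 2
  meas2 <- meas
  ctrl_mean <- mean(meas$A_nucleus[meas$condition == "control" &
                                     meas$replicate == 1])
  idx <- which(meas2$condition == "hs" & meas2$replicate == 1)[1]
  meas2$A_nucleus[idx] <- 2 * ctrl_mean
  norm2 <- normalize_to_control(meas2, "control")
  expect_equal(norm2$A_nucleus[idx], 2, tolerance = 1e-12)
  expect_error(normalize_to_control(meas, "missing"), "absent")
})

test_that("ascending profiles are sorted, stable and length-preserving", {
  meas <- data.frame(condition = "c", replicate = 1,
                     A_nucleus = c(3, 1, 2), nc_A = c(5, 5, 5))
  expect_equal(ascending_profile(meas, "A", "nucleus", "c"), c(1, 2, 3))
  expect_equal(ascending_profile(meas, "A", "nc", "c"), c(5, 5, 5))
  set.seed(2)
  v <- rnorm(57)
  meas2 <- data.frame(condition = "c", replicate = 1, A_nucleus = v)
  p <- ascending_profile(meas2, "A", "nucleus", "c")
  expect_length(p, 57)
  expect_equal(sort(v), p)
})

test_that("condition summaries compute mean and SEM per unit", {
  meas <- data.frame(condition = "c", replicate = c(1, 2, 3),
                     A_nucleus = c(1, 2, 3))
  s <- condition_summary(meas, unit = "cell")
  row <- s[s$quantity == "A_nucleus", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sem, 1 / sqrt(3), tolerance = 1e-4)  # 0.5774
  # identical replicates: SEM 0
  meas2 <- data.frame(condition = "c", replicate = rep(1:2, each = 3),
                      A_nucleus = rep(c(4, 5, 6), 2))
  s2 <- condition_summary(meas2, unit = "replicate")
  expect_equal(s2$sem[s2$quantity == "A_nucleus"], 0)
  # a single replicate leaves SEM undefined
  s3 <- condition_summary(meas2[meas2$replicate == 1, ], unit = "replicate")
  expect_true(is.na(s3$sem[s3$quantity == "A_nucleus"]))
})

test_that("gain and offset leave ratios and normalized values unchanged", {
  gf <- fixture_clean()
  f <- gf$field
  m0 <- measure_field(f, gf$truth$masks, min_cells = 0)
  # global gain on both protein channels
  fg <- f
  fg$channels$A <- 3.7 * f$channels$A
  fg$channels$B <- 3.7 * f$channels$B
  mg <- measure_field(fg, gf$truth$masks, min_cells = 0)
  expect_equal(mg$nc_A, m0$nc_A, tolerance = 1e-12)
  expect_equal(mg$nc_B, m0$nc_B, tolerance = 1e-12)
  n0 <- normalize_to_control(m0); ng <- normalize_to_control(mg)
  expect_equal(ng$A_nucleus, n0$A_nucleus, tolerance = 1e-12)
  # constant offset removed by background correction changes nothing
  fo <- f
  fo$channels <- lapply(f$channels, function(ch) ch + 25)
  bg <- estimate_background(fo$channels$A, gf$truth$masks$cell > 0)
  expect_equal(bg, 25, tolerance = 1e-9)
  fo$channels <- lapply(fo$channels, correct_background, background = 25)
  mo <- measure_field(fo, gf$truth$masks, min_cells = 0)
  expect_equal(mo$A_nucleus, m0$A_nucleus, tolerance = 1e-9)
  expect_equal(mo$nc_A, m0$nc_A, tolerance = 1e-9)
})

test_that("recovered N/C ratio is monotone in the configured enrichment", {
  cfg <- clean_config(n_cells = 8L, field_size = c(300L, 300L),
                      intensity = sim_config()$intensity)
  conds <- names(cfg$intensity)
  rec <- vapply(seq_along(conds), function(i) {
    gf <- generate_field(cfg, conds[i], seed = 50 + i)
    m <- measure_field(gf$field, gf$truth$masks, min_cells = 0)
    mean(m$nc_A)
  }, numeric(1))
  configured <- vapply(conds, function(cd) {
    mu <- cfg$intensity[[cd]]$A
    unname(mu["nucleus"] / mu["cytoplasm"])
  }, numeric(1))
  expect_equal(cor(rec, configured, method = "spearman"), 1)
  expect_true(all(diff(rec) > 0))
})
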