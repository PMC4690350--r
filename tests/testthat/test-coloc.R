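# Exhaustive-search Otsu over 256 bins: the independent oracle for the
# pooled-threshold method.
oracle_otsu <- function(x, levels = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(x, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (k in 1:(levels - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):levels])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- mids[k] }
  }
  best_t
}

test_that("thresholding is strict and monotone", {
  img <- matrix(c(1, 5, 9), 1, 3)
  expect_equal(as.vector(threshold_channel(img, 5)), c(FALSE, FALSE, TRUE))
  expect_true(all(threshold_channel(img, 0)))
  expect_false(any(threshold_channel(img, 10)))
  set.seed(4)
  big <- matrix(runif(500, 0, 100), 25, 20)
  low <- threshold_channel(big, 30); high <- threshold_channel(big, 60)
  expect_lte(sum(high), sum(low))
  expect_true(all(low[high]))   # raising the threshold only removes pixels
  expect_error(threshold_channel(big, -1), "non-negative")
})

test_that("fix_thresholds freezes per-channel scalars from control pools", {
  fixed <- fix_thresholds(list(), method = "fixed",
                          values = c(A = 42, B = 17))
  expect_equal(unname(fixed["A"]), 42)
  # bimodal pool: Otsu lands strictly between the modes and matches the
  # exhaustive-search oracle
  set.seed(12)
  pool <- c(rnorm(4000, 10, 1), rnorm(4000, 100, 5))
  pool <- pmax(pool, 0)
  f <- field_image(list(dna = matrix(pool, 80), A = matrix(pool, 80),
                        B = matrix(pool, 80)))
  th <- fix_thresholds(list(f), method = "otsu")
  expect_gt(th[["A"]], 10); expect_lt(th[["A"]], 100)
  # the between-class objective is flat across the empty gap between modes,
  # so any maximizer is a valid Otsu threshold: check the returned threshold
  # attains the oracle's maximal objective
  objective <- function(x, t, levels = 256) {
    rng <- range(x)
    breaks <- seq(rng[1], rng[2], length.out = levels + 1)
    h <- hist(x, breaks = breaks, plot = FALSE)$counts
    mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
    w0 <- sum(h[mids <= t]); w1 <- sum(h[mids > t])
    m0 <- sum((h * mids)[mids <= t]) / w0
    m1 <- sum((h * mids)[mids > t]) / w1
    w0 * w1 * (m0 - m1)^2
  }
  t_oracle <- oracle_otsu(pool)
  expect_equal(objective(pool, th[["A"]]), objective(pool, t_oracle),
               tolerance = 1e-6)
  # order invariance of the pooled histogram
  f2 <- f; f2$channels$A <- matrix(sample(pool), 80)
  expect_equal(fix_thresholds(list(f2), "otsu")[["A"]], th[["A"]])
  fconst <- f; fconst$channels$A <- matrix(5, 10, 10)
  expect_error(fix_thresholds(list(fconst), "otsu"), "constant")
  # percentile method
  expect_equal(fix_thresholds(list(f), "percentile", prob = 0.5)[["A"]],
               median(pool))
})

test_that("per-cell overlap percentages follow counting arithmetic", {
  masks <- toy_masks()
  roi_n <- masks$nucleus == 1
  full <- matrix(TRUE, 40, 40); none <- matrix(FALSE, 40, 40)
  rec <- coloc_per_cell(full, full, masks, 1)
  expect_equal(rec$pct_A_in_B, c(100, 100))
  expect_equal(rec$pct_B_in_A, c(100, 100))
  # disjoint masks: both percentages zero
  a <- none; b <- none
  idx_n <- which(roi_n)
  a[idx_n[1:20]] <- TRUE; b[idx_n[21:50]] <- TRUE
  rec2 <- coloc_per_cell(a, b, masks, 1)
  nrow_n <- rec2[rec2$compartment == "nucleus", ]
  expect_equal(nrow_n$pct_A_in_B, 0)
  expect_equal(nrow_n$pct_B_in_A, 0)
  # area_A = 10, area_B = 20, shared = 10 -> 100 / 50
  a <- none; b <- none
  a[idx_n[1:10]] <- TRUE; b[idx_n[1:20]] <- TRUE
  rec3 <- coloc_per_cell(a, b, masks, 1)
  nrow_n <- rec3[rec3$compartment == "nucleus", ]
  expect_equal(nrow_n$pct_A_in_B, 100)
  expect_equal(nrow_n$pct_B_in_A, 50)
  # zero denominator flags undefined, not zero
  rec4 <- coloc_per_cell(none, b, masks, 1)
  expect_true(all(is.na(rec4$pct_A_in_B)))
  expect_error(coloc_per_cell(a, b, masks, 99), "unknown cell_id")
})

test_that("the conservation identity holds exactly on random mask pairs", {
  masks <- toy_masks()
  set.seed(8)
  for (i in 1:200) {
    a <- matrix(runif(1600) < runif(1, 0.05, 0.9), 40, 40)
    b <- matrix(runif(1600) < runif(1, 0.05, 0.9), 40, 40)
    rec <- coloc_per_cell(a, b, masks, 1)
    ok <- !is.na(rec$pct_A_in_B) & !is.na(rec$pct_B_in_A)
    expect_equal(rec$pct_A_in_B[ok] * rec$area_A[ok],
                 rec$pct_B_in_A[ok] * rec$area_B[ok])
    expect_equal(rec$pct_A_in_B[ok] * rec$area_A[ok], 100 * rec$shared[ok])
    expect_true(all(rec$shared <= pmin(rec$area_A, rec$area_B)))
    # symmetry: swapping channels swaps areas and percentages
    swp <- coloc_per_cell(b, a, masks, 1)
    expect_equal(swp$area_A, rec$area_B)
    expect_equal(swp$pct_A_in_B, rec$pct_B_in_A)
  }
})

test_that("condition summaries flag small groups and skip undefined cells", {
  recs <- do.call(rbind, lapply(1:12, function(i)
    data.frame(field_id = "f", condition = ifelse(i <= 9, "small", "x"),
               replicate = 1, cell_id = i, compartment = "nucleus",
               area_A = 10, area_B = 10, shared = 10,
               pct_A_in_B = 100, pct_B_in_A = 100, pixel_area = 0.14)))
  out <- coloc_condition_summary(recs, control_condition = NULL)
  s <- out$summary
  expect_equal(s$mean[s$condition == "small" & s$direction == "A_in_B"], 100)
  expect_equal(s$sem[s$condition == "small" & s$direction == "A_in_B"], 0)
  expect_true(s$below_min[s$condition == "small"][1])   # 9 cells < 10
  # undefined percentages are excluded and counted
  recs$pct_B_in_A[1:3] <- NA
  out2 <- coloc_condition_summary(recs, control_condition = NULL)
  s2 <- out2$summary
  row <- s2[s2$condition == "small" & s2$direction == "B_in_A", ]
  expect_equal(row$n, 6)
  expect_equal(row$n_undefined, 3)
})
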