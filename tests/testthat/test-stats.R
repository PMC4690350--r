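# Brute-force oracles: definitional double-loop covariance, explicit SS
# decomposition. These stay independent of the implementations they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  cv <- 0
  for (i in seq_len(n)) cv <- cv + (x[i] - mean(x)) * (y[i] - mean(y))
  cv / (n - 1) / (sd(x) * sd(y))
}

oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  k <- length(groups); N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

test_that("pearson_r reproduces collinear and hand-computed cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  # deviations products sum to 3, sqrt(5 * 5) = 5
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
})

test_that("pearson_r matches the double-loop covariance oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:1000, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("pearson_r is affine-invariant and flags constant input", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(2.5 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(pearson_r(-3 * x + 1, y), -r, tolerance = 1e-12)
  expect_warning(rc <- pearson_r(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(rc))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1, 2), "at least 2")
})

test_that("linear_fit recovers exact lines and degenerate cases", {
  x <- c(0, 1, 2, 5)
  fit <- linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  fit0 <- linear_fit(x, rep(4, 4))
  expect_equal(fit0$slope, 0)
  expect_true(is.na(fit0$r_squared))      # SS_tot = 0: undefined, not 1
  expect_error(linear_fit(rep(2, 5), rnorm(5)), "constant x")
})

test_that("linear_fit agrees with lm and the R^2 = r^2 identity", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(50); y <- 1.3 * x + rnorm(50)
    fit <- linear_fit(x, y)
    ref <- lm(y ~ x)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$r_squared, pearson_r(x, y)^2, tolerance = 1e-10)
  }
})

test_that("one_way_anova reproduces hand-computed and degenerate cases", {
  eq <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(eq$f, 0)
  expect_equal(eq$p, 1)
  # SSB = 150, MSW = 1, df = (1, 4)
  f <- one_way_anova(list(a = c(1, 2, 3), b = c(11, 12, 13)))
  expect_equal(f$f, 150)
  flat <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_true(is.na(flat$f) && is.na(flat$p))
  expect_error(one_way_anova(list(ok = 1:3, tiny = 5)), "tiny")
})

test_that("one_way_anova matches aov and the two-group F = t^2 identity", {
  set.seed(17)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:30, 1), mean = j / 2))
    names(groups) <- paste0("g", seq_len(k))
    mine <- one_way_anova(groups)
    dat <- data.frame(v = unlist(groups),
                      g = rep(names(groups), lengths(groups)))
    ref <- summary(aov(v ~ g, dat))[[1]]
    expect_equal(mine$f, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
  a <- rnorm(12); b <- rnorm(15, 1)
  expect_equal(one_way_anova(list(a = a, b = b))$f,
               unname(t.test(a, b, var.equal = TRUE)$statistic)^2,
               tolerance = 1e-9)
})

test_that("bonferroni_vs_control multiplies, caps, and handles identity", {
  set.seed(23)
  groups <- list(ctl = rnorm(10), g1 = rnorm(10, 2), g2 = rnorm(10, 0.1),
                 g3 = rnorm(10), g4 = rnorm(10, 5))
  res <- bonferroni_vs_control(groups, "ctl")
  expect_equal(nrow(res), 4)
  expect_equal(res$p_adj, pmin(1, 4 * res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
  for (i in seq_len(nrow(res))) {
    ref <- t.test(groups[[res$group[i]]], groups$ctl, var.equal = TRUE)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_raw[i], ref$p.value, tolerance = 1e-12)
  }
  same <- bonferroni_vs_control(list(ctl = c(1, 2, 3), g = c(1, 2, 3)), "ctl")
  expect_equal(same$p_raw, 1)
  expect_equal(same$p_adj, 1)
  expect_error(bonferroni_vs_control(groups, "nope"), "not found")
})

test_that("significance stars follow the conventional cutpoints", {
  expect_equal(significance_stars(c(0.04, 0.009, 0.0009, 0.2)),
               c("*", "**", "***", ""))
})

test_that("correlation_table is invariant under dataset duplication", {
  meas <- synth_measurements(n_per = 40, conditions = "control",
                             replicates = 1, seed = 3)
  tab1 <- suppressWarnings(correlation_table(meas))
  tab2 <- suppressWarnings(correlation_table(rbind(meas, meas)))
  expect_equal(tab1$r, tab2$r, tolerance = 1e-12)
  expect_equal(tab1$quantity, c("nc", "nucleus", "cytoplasm"))
})

test_that("correlation_table recovers strong and null latent correlation", {
  gen <- function(cond, r, n) {
    z <- rnorm(n)
    rho <- if (cond == "corr") 0.9 else 0
    a <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
    b <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
    data.frame(A_nucleus = 100 + 10 * a, B_nucleus = 100 + 10 * b,
               A_cytoplasm = rnorm(n, 100), B_cytoplasm = rnorm(n, 100),
               A_nucleolus = NA_real_, B_nucleolus = NA_real_,
               nc_A = rnorm(n, 1, 0.1), nc_B = rnorm(n, 1, 0.1))
  }
  meas <- synth_measurements(n_per = 200, conditions = c("corr", "null"),
                             replicates = 1, seed = 8, gen = gen)
  tab <- suppressWarnings(correlation_table(meas))
  r_corr <- tab$r[tab$condition == "corr" & tab$quantity == "nucleus"]
  r_null <- tab$r[tab$condition == "null" & tab$quantity == "nucleus"]
  expect_gt(r_corr, 0.8)
  expect_lt(abs(r_null), 1.96 / sqrt(200))
})
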