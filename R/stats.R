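#' Pearson correlation coefficient
#'
#' Sample covariance over the product of sample standard deviations,
#' `r = cov(x, y) / (sd(x) sd(y))`. The n vs n-1 convention cancels between
#' numerator and denominator, so either gives the same r.
#'
#' @param x,y numeric vectors of equal length, n >= 2, finite.
#' @return r in `[-1, 1]`, or `NA` (with a warning) when either variable is
#'   constant — undefined, not zero.
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    warning("constant input: Pearson r undefined")
    return(NA_real_)
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  invisible(TRUE)
}

#' Ordinary least-squares line fit
#'
#' Fits `y = slope * x + intercept` by least squares and reports
#' `r_squared = 1 - SS_res / SS_tot`.
#'
#' @param x,y numeric vectors of equal length, n >= 2, finite; `x` must not
#'   be constant.
#' @return list of class `linear_fit` with `slope`, `intercept`, `r_squared`
#'   (`NA` when `y` is constant, i.e. `SS_tot = 0`) and `n`.
#' @export
linear_fit <- function(x, y) {
  check_paired(x, y)
  dx <- x - mean(x)
  sxx <- sum(dx^2)
  if (sxx == 0) stop("constant x: vertical fit undefined")
  slope <- sum(dx * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((y - (slope * x + intercept))^2) / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   (R^2 = %s, n = %d)\n", x$slope,
              x$intercept, format(x$r_squared, digits = 4), x$n))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F statistic with `(k - 1, N - k)`
#' degrees of freedom and p-value from the F distribution.
#'
#' @param groups named list of numeric vectors, one per group; at least two
#'   groups, each with n >= 2.
#' @return list of class `anova_result` with `f`, `p`, `df` (length-2),
#'   `group_means`, `group_sizes`. When all values are identical (0/0),
#'   `f` and `p` are `NA` flags.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  small <- names(groups)[sizes < 2]
  if (length(small))
    stop("group(s) with fewer than 2 values: ", paste(small, collapse = ", "))
  all_v <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(all_v))) stop("values must be finite")
  grand <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); N <- sum(sizes)
  df <- c(k - 1, N - k)
  if (ssw == 0 && ssb == 0) {
    f <- NA_real_; p <- NA_real_
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df[1]) / (ssw / df[2])
    p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  }
  structure(list(f = f, p = p, df = df, group_means = means,
                 group_sizes = sizes),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s\n", x$df[1], x$df[2],
              format(x$f, digits = 5), format(x$p, digits = 4)))
  invisible(x)
}

#' Bonferroni-adjusted pairwise t-tests against a control group
#'
#' Two-sided two-sample t-tests of each non-control group against the
#' control, with the raw p-values multiplied by the number of comparisons and
#' capped at 1 (classical Bonferroni post-hoc analysis).
#'
#' @param groups named list of numeric vectors.
#' @param control_label name of the control group; must be present.
#' @param welch use Welch's unequal-variance t-test instead of the classical
#'   equal-variance test (default `FALSE`).
#' @return data.frame with one row per non-control group: `group`, `t`,
#'   `p_raw`, `p_adj`, `stars` (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#' @export
bonferroni_vs_control <- function(groups, control_label, welch = FALSE) {
  if (!control_label %in% names(groups))
    stop("control group '", control_label, "' not found")
  ctrl <- groups[[control_label]]
  others <- setdiff(names(groups), control_label)
  m <- length(others)
  rows <- lapply(others, function(g) {
    tt <- two_sample_t(groups[[g]], ctrl, welch = welch)
    data.frame(group = g, t = tt$t, p_raw = tt$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p_raw)
  out$stars <- significance_stars(out$p_adj)
  out
}

# Two-sided two-sample t-test in closed form. Unlike stats::t.test this
# handles the zero-variance degenerate cases explicitly: equal means give
# t = 0, p = 1; different means with zero variance give p = 0.
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0)
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else NA_real_
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(m1 - m2) * Inf, p = 0, df = df))
  }
  t <- (m1 - m2) / sqrt(se2)
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE), df = df)
}

#' Significance stars at the conventional thresholds
#'
#' @param p numeric vector of p-values.
#' @return character vector: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#'   empty string otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-condition correlation grid for the two protein channels
#'
#' Pearson r between the matched single-cell values of channels A and B,
#' computed per condition for three quantities: the N/C ratio, the nuclear
#' mean and the cytoplasmic mean. Values are expected to be pooled across
#' replicates after per-replicate normalization (see
#' [normalize_to_control()]); raw tables are accepted too.
#'
#' @param measurements measurement table.
#' @param min_expected warn when a condition has fewer paired cells than this
#'   (default 115, the single-cell population size the analysis is designed
#'   for); any n >= 3 is accepted.
#' @return data.frame: `condition`, `quantity` (`nc`, `nucleus`,
#'   `cytoplasm`), `n`, `r`.
#' @export
correlation_table <- function(measurements, min_expected = 115) {
  quantities <- list(nc = c("nc_A", "nc_B"),
                     nucleus = c("A_nucleus", "B_nucleus"),
                     cytoplasm = c("A_cytoplasm", "B_cytoplasm"))
  rows <- list()
  for (cond in unique(measurements$condition)) {
    sub <- measurements[measurements$condition == cond, , drop = FALSE]
    for (q in names(quantities)) {
      cols <- quantities[[q]]
      ok <- stats::complete.cases(sub[, cols])
      x <- sub[[cols[1]]][ok]; y <- sub[[cols[2]]][ok]
      n <- length(x)
      if (n < 3) {
        warning("condition '", cond, "', quantity '", q, "': fewer than 3 cells")
        r <- NA_real_
      } else {
        if (n < min_expected)
          warning("condition '", cond, "', quantity '", q, "': only ", n,
                  " cells (", min_expected, " expected)")
        r <- pearson_r(x, y)
      }
      rows[[length(rows) + 1]] <- data.frame(condition = cond, quantity = q,
                                             n = n, r = r)
    }
  }
  do.call(rbind, rows)
}

#' Per-condition regression table for the two protein channels
#'
#' OLS fit of channel B on channel A per condition for the N/C ratio, the
#' nuclear mean and the cytoplasmic mean (the single-cell trendline summary).
#'
#' @param measurements measurement table (normalized recommended).
#' @return data.frame: `condition`, `quantity`, `n`, `slope`, `intercept`,
#'   `r_squared`.
#' @export
regression_table <- function(measurements) {
  quantities <- list(nc = c("nc_A", "nc_B"),
                     nucleus = c("A_nucleus", "B_nucleus"),
                     cytoplasm = c("A_cytoplasm", "B_cytoplasm"))
  rows <- list()
  for (cond in unique(measurements$condition)) {
    sub <- measurements[measurements$condition == cond, , drop = FALSE]
    for (q in names(quantities)) {
      cols <- quantities[[q]]
      ok <- stats::complete.cases(sub[, cols])
      x <- sub[[cols[1]]][ok]; y <- sub[[cols[2]]][ok]
      fit <- if (length(x) >= 2 && stats::sd(x) > 0) linear_fit(x, y) else
        list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, quantity = q, n = length(x), slope = fit$slope,
        intercept = fit$intercept, r_squared = fit$r_squared)
    }
  }
  do.call(rbind, rows)
}
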