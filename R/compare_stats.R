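# Method-comparison battery: Spearman rank correlation with t-approximation
# p-values, Bland-Altman analysis with bias tests, and mountain (folded
# empirical CDF) plots.

#' Spearman rank correlation with t-approximation significance
#'
#' Ranks (average ranks for ties) are Pearson-correlated; the p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom, the convention of the usual scientific-python
#' implementation.  `p < 0.05` is flagged significant.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return One-row tibble: `rho`, `statistic`, `p_value`, `n`, `significant`.
#'   Constant input yields `NA` values with a tie diagnostic message.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("spearman_cor: need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("spearman_cor: non-finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("spearman_cor: constant input; rho undefined (all ranks tied)")
    return(tibble(rho = NA_real_, statistic = NA_real_, p_value = NA_real_,
                  n = n, significant = NA))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-15) {
    stat <- sign(rho) * Inf
    p <- 0
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(stat), df = n - 2)
  }
  tibble(rho = rho, statistic = stat, p_value = p, n = n, significant = p < 0.05)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis z-scores into `K^2 = Z1^2 + Z2^2`,
#' referred to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return One-row tibble: `statistic`, `p_value`, `n`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) {
    warn("dagostino_pearson: omnibus test needs n >= 8; returning NA")
    return(tibble(statistic = NA_real_, p_value = NA_real_, n = n))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) return(tibble(statistic = NA_real_, p_value = NA_real_, n = n))
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) / sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  tibble(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE), n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `y - x` by default (documented orientation: second method
#' minus first).  Bias is the mean difference; the 95% limits of agreement
#' are `bias +/- 1.96 * sd(differences)` (assuming normally distributed
#' differences, which the attached omnibus normality test checks); a
#' one-sample t-test probes zero bias, and an ordinary least-squares
#' regression of the differences on the pair means tests for zero slope
#' (proportional bias).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3` (method A and B).
#' @param orientation `"y_minus_x"` (default) or `"x_minus_y"`.
#' @return Object of class `bland_altman` with `data` (tibble: mean, diff)
#'   and the test results; see [tidy.bland_altman()].
#' @export
bland_altman <- function(x, y, orientation = c("y_minus_x", "x_minus_y")) {
  orientation <- match.arg(orientation)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("bland_altman: need at least 3 pairs")
  d <- if (orientation == "y_minus_x") y - x else x - y
  mn <- (x + y) / 2
  bias <- mean(d)
  s <- sd(d)
  degenerate <- s < 1e-10  # exactly-offset methods up to float round-off
  loa <- bias + c(-1.96, 1.96) * s
  norm <- suppressWarnings(dagostino_pearson(d))
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
    reg <- list(slope = 0, slope_se = NA_real_, intercept = bias,
                intercept_se = NA_real_, slope_p = NA_real_)
  } else {
    t0 <- t.test(d, mu = 0)
    tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    if (sd(mn) == 0) {
      reg <- list(slope = NA_real_, slope_se = NA_real_, intercept = NA_real_,
                  intercept_se = NA_real_, slope_p = NA_real_)
    } else {
      fit <- lm(d ~ mn)
      sm <- summary(fit)$coefficients
      reg <- list(slope = sm[2, 1], slope_se = sm[2, 2],
                  intercept = sm[1, 1], intercept_se = sm[1, 2],
                  slope_p = sm[2, 4])
    }
  }
  structure(list(data = tibble(mean = mn, diff = d),
                 orientation = orientation, n = n,
                 bias = bias, sd_diff = s,
                 loa_low = loa[1], loa_high = loa[2],
                 normality_stat = norm$statistic, normality_p = norm$p_value,
                 t_stat = tt$statistic, t_p = tt$p.value,
                 slope = reg$slope, slope_se = reg$slope_se,
                 intercept = reg$intercept, intercept_se = reg$intercept_se,
                 slope_p = reg$slope_p, degenerate = degenerate),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.4g LoA=(%.4g, %.4g)%s\n",
              x$n, x$bias, x$loa_low, x$loa_high,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         normality_stat = x$normality_stat, normality_p = x$normality_p,
         t_stat = x$t_stat, t_p = x$t_p,
         slope = x$slope, slope_se = x$slope_se,
         intercept = x$intercept, intercept_se = x$intercept_se,
         slope_p = x$slope_p)
}

#' @export
glance.bland_altman <- function(x, ...) tidy(x)

#' Mountain plot (folded empirical CDF) of paired differences
#'
#' The empirical CDF `p_i = i/n` of the sorted differences is folded at the
#' median: the plotted value is `p_i` when `p_i <= 0.5` and `1 - p_i`
#' otherwise, producing a "mountain" peaking at the median.
#'
#' @param d Numeric vector of differences, `n >= 3`.
#' @return Object of class `mountain_plot`: `curve` (tibble: diff, ecdf,
#'   folded), `median`, `ci95` (2.5th/97.5th percentiles).
#' @export
mountain_plot <- function(d) {
  n <- length(d)
  if (n < 3) abort("mountain_plot: need at least 3 differences")
  ds <- sort(d)
  p <- seq_len(n) / n
  folded <- ifelse(p <= 0.5, p, 1 - p)
  structure(list(curve = tibble(diff = ds, ecdf = p, folded = folded),
                 median = median(d),
                 ci95 = quantile(d, c(0.025, 0.975), names = FALSE)),
            class = "mountain_plot")
}

#' @export
print.mountain_plot <- function(x, ...) {
  cat(sprintf("<mountain_plot> n=%d median=%.4g central 95%% (%.4g, %.4g)\n",
              nrow(x$curve), x$median, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Per-parameter agreement report between two morphometry tables
#'
#' Joins the two per-prism tables by prism id and computes, for each
#' requested parameter, the Spearman correlation, the Bland-Altman analysis
#' (with normality, zero-bias t-test and zero-slope regression) and the
#' mountain-plot summary.  The default parameter set is the five parameters
#' usually compared between modalities.
#'
#' @param tbl_a,tbl_b Tibbles with a `prism` id column and parameter columns
#'   (method A = reference, e.g. microCT; method B = histology).
#' @param parameters Character vector of parameter column names.
#' @param orientation Difference orientation for [bland_altman()]; the
#'   default is method B minus method A (histology minus microCT).
#' @return Object of class `agreement_report`: `table` (one row per
#'   parameter), plus stored `bland_altman` and `mountain_plot` objects per
#'   parameter for plotting.
#' @export
build_agreement_report <- function(tbl_a, tbl_b,
                                   parameters = c("BV/TV", "BS/TV", "Tb.Pf",
                                                  "Tb.Th", "Tb.Sp"),
                                   orientation = "y_minus_x") {
  if (!("prism" %in% names(tbl_a)) || !("prism" %in% names(tbl_b)))
    abort("build_agreement_report: both tables need a `prism` id column")
  only_a <- setdiff(tbl_a$prism, tbl_b$prism)
  only_b <- setdiff(tbl_b$prism, tbl_a$prism)
  if (length(only_a) || length(only_b))
    abort(paste0("build_agreement_report: unmatched prism ids: ",
                 paste(c(only_a, only_b), collapse = ", ")))
  missing_cols <- setdiff(parameters, intersect(names(tbl_a), names(tbl_b)))
  if (length(missing_cols))
    abort(paste0("build_agreement_report: parameter column(s) not present: ",
                 paste(missing_cols, collapse = ", ")))
  joined <- dplyr::inner_join(
    dplyr::select(tbl_a, "prism", dplyr::all_of(parameters)),
    dplyr::select(tbl_b, "prism", dplyr::all_of(parameters)),
    by = "prism", suffix = c("_a", "_b"))
  ba_list <- list(); mp_list <- list()
  rows <- lapply(parameters, function(p) {
    xa <- joined[[paste0(p, "_a")]]
    xb <- joined[[paste0(p, "_b")]]
    keep <- is.finite(xa) & is.finite(xb)
    xa <- xa[keep]; xb <- xb[keep]
    sp <- suppressWarnings(spearman_cor(xa, xb))
    ba <- bland_altman(xa, xb, orientation)
    mp <- mountain_plot(ba$data$diff)
    ba_list[[p]] <<- ba
    mp_list[[p]] <<- mp
    dplyr::bind_cols(tibble(parameter = p, n = length(xa),
                            rho = sp$rho, rho_p = sp$p_value),
                     tidy(ba)[, -1],
                     tibble(median_diff = mp$median,
                            ci_low = mp$ci95[1], ci_high = mp$ci95[2]))
  })
  structure(list(table = dplyr::bind_rows(rows),
                 bland_altman = ba_list, mountain = mp_list,
                 orientation = orientation),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  print(dplyr::select(x$table, "parameter", "n", "rho", "rho_p", "bias",
                      "loa_low", "loa_high"))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) x$table

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(n_parameters = nrow(x$table), mean_rho = mean(x$table$rho),
         n_significant = sum(x$table$rho_p < 0.05))
}
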