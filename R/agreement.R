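#' Paired measurements of one parameter by two systems
#'
#' Holds pairwise-aligned measurements of the same quantity by a reference
#' system and a test system (same units). Differences are always taken as
#' test minus reference, so a positive bias means the test system reads high.
#'
#' @param x_ref,x_test Equal-length numeric vectors (length >= 3), aligned by
#'   stride or subject.
#' @param label Parameter name used in reports.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(x_ref, x_test, label = "parameter") {
  stopifnot(is.numeric(x_ref), is.numeric(x_test))
  if (length(x_ref) != length(x_test))
    stop("x_ref and x_test must have equal length")
  if (length(x_ref) < 3L) stop("at least 3 pairs are required")
  structure(list(x_ref = as.numeric(x_ref), x_test = as.numeric(x_test),
                 label = label),
            class = "paired_measurements")
}

#' Normality test
#'
#' One-sample Kolmogorov-Smirnov test against a normal law with mean and SD
#' estimated from the sample, the gate used throughout the agreement pipeline
#' (normal at p >= 0.05). Estimating the parameters makes the raw KS p-value
#' conservative; set `lilliefors = TRUE` to use the Lilliefors correction
#' instead (requires the `nortest` package).
#'
#' @param values Numeric sample, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param lilliefors Use the Lilliefors-corrected test.
#' @return A list with `is_normal` and `p` (`NA` for a degenerate constant
#'   sample, which is reported non-normal).
#' @export
normality_test <- function(values, alpha = 0.05, lilliefors = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("normality test needs at least 3 values")
  if (stats::sd(values) == 0)
    return(list(is_normal = FALSE, p = NA_real_))
  p <- if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the nortest package is required for lilliefors = TRUE")
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  }
  list(is_normal = p >= alpha, p = p)
}

#' Fixed-bias test on paired differences
#'
#' Tests whether the differences are centred on zero: a one-sample t-test
#' when they are normally distributed, otherwise a Wilcoxon signed-rank test
#' with the zero-inclusive (Pratt) treatment — zeros keep their ranks in the
#' ranking of `|D|` but contribute nothing to the statistic; the variance is
#' the exact conditional variance `sum(rank^2)` over the non-zero
#' differences, with a normal approximation for the p-value.
#'
#' @param D Differences (test minus reference).
#' @param normal Are the differences normal? (gate from [normality_test()]).
#' @return The p-value (1 when all differences are zero).
#' @export
fixed_bias_test <- function(D, normal) {
  D <- D[!is.na(D)]
  if (all(D == 0)) return(1)
  if (normal) return(stats::t.test(D, mu = 0)$p.value)
  r <- rank(abs(D))
  nz <- D != 0
  T_stat <- sum(sign(D[nz]) * r[nz])
  v <- sum(r[nz]^2)
  2 * stats::pnorm(-abs(T_stat) / sqrt(v))
}

#' Proportional-bias test
#'
#' Correlates the paired differences `D` against the paired averages `A`:
#' Pearson when both are normally distributed, Spearman otherwise. A
#' significant correlation means the disagreement grows (or shrinks) with the
#' magnitude of the measured quantity, in which case the limits of agreement
#' should be corrected to lines.
#'
#' @param D,A Differences and averages of the paired measurements.
#' @param normal_both Are both `D` and `A` normal?
#' @return A list with the correlation `r` and its p-value (constant input
#'   returns `r = 0`, `p = 1` by convention).
#' @export
proportional_bias_test <- function(D, A, normal_both) {
  ok <- !is.na(D) & !is.na(A)
  D <- D[ok]; A <- A[ok]
  if (stats::sd(D) == 0 || stats::sd(A) == 0)
    return(list(r = 0, p = 1))
  method <- if (normal_both) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(A, D, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Classic Bland-Altman limits of agreement
#'
#' Constant 95% limits for the paired differences: mean +/- 1.96 SD under
#' normality, otherwise the empirical 2.5th and 97.5th percentiles
#' (linear-interpolation quantiles).
#'
#' @param D Differences (test minus reference).
#' @param normal Are the differences normal?
#' @return `c(lower, upper)`.
#' @export
loa_classic <- function(D, normal) {
  D <- D[!is.na(D)]
  if (normal) {
    m <- mean(D); s <- stats::sd(D)
    c(lower = m - 1.96 * s, upper = m + 1.96 * s)
  } else {
    stats::setNames(stats::quantile(D, c(0.025, 0.975), names = FALSE, type = 7),
                    c("lower", "upper"))
  }
}

#' Parametric correction of the limits of agreement
#'
#' When the bias is proportional to the measured magnitude, the
#' perfect-agreement (PA) line is fitted by least squares,
#' `D-hat = b1 A + b0`, and the limits are drawn parallel to it at
#' `+/- 1.96 sqrt(pi/2) mean(|R|)`, where `R` are the regression residuals.
#' For normal residuals `E|R| = sigma sqrt(2/pi)`, so the half-width equals
#' the familiar `1.96 sigma`.
#'
#' @param D,A Differences and averages of the paired measurements.
#' @return A list with `pa_line`, `lower`, `upper` (each
#'   `c(intercept, slope)`) and `half_width`.
#' @export
loa_parametric_corrected <- function(D, A) {
  ok <- !is.na(D) & !is.na(A)
  D <- D[ok]; A <- A[ok]
  if (length(D) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(A) == 0) stop("A is constant: the regression is undefined")
  fit <- stats::lm.fit(cbind(1, A), D)
  b <- unname(fit$coefficients)
  h <- 1.96 * sqrt(pi / 2) * mean(abs(fit$residuals))
  list(pa_line = c(intercept = b[1], slope = b[2]),
       lower = c(intercept = b[1] - h, slope = b[2]),
       upper = c(intercept = b[1] + h, slope = b[2]),
       half_width = h)
}

# Linear quantile regression of y on x by pinball-loss minimisation.
# The pinball objective profiled over the slope is convex (partial
# minimisation of a jointly convex function), so the slope is found by
# golden-section search and the intercept is the type-1 empirical quantile of
# the residuals, which minimises the pinball loss exactly.
fit_quantile_line <- function(x, y, tau) {
  pinball <- function(r) sum(r * (tau - (r < 0)))
  intercept_for <- function(b1) stats::quantile(y - b1 * x, tau, type = 1, names = FALSE)
  profile_loss <- function(b1) {
    r <- y - b1 * x
    pinball(r - stats::quantile(r, tau, type = 1, names = FALSE))
  }
  if (stats::sd(x) == 0) return(c(intercept = intercept_for(0), slope = 0))
  b_ls <- stats::cov(x, y) / stats::var(x)
  span <- 5 * (abs(b_ls) + stats::sd(y) / stats::sd(x)) + 1
  opt <- stats::optimize(profile_loss, lower = b_ls - span, upper = b_ls + span,
                         tol = 1e-9 * (1 + abs(b_ls)))
  b1 <- opt$minimum
  c(intercept = intercept_for(b1), slope = b1)
}

#' Quantile-regression correction of the limits of agreement
#'
#' Nonparametric counterpart of [loa_parametric_corrected()]: linear quantile
#' regression of `D` on `A` at tau = 0.025, 0.50 and 0.975. The median line
#' is the perfect-agreement line; the outer quantile lines are the lower and
#' upper limits of agreement.
#'
#' @param D,A Differences and averages of the paired measurements.
#' @return A list with `pa_line`, `lower`, `upper`, each `c(intercept, slope)`.
#' @export
loa_quantile_corrected <- function(D, A) {
  ok <- !is.na(D) & !is.na(A)
  D <- D[ok]; A <- A[ok]
  if (length(D) < 10L)
    warning("fewer than 10 pairs: quantile limit lines are unstable")
  list(pa_line = fit_quantile_line(A, D, 0.50),
       lower = fit_quantile_line(A, D, 0.025),
       upper = fit_quantile_line(A, D, 0.975))
}

#' Intraclass correlation coefficient, two-way random, absolute agreement
#'
#' ICC under the two-way random-effects, absolute-agreement model
#' (Shrout-Fleiss conventions), computed from the two-way mean squares:
#' single-measure ICC(2,1) for one-stride comparisons and average-measure
#' ICC(2,k) for multi-stride averages. The attached interpretation follows
#' the usual bands: excellent > 0.750, good 0.600-0.749, fair 0.400-0.599,
#' poor < 0.400.
#'
#' @param x_ref,x_test Paired measurements (the two "raters").
#' @param form `"2,1"` or `"2,k"`.
#' @return A list with `icc`, `form` and `interpretation`.
#' @export
icc <- function(x_ref, x_test, form = c("2,1", "2,k")) {
  form <- match.arg(form)
  ok <- !is.na(x_ref) & !is.na(x_test)
  m <- cbind(x_ref[ok], x_test[ok])
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("at least 3 pairs are required")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2) /
    ((n - 1) * (k - 1))
  val <- if (form == "2,1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  list(icc = val, form = form, interpretation = interpret_icc(val))
}

interpret_icc <- function(v) {
  if (is.na(v)) return(NA_character_)
  if (v > 0.750) "excellent" else if (v >= 0.600) "good"
  else if (v >= 0.400) "fair" else "poor"
}

#' Kendall's coefficient of concordance for two raters
#'
#' Kendall's W over `m = 2` raters with the tie correction (average ranks;
#' the tie term is subtracted from the denominator) — with a 10 ms temporal
#' resolution tied measurements are guaranteed. W is invariant under a common
#' strictly monotone transformation of both series. The attached
#' interpretation follows the usual bands: strong > 0.600, moderate
#' 0.300-0.599, weak 0.100-0.299, almost none < 0.100.
#'
#' @param x_ref,x_test Paired measurements (the two "raters").
#' @return A list with `W` and `interpretation`.
#' @export
kendalls_w <- function(x_ref, x_test) {
  ok <- !is.na(x_ref) & !is.na(x_test)
  ratings <- rbind(rank(x_ref[ok]), rank(x_test[ok]))
  m <- nrow(ratings); n <- ncol(ratings)
  if (n < 3L) stop("at least 3 pairs are required")
  totals <- colSums(ratings)
  s <- sum((totals - mean(totals))^2)
  tie_term <- sum(apply(ratings, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) / 12 - m * tie_term / 12
  w <- if (denom <= 0) NA_real_ else s / denom
  list(W = w, interpretation = interpret_w(w))
}

interpret_w <- function(v) {
  if (is.na(v)) return(NA_character_)
  if (v > 0.600) "strong" else if (v >= 0.300) "moderate"
  else if (v >= 0.100) "weak" else "almost none"
}

#' Full method-comparison pipeline
#'
#' Runs the complete gated statistics flow on one parameter's paired
#' measurements:
#' normality gates (KS) on the differences, averages and both raw series;
#' accuracy and precision as mean/SD when the differences are normal, else
#' median and quartile deviation `(Q3 - Q1) / 2`; the fixed-bias test
#' (t-test or zero-inclusive Wilcoxon); the proportional-bias test (Pearson
#' or Spearman of `D` against `A`); limits of agreement — classic constants,
#' upgraded to parallel regression lines (parametric) when `D` and `A` are
#' normal with a significant proportional bias, or to quantile-regression
#' lines otherwise; and the agreement coefficient — ICC(2,1) (or ICC(2,k)
#' with `multi_stride = TRUE`) when both raw series are normal, else
#' Kendall's W.
#'
#' @param pairs A [paired_measurements()].
#' @param multi_stride Are the values multi-stride averages? Selects
#'   ICC(2,k) over ICC(2,1) on the normal branch.
#' @param alpha Significance level for every gate (default 0.05).
#' @return A list of class `agreement_report`.
#' @export
run_agreement_pipeline <- function(pairs, multi_stride = FALSE, alpha = 0.05) {
  stopifnot(inherits(pairs, "paired_measurements"))
  D <- pairs$x_test - pairs$x_ref
  A <- (pairs$x_test + pairs$x_ref) / 2
  nt_d <- normality_test(D, alpha)
  nt_a <- normality_test(A, alpha)
  nt_ref <- normality_test(pairs$x_ref, alpha)
  nt_test <- normality_test(pairs$x_test, alpha)
  normal_d <- nt_d$is_normal
  normal_da <- normal_d && nt_a$is_normal
  normal_both <- nt_ref$is_normal && nt_test$is_normal

  accuracy <- if (normal_d) mean(D) else stats::median(D)
  precision <- if (normal_d) stats::sd(D) else
    unname(diff(stats::quantile(D, c(0.25, 0.75), type = 7))) / 2

  fb_p <- fixed_bias_test(D, normal_d)
  pb <- proportional_bias_test(D, A, normal_da)

  if (pb$p < alpha && stats::sd(A) > 0) {
    if (normal_da) {
      loa <- loa_parametric_corrected(D, A)
      loa_method <- "parametric-corrected"
    } else {
      loa <- loa_quantile_corrected(D, A)
      loa_method <- "quantile-corrected"
    }
    loa_lower <- loa$lower; loa_upper <- loa$upper; pa_line <- loa$pa_line
  } else {
    lim <- loa_classic(D, normal_d)
    loa_method <- if (normal_d) "classic-normal" else "classic-percentile"
    loa_lower <- c(intercept = unname(lim["lower"]), slope = 0)
    loa_upper <- c(intercept = unname(lim["upper"]), slope = 0)
    pa_line <- c(intercept = accuracy, slope = 0)
  }

  if (normal_both) {
    co <- icc(pairs$x_ref, pairs$x_test, if (multi_stride) "2,k" else "2,1")
    coefficient <- co$icc
    coefficient_method <- paste0("ICC(", co$form, ")")
    interpretation <- co$interpretation
  } else {
    co <- kendalls_w(pairs$x_ref, pairs$x_test)
    coefficient <- co$W
    coefficient_method <- "Kendall's W"
    interpretation <- co$interpretation
  }

  structure(list(
    label = pairs$label, n = length(D),
    normal_d = normal_d, normal_both = normal_both,
    normality_p = c(D = nt_d$p, A = nt_a$p, ref = nt_ref$p, test = nt_test$p),
    accuracy = accuracy, precision = precision,
    fixed_bias_p = fb_p,
    prop_bias_r = pb$r, prop_bias_p = pb$p,
    loa_method = loa_method,
    loa_lower = loa_lower, loa_upper = loa_upper,
    pa_line = pa_line,
    coefficient = coefficient,
    coefficient_method = coefficient_method,
    interpretation = interpretation), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  differences %s; accuracy %.4g, precision %.4g\n",
              if (x$normal_d) "normal (mean/SD)" else "non-normal (median/QD)",
              x$accuracy, x$precision))
  cat(sprintf("  fixed bias p = %.3g; proportional bias r = %.3f (p = %.3g)\n",
              x$fixed_bias_p, x$prop_bias_r, x$prop_bias_p))
  cat(sprintf("  LoA [%s]: lower %.4g + %.4g A, upper %.4g + %.4g A\n",
              x$loa_method, x$loa_lower[["intercept"]], x$loa_lower[["slope"]],
              x$loa_upper[["intercept"]], x$loa_upper[["slope"]]))
  cat(sprintf("  %s = %.3f (%s)\n", x$coefficient_method, x$coefficient,
              x$interpretation))
  invisible(x)
}
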