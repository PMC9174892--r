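#' Paired rest-versus-stress comparison with normality gating
#'
#' Applies a Shapiro-Wilk test to the paired differences; if normality is
#' not rejected at `alpha_normality` a paired t-test is used, otherwise a
#' Wilcoxon signed-rank test. Two-sided throughout.
#'
#' @param rest,stress equal-length paired numeric vectors, `n >= 3`.
#' @param alpha_normality significance level of the normality gate.
#' @return an object of class `paired_test`: `test_used` (`"paired-t"` or
#'   `"wilcoxon"`), `statistic`, `p_value`, `normality_p`, `n`,
#'   `degenerate` (`TRUE` when all differences are identical; no p-value is
#'   reported then).
#' @export
paired_compare <- function(rest, stress, alpha_normality = 0.05) {
  stopifnot(length(rest) == length(stress))
  n <- length(rest)
  if (n < 3) stop("paired comparison needs n >= 3")
  d <- stress - rest
  if (diff(range(d)) <= 1e-10 * max(1, abs(mean(d)))) {
    # zero-variance differences: no distributional test is possible. A
    # constant nonzero shift is an infinite paired-t statistic (p -> 0);
    # identical vectors give no evidence at all.
    shifted <- d[1] != 0
    return(structure(list(test_used = if (shifted) "paired-t" else NA_character_,
                          statistic = if (shifted) Inf * sign(d[1]) else NA_real_,
                          p_value = if (shifted) 0 else NA_real_,
                          normality_p = NA_real_,
                          n = n, degenerate = TRUE),
                     class = "paired_test"))
  }
  norm_p <- stats::shapiro.test(d)$p.value
  if (norm_p >= alpha_normality) {
    ht <- stats::t.test(stress, rest, paired = TRUE)
    used <- "paired-t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(stress, rest, paired = TRUE))
    used <- "wilcoxon"
  }
  structure(list(test_used = used, statistic = unname(ht$statistic),
                 p_value = ht$p.value, normality_p = norm_p, n = n,
                 degenerate = FALSE),
            class = "paired_test")
}

#' Inter-region comparison with normality-gated post-hoc tests
#'
#' Per-group Shapiro-Wilk tests gate the procedure: if no group rejects
#' normality at `alpha_normality`, a one-way ANOVA with Tukey's HSD post-hoc
#' is used; otherwise Kruskal-Wallis with Dunn's post-hoc (with tie
#' correction and, by default, Bonferroni adjustment of the pairwise
#' p-values).
#'
#' @param values_by_region named list of numeric vectors, one per group,
#'   each with `n >= 3`.
#' @param alpha_normality significance level of the normality gate.
#' @param dunn_adjust p-value adjustment for Dunn's pairwise tests (a
#'   `p.adjust` method).
#' @return an object of class `region_test`: `method` (`"anova-tukey"` or
#'   `"kruskal-dunn"`), `omnibus_p`, `pairwise` (data frame with `group1`,
#'   `group2`, `p_adj`), `normality_p` (named), `degenerate`.
#' @export
region_compare <- function(values_by_region, alpha_normality = 0.05,
                           dunn_adjust = "bonferroni") {
  stopifnot(is.list(values_by_region), length(values_by_region) >= 2)
  ns <- lengths(values_by_region)
  if (any(ns < 3)) stop("every group needs n >= 3")
  if (is.null(names(values_by_region))) {
    names(values_by_region) <- paste0("G", seq_along(values_by_region))
  }
  g_names <- names(values_by_region)
  x <- unlist(values_by_region, use.names = FALSE)
  g <- factor(rep(g_names, ns), levels = g_names)
  pairs <- utils::combn(g_names, 2)

  if (stats::sd(x) == 0) {
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_adj = 1)
    return(structure(list(method = NA_character_, omnibus_p = 1,
                          pairwise = pw, normality_p = NULL,
                          degenerate = TRUE),
                     class = "region_test"))
  }

  norm_p <- vapply(values_by_region, function(v) {
    if (stats::sd(v) == 0) return(0)  # constant group: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))

  if (all(norm_p >= alpha_normality)) {
    fit <- stats::aov(x ~ g)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    key <- paste(pairs[2, ], pairs[1, ], sep = "-")
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p_adj = tk[key, "p adj"])
    method <- "anova-tukey"
  } else {
    omnibus <- stats::kruskal.test(x, g)$p.value
    pw <- dunn_pairwise(x, g, pairs, adjust = dunn_adjust)
    method <- "kruskal-dunn"
  }
  rownames(pw) <- NULL
  structure(list(method = method, omnibus_p = omnibus, pairwise = pw,
                 normality_p = norm_p, degenerate = FALSE),
            class = "region_test")
}

# Dunn's rank-based pairwise z-tests with tie correction.
dunn_pairwise <- function(x, g, pairs, adjust = "bonferroni") {
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt(s2 * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_adj = pmin(p, 1))
}

#' Fold change of a stress mean over a rest mean
#'
#' Ratio `mean_stress / mean_rest`, rounded half-up to one decimal, the
#' convention used for printed fold increases.
#'
#' @param mean_rest rest mean (> 0).
#' @param mean_stress stress mean.
#' @param digits decimals for the half-up rounding; `NULL` for the raw ratio.
#' @return the (rounded) ratio.
#' @export
fold_change <- function(mean_rest, mean_stress, digits = 1) {
  if (any(mean_rest <= 0)) stop("mean_rest must be positive")
  r <- mean_stress / mean_rest
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression summary used for relating peak total TKE to
#' cardiac output, stroke volume and heart rate: slope, intercept,
#' `R^2 = 1 - SSres/SStot` and the two-sided p-value of the slope's
#' t-statistic.
#'
#' @param x,y numeric vectors, `n >= 3`; `x` must not be constant.
#' @return an object of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("linear fit needs n >= 3")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  # exact linear data triggers the "essentially perfect fit" warning; a
  # perfect fit is a legitimate input here (R^2 = 1)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = n),
            class = "linear_fit")
}

#' Intraclass correlation: two-way model, absolute agreement, average measures
#'
#' ICC(A,k) in the McGraw & Wong nomenclature (the "2-way mixed-effects,
#' absolute-agreement, mean-rating" estimate used for observer variability):
#' from the two-way mean squares with subjects as rows and raters as
#' columns, `icc = (MSR - MSE) / (MSR + (MSC - MSE)/n)`. Confidence bounds
#' follow McGraw & Wong's F-based interval with a Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param ratings numeric matrix, subjects in rows (`n >= 5`), raters in
#'   columns (`k >= 2`).
#' @param conf confidence level for the bounds.
#' @return an object of class `icc_result`: `icc`, `lower`, `upper`,
#'   `model` (descriptor string), `n`, `k`, `degenerate` (`TRUE` with
#'   `icc = 1` when all ratings are identical).
#' @export
icc_agreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("ICC needs at least 5 subjects")
  if (k < 2) stop("ICC needs at least 2 raters")
  if (anyNA(ratings)) stop("ratings must be complete")
  model <- "two-way mixed, absolute agreement, average measures (ICC A,k)"
  if (stats::sd(as.vector(ratings)) == 0) {
    return(structure(list(icc = 1, lower = NA_real_, upper = NA_real_,
                          model = model, n = n, k = k, degenerate = TRUE),
                     class = "icc_result"))
  }
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  grand <- mean(ratings)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))

  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r1) r1 * k / (1 + (k - 1) * r1)  # Spearman-Brown step-up
  structure(list(icc = icc_k, lower = sb(l1), upper = sb(u1),
                 model = model, n = n, k = k, degenerate = FALSE),
            class = "icc_result")
}

#' Cardiac output from heart rate and stroke volume
#'
#' `CO = HR * SV / 1000` (L/min), rounded half-up to `digits` decimals for
#' reporting (`NULL` for the raw value).
#'
#' @param hr heart rate (bpm).
#' @param sv stroke volume (ml).
#' @param digits decimals; default 1 as printed in clinical tables.
#' @return cardiac output (L/min).
#' @export
derived_co <- function(hr, sv, digits = 1) {
  stopifnot(all(hr > 0), all(sv > 0))
  co <- hr * sv / 1000
  if (is.null(digits)) co else round_half_up(co, digits)
}
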