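#' Correlation between gene and genome ANI
#'
#' Pearson product-moment and Spearman rank correlations (average ranks for
#' ties) between two matched ANI vectors, e.g. ANIm vs ANIstt over the same
#' strain pairs.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble with `pearson_r`, `spearman_rho`, `n`.
#' @export
ani_correlations <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(is.na(x)) || any(is.na(y))) stop("NA values in ANI vectors")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  tibble(pearson_r = stats::cor(x, y, method = "pearson"),
         spearman_rho = stats::cor(x, y, method = "spearman"),
         n = length(x))
}

#' Least-squares polynomial fit of gene ANI on genome ANI
#'
#' Curve estimation for the ANIm-ANIstt relation: ordinary least squares fit
#' of a degree-1 (linear) or degree-2 (quadratic) polynomial, with the
#' overall F statistic against the intercept-only model.
#'
#' @param x Predictor (genome ANI).
#' @param y Response (gene/concatenate ANI).
#' @param degree 1 or 2.
#' @return An object of class `ani_fit` with fields `model` (`"linear"` or
#'   `"quadratic"`), `coefficients`, `r_squared`, `sse`, `df_residual`,
#'   `f_overall`, `p_overall`, `n` and the underlying `lm` fit.
#' @export
fit_ani_curve <- function(x, y, degree = 1) {
  stopifnot(degree %in% c(1, 2), length(x) == length(y))
  n <- length(x)
  if (n <= degree + 1) stop("need more than degree + 1 observations")
  if (length(unique(x)) <= degree) stop("rank-deficient design: too few distinct x")
  df <- data.frame(x = x, y = y)
  fit <- if (degree == 1) stats::lm(y ~ x, data = df)
         else stats::lm(y ~ x + I(x^2), data = df)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  p <- degree
  df_res <- n - p - 1
  f <- (ssr / p) / (sse / df_res)
  structure(list(model = if (degree == 1) "linear" else "quadratic",
                 coefficients = stats::coef(fit),
                 r_squared = 1 - sse / sst, sse = sse, df_residual = df_res,
                 f_overall = f,
                 p_overall = stats::pf(f, p, df_res, lower.tail = FALSE),
                 n = n, fit = fit),
            class = "ani_fit")
}

#' @export
print.ani_fit <- function(x, ...) {
  cat("<ani_fit> ", x$model, " fit, n = ", x$n, "\n  R^2 = ",
      format(x$r_squared, digits = 4), ", F(", length(x$coefficients) - 1, ", ",
      x$df_residual, ") = ", format(x$f_overall, digits = 7), ", P ",
      format_p(x$p_overall), "\n", sep = "")
  invisible(x)
}

format_p <- function(p, floor = 1e-4) {
  if (is.na(p)) "= NA" else if (p < floor) paste0("< ", format(floor)) else paste0("= ", format(p, digits = 3))
}

#' @importFrom broom tidy
#' @exportS3Method broom::tidy
tidy.ani_fit <- function(x, ...) {
  broom::tidy(x$fit, ...)
}

#' @importFrom broom glance
#' @exportS3Method broom::glance
glance.ani_fit <- function(x, ...) {
  tibble(model = x$model, r.squared = x$r_squared, sse = x$sse,
         df.residual = x$df_residual, statistic = x$f_overall,
         p.value = x$p_overall, nobs = x$n)
}

#' Extra sum-of-squares comparison of nested linear vs quadratic fits
#'
#' F = ((SSE_lin - SSE_quad) / 1) / (SSE_quad / (n - 3)) with p from
#' F(1, n - 3). A quadratic SSE of exactly zero is reported as infinite F
#' with p = 0 and `degenerate = TRUE`.
#'
#' @param fit_lin,fit_quad [fit_ani_curve()] results on the same data.
#' @param alpha Significance level deciding `better`.
#' @return One-row tibble with `f_extra`, `df1`, `df2`, `p_value`, `better`,
#'   `degenerate`.
#' @export
extra_ss_test <- function(fit_lin, fit_quad, alpha = 0.05) {
  stopifnot(inherits(fit_lin, "ani_fit"), inherits(fit_quad, "ani_fit"),
            fit_lin$model == "linear", fit_quad$model == "quadratic")
  if (fit_lin$n != fit_quad$n) stop("fits are not on the same data")
  n <- fit_lin$n
  df2 <- n - 3
  if (fit_quad$sse <= 1e-12 * max(fit_lin$sse, 1e-300)) {
    return(tibble(f_extra = Inf, df1 = 1, df2 = df2, p_value = 0,
                  better = "quadratic", degenerate = TRUE))
  }
  f <- ((fit_lin$sse - fit_quad$sse) / 1) / (fit_quad$sse / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  tibble(f_extra = f, df1 = 1, df2 = df2, p_value = p,
         better = if (p < alpha) "quadratic" else "linear", degenerate = FALSE)
}

#' Tally scatter regions of paired genome/concatenate ANI values
#'
#' Counts pairs in the interspecies region (ANIm < 93 and ANIstt < 94), the
#' intraspecies region (ANIm > 95 and ANIstt > 96) and between them. The
#' inequalities are strict, so pairs lying exactly on a region edge count as
#' `between`. The three counts always sum to the total.
#'
#' @param pairs Tibble with `anim` and `anistt` columns.
#' @param cfg A [threshold_config()].
#' @return One-row tibble `n_intra_region`, `n_inter_region`, `n_between`,
#'   `total`.
#' @export
region_tally <- function(pairs, cfg = threshold_config()) {
  stopifnot(all(c("anim", "anistt") %in% names(pairs)))
  intra <- pairs$anim > cfg$region_genome_high & pairs$anistt > cfg$intra_floor
  inter <- pairs$anim < cfg$region_genome_low & pairs$anistt < cfg$inter_ceiling
  tibble(n_intra_region = sum(intra), n_inter_region = sum(inter),
         n_between = sum(!intra & !inter), total = nrow(pairs))
}

#' Full concordance analysis of genome vs concatenate ANI
#'
#' Bundles [ani_correlations()], linear and quadratic [fit_ani_curve()]
#' fits, the [extra_ss_test()] model comparison and the [region_tally()].
#'
#' @param pairs Tibble with `anim` and `anistt` columns (one row per strain
#'   pair).
#' @param cfg A [threshold_config()].
#' @return An `ani_concordance` object (list) with components `pairs`,
#'   `correlations`, `fit_linear`, `fit_quadratic`, `comparison`, `regions`.
#' @export
ani_concordance <- function(pairs, cfg = threshold_config()) {
  stopifnot(all(c("anim", "anistt") %in% names(pairs)))
  fl <- fit_ani_curve(pairs$anim, pairs$anistt, degree = 1)
  fq <- fit_ani_curve(pairs$anim, pairs$anistt, degree = 2)
  structure(list(pairs = as_tibble(pairs),
                 correlations = ani_correlations(pairs$anim, pairs$anistt),
                 fit_linear = fl, fit_quadratic = fq,
                 comparison = extra_ss_test(fl, fq),
                 regions = region_tally(pairs, cfg),
                 cfg = cfg),
            class = "ani_concordance")
}

#' @export
print.ani_concordance <- function(x, ...) {
  cat("<ani_concordance> n =", x$correlations$n, "pairs\n")
  cat("  Pearson r =", format(x$correlations$pearson_r, digits = 3),
      " Spearman rho =", format(x$correlations$spearman_rho, digits = 3), "\n")
  cat("  linear    R^2 =", format(x$fit_linear$r_squared, digits = 3), "\n")
  cat("  quadratic R^2 =", format(x$fit_quadratic$r_squared, digits = 3), "\n")
  cat("  extra-SS F(1,", x$comparison$df2, ") = ",
      format(x$comparison$f_extra, digits = 7), ", P ",
      format_p(x$comparison$p_value), " -> ", x$comparison$better, "\n", sep = "")
  cat("  regions: intra", x$regions$n_intra_region,
      "| inter", x$regions$n_inter_region,
      "| between", x$regions$n_between, "\n")
  invisible(x)
}

#' Scatter plot of concatenate vs genome ANI with species regions
#'
#' Draws the two-dimensional ANI scatter with the interspecies and
#' intraspecies regions shaded and the fitted quadratic curve overlaid.
#'
#' @param object An [ani_concordance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.ani_concordance <- function(object, ...) {
  cfg <- object$cfg
  co <- object$fit_quadratic$coefficients
  grid <- tibble(anim = seq(min(object$pairs$anim), max(object$pairs$anim),
                            length.out = 200))
  grid$anistt <- co[[1]] + co[[2]] * grid$anim + co[[3]] * grid$anim^2
  regions <- tibble(
    xmin = c(-Inf, cfg$region_genome_high),
    xmax = c(cfg$region_genome_low, Inf),
    ymin = c(-Inf, cfg$intra_floor),
    ymax = c(cfg$inter_ceiling, Inf),
    region = c("interspecies", "intraspecies")
  )
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$anim, y = .data$anistt)) +
    ggplot2::geom_rect(data = regions, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$region), alpha = 0.15) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = "genome ANI (ANIm, %)", y = "concatenate ANI (ANIstt, %)",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ani_concordance
#' @param x An [ani_concordance()] result.
#' @param y Unused.
#' @export
plot.ani_concordance <- function(x, y, ...) print(autoplot(x, ...))
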