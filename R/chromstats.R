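#' Fit the autosome count-versus-length regression
#'
#' Ordinary least squares of per-chromosome event counts on chromosome
#' length over autosomes only (the X chromosome is excluded from the fit
#' so it can be tested as an outlier). Counts are modelled on the raw
#' scale, matching a linear null in which events accumulate uniformly per
#' base pair; a Poisson GLM is available as a sensitivity mode.
#'
#' @param table a `chrom_count_table` (from [count_by_chromosome()] or
#'   [categorize_direction()]) with columns `chrom`, `length`, `is_x`.
#' @param category name of the count column to model.
#' @param mode `"ols"` (default) or `"poisson"` for a log-link GLM.
#' @return list of class `autosome_fit`: `slope` (events per bp),
#'   `intercept`, `r_squared`, `sigma2` (residual variance), `n`,
#'   `x_bar`, `ss_x`, `category`, `mode`.
#' @export
fit_autosome_regression <- function(table, category, mode = c("ols", "poisson")) {
  mode <- match.arg(mode)
  if (!category %in% names(table))
    stop("no count column '", category, "' in table")
  aut <- table[!table$is_x, , drop = FALSE]
  n <- nrow(aut)
  if (n < 3L) stop("need at least 3 autosomes to fit the regression")
  x <- aut$length; y <- aut[[category]]
  if (stats::var(x) == 0) stop("zero variance in chromosome lengths")
  if (mode == "poisson") {
    fit <- stats::glm(y ~ x, family = stats::poisson())
    co <- coef(fit)
    return(structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                          r_squared = NA_real_, sigma2 = NA_real_, n = n,
                          x_bar = mean(x), ss_x = sum((x - mean(x))^2),
                          category = category, mode = mode, glm = fit),
                     class = "autosome_fit"))
  }
  fit <- lm(y ~ x)
  co <- coef(fit)
  res <- stats::residuals(fit)
  sigma2 <- if (n > 2) sum(res^2) / (n - 2) else NA_real_
  r2 <- if (stats::var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else 0
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, sigma2 = sigma2, n = n,
                 x_bar = mean(x), ss_x = sum((x - mean(x))^2),
                 category = category, mode = mode),
            class = "autosome_fit")
}

predict_autosome <- function(fit, x_length) {
  if (fit$mode == "poisson") unname(exp(fit$intercept + fit$slope * x_length))
  else fit$intercept + fit$slope * x_length
}

#' Deficiency or excess of the X chromosome relative to autosomes
#'
#' Predicts the X-chromosome count from the autosome regression, scales
#' the expectation by the effective-population-size factor (the X is
#' carried in roughly three quarters as many copies as an autosome), and
#' reports the signed percentage deviation of the observed count:
#' negative values are deficiencies, positive values excesses. The
#' unadjusted deviation (`ne_factor = 1`) is co-reported because the
#' adjustment weakens deficiencies but strengthens excesses.
#'
#' @param fit an `autosome_fit`.
#' @param x_length X-chromosome length in bp.
#' @param x_observed observed X-chromosome count.
#' @param ne_factor effective-population-size scaling of the X
#'   expectation (default 3/4).
#' @return list of class `deviation_result`: `category`, `slope`,
#'   `intercept`, `r_squared`, `x_observed`, `x_predicted`, `ne_factor`,
#'   `x_expected_adjusted`, `deviation_pct`, `deviation_pct_unadjusted`,
#'   `p_value`, `t_stat`, `df`.
#' @export
x_deviation <- function(fit, x_length, x_observed, ne_factor = 0.75) {
  pred <- predict_autosome(fit, x_length)
  adj <- ne_factor * pred
  if (!is.finite(adj) || adj <= 0)
    stop("adjusted X expectation must be positive")
  ot <- outlier_test(fit, x_length, x_observed)
  structure(list(category = fit$category,
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 x_observed = x_observed, x_predicted = pred,
                 ne_factor = ne_factor, x_expected_adjusted = adj,
                 deviation_pct = 100 * (x_observed - adj) / adj,
                 deviation_pct_unadjusted = 100 * (x_observed - pred) / pred,
                 p_value = ot$p_value, t_stat = ot$t_stat, df = ot$df),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf(
    "%s: observed %d vs adjusted expectation %.2f (Ne factor %.2f): %+.2f%% (p = %.3g)\n",
    x$category, as.integer(round(x$x_observed)), x$x_expected_adjusted,
    x$ne_factor, x$deviation_pct,
    if (is.na(x$p_value)) NA else x$p_value))
  invisible(x)
}

#' Outlier test for the X chromosome against the autosome fit
#'
#' Treats the X as a new observation and computes the externally
#' studentized prediction residual
#' `t = (observed - predicted) / SE_pred` with
#' `SE_pred = sigma * sqrt(1 + 1/n + (x0 - mean(x))^2 / SS_x)`,
#' referred to a two-sided t distribution on `n - 2` degrees of freedom.
#' With zero residual variance and an off-line observation the p-value is
#' reported as not computable (`NA`) rather than zero.
#'
#' @inheritParams x_deviation
#' @return list with `t_stat`, `p_value`, `se_pred`, `df`.
#' @export
outlier_test <- function(fit, x_length, x_observed) {
  if (fit$mode != "ols")
    stop("outlier_test requires an OLS fit")
  pred <- predict_autosome(fit, x_length)
  dfree <- fit$n - 2L
  resid <- x_observed - pred
  if (abs(resid) < .Machine$double.eps * max(1, abs(pred)))
    return(list(t_stat = 0, p_value = 1,
                se_pred = NA_real_, df = dfree))
  scale0 <- max(1, abs(pred))
  if (!is.finite(fit$sigma2) || fit$sigma2 <= (1e-12 * scale0)^2)
    return(list(t_stat = NA_real_, p_value = NA_real_,
                se_pred = 0, df = dfree))
  se <- sqrt(fit$sigma2 *
               (1 + 1 / fit$n + (x_length - fit$x_bar)^2 / fit$ss_x))
  t <- resid / se
  list(t_stat = t, p_value = 2 * pt(-abs(t), dfree), se_pred = se,
       df = dfree)
}

#' Simulate a per-chromosome count table under the linear null
#'
#' Autosome counts are Poisson with mean `rate_per_mb * length`; the X
#' count is set to `x_relative * ne_factor` times its linear prediction,
#' so `x_relative = 0.5` plants a 50% deficiency under the Ne-adjusted
#' model. Chromosome lengths default to a karyotype of 18 autosomes
#' spanning 40--274 Mb plus a 126 Mb X, mirroring the pig genome scale.
#'
#' @param seed integer seed.
#' @param rate_per_mb expected events per Mb on autosomes.
#' @param lengths named vector of chromosome lengths in bp; the X must be
#'   named `x_name`.
#' @param x_name name of the X chromosome.
#' @param x_relative planted X count relative to the Ne-adjusted
#'   expectation (1 = no deviation).
#' @param ne_factor effective-population-size factor used for planting.
#' @return a `chrom_count_table` with one count column `"events"`.
#' @export
simulate_count_table <- function(seed, rate_per_mb = 5,
                                 lengths = NULL, x_name = "chrX",
                                 x_relative = 1, ne_factor = 0.75) {
  if (is.null(lengths)) {
    aut <- c(274, 151, 133, 131, 105, 171, 122, 139, 139, 69,
             79, 61, 208, 142, 140, 80, 63, 56) * 1e6
    names(aut) <- paste0("chr", seq_along(aut))
    lengths <- c(aut, stats::setNames(126e6, x_name))
  }
  set.seed(seed)
  is_x <- names(lengths) == x_name
  lambda <- rate_per_mb * lengths / 1e6
  counts <- rpois(length(lengths), lambda)
  counts[is_x] <- round(x_relative * ne_factor * lambda[is_x])
  out <- data.frame(chrom = names(lengths), length = as.numeric(lengths),
                    is_x = is_x, events = counts,
                    stringsAsFactors = FALSE)
  class(out) <- c("chrom_count_table", "data.frame")
  out
}
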