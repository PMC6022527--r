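# Statistical analyses of cohort tables: exponential and linear fits of
# surface kerma, paired t-test of the collar effect, one-way ANOVA with
# Tukey-Kramer contrasts across breast-size groups, Pearson correlation.

#' Exponential least-squares fit
#'
#' Fits \eqn{y = A e^{b x}} by nonlinear least squares on the natural scale
#' (unweighted), initialised from the log-linear regression. Standard errors
#' from the local linearisation.
#'
#' @param x predictor (compression, cm).
#' @param y response (kerma, uGy), strictly positive.
#' @param log_scale fit on the log scale instead (optional).
#' @return object of class \code{fit_result}: A, b, standard errors, n.
#' @export
fit_exponential <- function(x, y, log_scale = FALSE) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3 paired points")
  if (any(y <= 0)) stop("y must be strictly positive")
  lmfit <- lm(log(y) ~ x)
  start <- list(A = exp(coef(lmfit)[[1]]), b = coef(lmfit)[[2]])
  if (log_scale) {
    s <- summary(lmfit)$coefficients
    out <- list(model = "exponential", A = start$A, b = start$b,
                A_se = start$A * s[1, 2], b_se = s[2, 2], n = length(x))
    return(structure(out, class = "fit_result"))
  }
  fit <- minpack.lm::nlsLM(y ~ A * exp(b * x), start = start,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10, maxiter = 500))
  s <- summary(fit)$coefficients
  structure(list(model = "exponential",
                 A = s["A", 1], b = s["b", 1],
                 A_se = s["A", 2], b_se = s["b", 2],
                 n = length(x)), class = "fit_result")
}

#' Linear least-squares fit with Pearson correlation
#'
#' @param x predictor (e.g. BMI).
#' @param y response (kerma, uGy).
#' @return object of class \code{fit_result}: intercept, slope, standard
#'   errors, pearson_r, n.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3 paired points")
  fit <- lm(y ~ x)
  s <- summary(fit)$coefficients
  structure(list(model = "linear",
                 intercept = s[1, 1], slope = s[2, 1],
                 intercept_se = s[1, 2], slope_se = s[2, 2],
                 pearson_r = unname(cor(x, y)), n = length(x)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$model == "exponential")
    cat(sprintf("<fit> y = %.4g * exp(%.4g x)  (se %.2g, %.2g; n = %d)\n",
                x$A, x$b, x$A_se, x$b_se, x$n))
  else
    cat(sprintf("<fit> y = %.4g + %.4g x  (r = %.3f; n = %d)\n",
                x$intercept, x$slope, x$pearson_r, x$n))
  invisible(x)
}

#' Paired t-test (collar protective effect)
#'
#' Two-sided paired t-test of before (outside collar) vs after (behind
#' collar). Identical vectors are the degenerate zero-variance case and are
#' reported with \code{statistic = 0} and \code{p_value = 1}.
#'
#' @param before,after equal-length paired dose vectors (mGy).
#' @return object of class \code{test_report}.
#' @export
paired_test <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2)
    stop("need equal-length paired vectors, n >= 2")
  d <- before - after
  if (sd(d) == 0) {
    if (all(d == 0))
      return(structure(list(test = "paired-t", statistic = 0, p_value = 1,
                            df = length(d) - 1,
                            mean_difference = 0,
                            stderr = 0), class = "test_report"))
    stop("degenerate case: constant non-zero differences")
  }
  tt <- t.test(before, after, paired = TRUE)
  structure(list(test = "paired-t",
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 mean_difference = unname(tt$estimate),
                 stderr = unname(tt$stderr)), class = "test_report")
}

#' One-way ANOVA with Tukey-Kramer post-hoc contrasts
#'
#' Overall F test across groups followed by Tukey's honest significant
#' difference on the fitted model (the Tukey-Kramer extension handles the
#' unequal group sizes).
#'
#' @param groups named list mapping group label to a dose vector (>= 2
#'   groups, each n >= 2).
#' @return list: \code{anova} (a \code{test_report}) and \code{tukey}
#'   (data.frame of pairwise comparisons with adjusted p-values) and
#'   \code{means} (group means +- stderr).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L))))
  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  rep_ <- structure(list(test = "anova",
                         statistic = s[["F value"]][1],
                         p_value = s[["Pr(>F)"]][1],
                         df = unname(s[["Df"]])), class = "test_report")
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  means <- data.frame(
    group = names(groups),
    mean = vapply(groups, mean, 1),
    stderr = vapply(groups, function(v) sd(v) / sqrt(length(v)), 1),
    n = vapply(groups, length, 1L), row.names = NULL)
  list(anova = rep_, tukey = tukey, means = means)
}

#' Pearson correlation coefficient
#'
#' @param x,y equal-length vectors, n >= 3, non-degenerate.
#' @return object of class \code{test_report} with \code{statistic} the
#'   sample r.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate: zero variance input")
  ct <- cor.test(x, y)
  structure(list(test = "pearson", statistic = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x)),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.3g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Cohort statistics report
#'
#' Runs the full statistical pipeline on a cohort table: paired t-tests of
#' outside vs inside dose (all patients and per group), one-way ANOVA +
#' Tukey for both dose series across groups, the exponential fit of outside
#' dose against CC compression, and the BMI linear fit with Pearson r.
#'
#' @param cohort a \code{cohort_table}.
#' @return nested list mirroring the study's table structure.
#' @export
cohort_stats <- function(cohort) {
  by_group <- split(cohort, cohort$group)
  paired <- c(list(all = paired_test(cohort$k_out, cohort$k_in)),
              lapply(by_group, function(d) paired_test(d$k_out, d$k_in)))
  out <- anova_tukey(lapply(by_group, `[[`, "k_out"))
  ins <- anova_tukey(lapply(by_group, `[[`, "k_in"))
  fit_c <- fit_exponential(cohort$compression_cc / 10, cohort$k_out * 1000)
  fit_b <- fit_linear(cohort$bmi, cohort$k_out * 1000)
  list(paired = paired, anova_outside = out, anova_inside = ins,
       fit_compression = fit_c, fit_bmi = fit_b,
       ratio_median = median(cohort$k_in / cohort$k_out))
}

#' @importFrom stats lm coef t.test aov TukeyHSD cor cor.test median
NULL
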