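# Statistical layer over tidy per-cell tables: ALP-positive fractions,
# rank-correlation trends, volume-response fits, group comparisons.

#' ALP-positive fraction with exact binomial interval
#'
#' Percentage of cells scored positive for alkaline phosphatase, the
#' early osteogenic marker. Input is either a table with a binary
#' `alp_positive` column, or a numeric vector of per-cell mean stain
#' intensities scored against an explicit `cutoff` (the positivity
#' criterion is a configurable, logged threshold, not a judgement
#' call).
#'
#' @param x data.frame with column `alp_positive`, or numeric vector of
#'   per-cell stain intensities.
#' @param cutoff positivity cutoff for the intensity form.
#' @param conf confidence level for the exact (Clopper-Pearson)
#'   interval.
#' @return list: `percent`, `ci_low`, `ci_high` (percent),
#'   `n_positive`, `n`.
#' @export
alpPositiveFraction <- function(x, cutoff = NULL, conf = 0.95) {
  if (is.data.frame(x)) {
    stopifnot("alp_positive" %in% names(x))
    pos <- sum(x$alp_positive > 0)
    n <- nrow(x)
  } else {
    if (is.null(cutoff)) stop("intensity input needs a cutoff")
    pos <- sum(x > cutoff)
    n <- length(x)
  }
  if (n == 0L) stop("zero cells: positive fraction undefined")
  bt <- stats::binom.test(pos, n, conf.level = conf)
  list(percent = 100 * pos / n,
       ci_low = 100 * bt$conf.int[1], ci_high = 100 * bt$conf.int[2],
       n_positive = pos, n = n)
}

#' Spearman rank correlation with exact small-sample p
#'
#' Rank correlation using mid-ranks for ties. The p-value is two-sided:
#' exact by full permutation enumeration for `n <= 10`, and by the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees
#' of freedom otherwise. Invariant under strictly monotone transforms
#' of either variable.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list: `rho`, `p`, `n`, `method`.
#' @export
spearmanTrend <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant ranks: correlation undefined")
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- cpp_perm_pvalue(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Fit the volume-response trend
#'
#' The relationship between per-cell volume and a response (ALP
#' positivity percent, N:C ratio, ...) observed to collapse onto a
#' single curve across perturbations. Two forms are offered -- which one
#' a given dataset warrants is the caller's choice:
#' \describe{
#'   \item{linear}{ordinary least squares `r = b0 + b1 V`.}
#'   \item{saturating}{`r = a V / (k + V)` by nonlinear least squares
#'     (Levenberg-Marquardt), initialized at `a = max(r)`,
#'     `k = median(V)`.}
#' }
#'
#' @param volumes,responses numeric vectors.
#' @param model `"linear"` or `"saturating"`.
#' @return `TrendFit` list: `model`, `coefficients`, `se`, `n`,
#'   `r_squared`, and `predict(newVolumes)` evaluator reproducing the
#'   fitted curve.
#' @export
fitVolumeResponse <- function(volumes, responses,
                              model = c("linear", "saturating")) {
  model <- match.arg(model)
  keep <- stats::complete.cases(volumes, responses)
  v <- as.numeric(volumes[keep]); r <- as.numeric(responses[keep])
  n <- length(v)
  if (n < 3L) stop("need at least 3 points (parameters + 1)")
  if (model == "linear") {
    fit <- stats::lm(r ~ v)
    cf <- stats::setNames(coef(fit), c("intercept", "slope"))
    se <- stats::setNames(suppressWarnings(summary(fit))$coefficients[, 2],
                          names(cf))
    pred <- function(newVolumes)
      cf[["intercept"]] + cf[["slope"]] * newVolumes
    rsq <- suppressWarnings(summary(fit))$r.squared
  } else {
    df <- data.frame(v = v, r = r)
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ a * v / (k + v), data = df,
                        start = list(a = max(r), k = stats::median(v)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("saturating fit did not converge: ", conditionMessage(e)))
    cf <- coef(fit)
    se <- summary(fit)$coefficients[, 2]
    pred <- function(newVolumes)
      cf[["a"]] * newVolumes / (cf[["k"]] + newVolumes)
    rsq <- 1 - sum(stats::residuals(fit)^2) / sum((r - mean(r))^2)
  }
  structure(list(model = model, coefficients = cf, se = se, n = n,
                 r_squared = rsq, predict = pred),
            class = "TrendFit")
}

#' @export
print.TrendFit <- function(x, ...) {
  cat(sprintf("TrendFit <%s>, n = %d, R^2 = %.3f\n",
              x$model, x$n, x$r_squared))
  for (nm in names(x$coefficients))
    cat(sprintf("  %s = %.5g (se %.3g)\n", nm, x$coefficients[[nm]],
                x$se[[nm]]))
  invisible(x)
}

#' Compare a measurement between groups
#'
#' Two-sample two-tailed t-test, or one-way ANOVA with
#' Bonferroni-adjusted pairwise follow-up.
#'
#' @param table data.frame.
#' @param value name of the measurement column.
#' @param group name of the grouping column.
#' @param test `"t"` (exactly two groups) or `"anova"`.
#' @return list: `test`, `statistic`, `p`, `groups`, and for ANOVA a
#'   `pairwise` matrix of Bonferroni-adjusted p-values.
#' @export
groupCompare <- function(table, value, group, test = c("t", "anova")) {
  test <- match.arg(test)
  v <- table[[value]]; g <- factor(table[[group]])
  if (is.null(v) || is.null(table[[group]]))
    stop("columns '", value, "' / '", group, "' not found")
  ng <- nlevels(droplevels(g))
  if (test == "t") {
    if (ng != 2L) stop("t-test needs exactly 2 groups, got ", ng)
    tt <- stats::t.test(v ~ g)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         groups = levels(droplevels(g)))
  } else {
    if (ng < 2L) stop("ANOVA needs at least 2 groups, got ", ng)
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    pw <- stats::pairwise.t.test(v, g, p.adjust.method = "bonferroni")
    list(test = "anova", statistic = s[["F value"]][1],
         p = s[["Pr(>F)"]][1], groups = levels(droplevels(g)),
         pairwise = pw$p.value)
  }
}
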