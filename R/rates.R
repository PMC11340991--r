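#' Fit a Numt accumulation rate by ordinary least squares
#'
#' Linear regression `Y = b0 + b1 X + e` of Numt count (raw or normalized)
#' on days cultured, with a t-based 95% confidence interval on the slope
#' (n - 2 degrees of freedom). The per-10-day rate is `10 * b1`.
#'
#' @param x Days cultured (or a `data.frame` with `day` and `count`).
#' @param y Numt counts (omit when `x` is a `data.frame`).
#' @return An object of class `rate_fit`: list with `beta0`, `beta1`, `se`,
#'   `ci` (95%), `r2`, `p` (two-sided, slope), `n`,
#'   `rate_per_10_days`, and the underlying `lm` fit.
#' @export
fit_rate <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$count
    x <- x$day
  }
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::sd(x) == 0) stop("zero variance in X; cannot fit a slope")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- sm$coefficients["x", "Std. Error"]
  p <- sm$coefficients["x", "Pr(>|t|)"]
  r2 <- sm$r.squared
  if (stats::var(y) == 0) {  # constant response: no variance to explain
    r2 <- 0
    p <- 1
  }
  tq <- stats::qt(0.975, df = length(x) - 2)
  structure(list(beta0 = beta[1], beta1 = beta[2], se = se,
                 ci = beta[2] + c(-1, 1) * tq * se,
                 r2 = r2, p = p, n = length(x),
                 rate_per_10_days = 10 * beta[2], lm = fit),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "rate_fit: slope %.4f /day (%.2f per 10 days, 95%% CI %.2f-%.2f), r2 = %.3f, p = %.3g, n = %d\n",
    x$beta1, x$rate_per_10_days, 10 * x$ci[1], 10 * x$ci[2], x$r2, x$p, x$n))
  invisible(x)
}

#' Normalize counts by their group median
#'
#' Divides each count by the median of its group. A zero group median would
#' make the normalization undefined; such groups fall back to a divisor of
#' 1 (counts unchanged) with a warning.
#'
#' @param counts Numeric counts.
#' @param groups Group labels, one per count.
#' @return Normalized counts.
#' @export
normalize_by_group_median <- function(counts, groups) {
  stopifnot(length(counts) == length(groups))
  med <- tapply(counts, groups, stats::median)
  if (any(med == 0)) {
    warning("group(s) with zero median: ",
            paste(names(med)[med == 0], collapse = ", "),
            "; using divisor 1 for these groups")
    med[med == 0] <- 1
  }
  as.vector(counts / med[as.character(groups)])
}

#' Compare accumulation slopes between two groups by ANOVA
#'
#' Fits the pooled interaction model `Y ~ X * group` on (typically
#' median-normalized) counts and tests the slope difference with the F-test
#' of the interaction term, which equals the nested-model ANOVA comparison
#' of a common-slope versus separate-slopes model.
#'
#' @param series_a,series_b `data.frame`s with `day` and `count`.
#' @param label_a,label_b Distinct group labels.
#' @return List with `F`, `p`, `df`, `slopes` (per-group slopes), and the
#'   pooled `lm` fit.
#' @export
compare_slopes <- function(series_a, series_b,
                           label_a = "A", label_b = "B") {
  if (identical(label_a, label_b)) stop("group labels must differ")
  dat <- rbind(data.frame(day = series_a$day, count = series_a$count,
                          group = label_a),
               data.frame(day = series_b$day, count = series_b$count,
                          group = label_b))
  dat$group <- factor(dat$group, levels = c(label_a, label_b))
  fit <- stats::lm(count ~ day * group, data = dat)
  av <- stats::anova(fit)
  Fval <- av["day:group", "F value"]
  pval <- av["day:group", "Pr(>F)"]
  co <- stats::coef(fit)
  slopes <- c(co[["day"]],
              co[["day"]] + co[[paste0("day:group", label_b)]])
  names(slopes) <- c(label_a, label_b)
  list(F = Fval, p = pval,
       df = c(av["day:group", "Df"], av["Residuals", "Df"]),
       slopes = slopes, lm = fit)
}

#' Fold-change between two rates or means
#'
#' Ratio `a / b` rounded (half-even) to one decimal, the convention used for
#' reporting relative Numt frequencies and accumulation rates.
#'
#' @param a,b Numerator and denominator (`b` must be positive).
#' @return Ratio rounded to 1 decimal.
#' @examples
#' fold_change(4.13, 0.75) # 5.5
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be positive")
  round(a / b, 1)
}

#' Hedge's g standardized mean difference
#'
#' `g = J * (mean_A - mean_B) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 (n_A + n_B) - 9)`.
#'
#' @param a,b Numeric value vectors (each of length >= 2).
#' @return List with `g`, `J`, `means`, `ns`, `pooled_sd`.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  J <- 1 - 3 / (4 * (na + nb) - 9)
  list(g = J * (mean(a) - mean(b)) / sqrt(sp2), J = J,
       means = c(mean(a), mean(b)), ns = c(na, nb), pooled_sd = sqrt(sp2))
}

#' Assign age-at-death groups
#'
#' Three boundary-inclusive groups: died younger than 85; at or above 85 and
#' below 93; at or above 93.
#'
#' @param age Age at death in years (> 0).
#' @return Factor with levels `"<85"`, `"85-92"`, `">=93"`.
#' @export
assign_age_group <- function(age) {
  if (any(age <= 0)) stop("age must be positive")
  cut(age, breaks = c(0, 85, 93, Inf), right = FALSE,
      labels = c("<85", "85-92", ">=93"))
}

#' Age-at-death association of Numt burden by cognitive stratum
#'
#' Within each stratum, ordinary least-squares regression of the exclusive
#' Numt count on age at death; reports the slope per year and per decade,
#' r-squared, and the two-sided p-value. Strata with fewer than 3 samples
#' are skipped with a warning.
#'
#' @param counts Per-sample exclusive Numt counts.
#' @param ages Ages at death.
#' @param strata Stratum labels (e.g., cognitive group), one per sample.
#' @return `data.frame(stratum, n, slope_per_year, slope_per_decade, se,
#'   r2, p)`.
#' @export
age_association <- function(counts, ages, strata) {
  stopifnot(length(counts) == length(ages), length(ages) == length(strata))
  out <- lapply(unique(as.character(strata)), function(s) {
    i <- strata == s
    if (sum(i) < 3) {
      warning("stratum '", s, "' has fewer than 3 samples; skipped")
      return(NULL)
    }
    f <- fit_rate(ages[i], counts[i])
    data.frame(stratum = s, n = f$n, slope_per_year = f$beta1,
               slope_per_decade = 10 * f$beta1, se = f$se, r2 = f$r2,
               p = f$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cognitive group from a COGDX score
#'
#' Standard convention: 1 = no cognitive impairment (NCI), 2-3 = mild
#' cognitive impairment (MCI), 4-5 = Alzheimer's dementia (AD).
#'
#' @param cogdx Integer COGDX scores in 1..5.
#' @return Character vector of group labels.
#' @export
cognitive_group <- function(cogdx) {
  if (any(!cogdx %in% 1:5)) stop("COGDX scores must be in 1..5")
  c("NCI", "MCI", "MCI", "AD", "AD")[cogdx]
}
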