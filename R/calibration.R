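#' Fit a linear calibration curve
#'
#' Ordinary least squares of response on concentration. Detection and
#' quantitation limits follow the ICH/VICH residual-based convention:
#' LOD = 3.3 s / |slope| and LOQ = 10 s / |slope|, where s is the residual
#' standard deviation of the fit unless a blank standard deviation is
#' supplied.
#'
#' @param concs concentrations in ug/mL, strictly positive, >= 3 values.
#' @param responses matching scalar responses.
#' @param descriptor the [response_descriptor()] the responses were read
#'   with (kept for bookkeeping; may be `NULL`).
#' @param analyte analyte name.
#' @param range optional calibration range `c(lower, upper)` in ug/mL;
#'   defaults to the span of `concs`.
#' @param blank_sd optional standard deviation of blank responses to use
#'   in place of the residual standard deviation for LOD/LOQ.
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r`, `range`, `lod`, `loq`, `sd_resid`, `n`.
#' @examples
#' cc <- fit_calibration(1:5, 2 * (1:5) + 1, analyte = "X")
#' cc$slope     # 2
#' cc$intercept # 1
#' @export
fit_calibration <- function(concs, responses, descriptor = NULL,
                            analyte = "", range = NULL, blank_sd = NULL) {
  concs <- as.numeric(concs); responses <- as.numeric(responses)
  if (length(concs) < 3L || length(concs) != length(responses)) {
    stop("need >= 3 matched (concentration, response) points", call. = FALSE)
  }
  if (any(concs <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (stats::sd(concs) == 0) {
    stop("rank-deficient input: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(responses ~ concs)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope == 0) stop("degenerate fit: slope is zero", call. = FALSE)
  r <- suppressWarnings(stats::cor(concs, responses))
  s <- if (!is.null(blank_sd)) blank_sd else
    sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  if (is.null(range)) range <- range(concs)
  structure(
    list(analyte = analyte, descriptor = descriptor, slope = slope,
         intercept = intercept, r = r, range = sort(as.numeric(range)),
         lod = 3.3 * s / abs(slope), loq = 10 * s / abs(slope),
         sd_resid = s, n = length(concs)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration> %s: y = %.6g x %+.6g (r = %.6f), range %g-%g ug/mL\n",
    x$analyte, x$slope, x$intercept, x$r, x$range[1], x$range[2]))
  cat(sprintf("  LOD %.3g, LOQ %.3g ug/mL (n = %d)\n", x$lod, x$loq, x$n))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Maps a measured response to a concentration, `(response - intercept) /
#' slope`. Results below the curve's detection limit carry a `below_lod`
#' attribute (they are reported, never clipped).
#'
#' @param curve a [fit_calibration()] object.
#' @param response scalar (or vector of) measured response(s).
#' @return concentration(s) in ug/mL with attribute `below_lod`.
#' @export
predict_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (response - curve$intercept) / curve$slope
  attr(conc, "below_lod") <- conc < curve$lod
  conc
}

#' Percent recovery
#'
#' @param found found concentration(s), ug/mL.
#' @param taken nominal concentration(s), ug/mL, > 0.
#' @return `100 * found / taken`, percent.
#' @export
recovery <- function(found, taken) {
  if (any(taken <= 0)) stop("taken must be > 0", call. = FALSE)
  100 * found / taken
}

#' Intra- and inter-day precision
#'
#' Repeatability is the pooled within-day percent RSD (root mean square of
#' the per-day RSDs); intermediate precision is the percent RSD of the full
#' set across days.
#'
#' @param values replicate measurements.
#' @param day grouping factor (one level per day), >= 2 replicates per
#'   level.
#' @return list with `rsd_intra` and `rsd_inter`, percent.
#' @export
precision <- function(values, day) {
  day <- as.factor(day)
  if (any(tapply(values, day, length) < 2L)) {
    stop("each day needs >= 2 replicates", call. = FALSE)
  }
  per_day <- tapply(values, day, function(v) 100 * stats::sd(v) / mean(v))
  list(
    rsd_intra = sqrt(mean(per_day^2)),
    rsd_inter = 100 * stats::sd(values) / mean(values)
  )
}

#' Compare two sets of assay results by t and F tests
#'
#' Two-sample Student's t test with pooled variance and the variance-ratio
#' F test (larger variance over smaller), as used to compare a proposed
#' method against a reference method at p = 0.05. Critical values are
#' computed from the t and F distributions at the stated degrees of
#' freedom, not tabulated.
#'
#' @param a,b numeric result vectors (e.g. percent recoveries), n >= 2
#'   each.
#' @param alpha significance level (default 0.05, two-sided).
#' @return list with `t`, `t_crit`, `t_df`, `f`, `f_crit`, `f_df`
#'   (numerator/denominator), and logical `significant_t`,
#'   `significant_f`.
#' @export
compare_methods <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  t_df <- length(a) + length(b) - 2L
  va <- stats::var(a); vb <- stats::var(b)
  if (va >= vb) {
    f <- va / vb; f_df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f <- vb / va; f_df <- c(length(b) - 1L, length(a) - 1L)
  }
  t_crit <- stats::qt(1 - alpha / 2, t_df)
  f_crit <- stats::qf(1 - alpha / 2, f_df[1], f_df[2])
  list(t = unname(abs(tt$statistic)), t_crit = t_crit, t_df = t_df,
       f = f, f_crit = f_crit, f_df = f_df,
       significant_t = abs(tt$statistic) > t_crit,
       significant_f = f > f_crit)
}

#' Single-factor ANOVA table
#'
#' One-way analysis of variance across result groups (e.g. one group per
#' method), returned as the classical between/within/total table.
#'
#' @param groups named list of numeric vectors, >= 2 groups of >= 2
#'   values.
#' @param alpha significance level for the critical F (default 0.05).
#' @return list with `table` (data frame: source, ss, df, ms, f, f_crit)
#'   and `p_value`.
#' @export
anova_single_factor <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  ss_b <- an$`Sum Sq`[1]; ss_w <- an$`Sum Sq`[2]
  df_b <- an$Df[1]; df_w <- an$Df[2]
  tab <- data.frame(
    source = c("Between groups", "Within groups", "Total"),
    ss = c(ss_b, ss_w, ss_b + ss_w),
    df = c(df_b, df_w, df_b + df_w),
    ms = c(an$`Mean Sq`[1], an$`Mean Sq`[2], NA),
    f = c(an$`F value`[1], NA, NA),
    f_crit = c(stats::qf(1 - alpha, df_b, df_w), NA, NA)
  )
  list(table = tab, p_value = an$`Pr(>F)`[1])
}
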