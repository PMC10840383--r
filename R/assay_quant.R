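# Beta-lactamase surface-expression assay (nitrocefin hydrolysis slopes)
# and biomembrane force probe adhesion-frequency quantification.

#' OLS slope of a plate-reader kinetic trace
#'
#' Ordinary least-squares slope of absorbance versus time for one well,
#' with its standard error. Nitrocefin hydrolysis is linear over the 30-min
#' read, so the slope is the activity readout.
#'
#' @param t_min Time points (minutes), strictly increasing, >= 3 points.
#' @param absorbance Absorbance (AU) at each time point.
#' @return List with `slope` (AU/min), `se`, `intercept`, `n`; a negative
#'   slope is returned as-is with a warning (evaporation/bubble artifacts).
#' @export
kinetic_slope <- function(t_min, absorbance) {
  if (length(t_min) < 3) stop("need >= 3 time points")
  if (length(t_min) != length(absorbance)) stop("length mismatch")
  if (stats::var(t_min) == 0) stop("constant timestamps")
  fit <- stats::lm(absorbance ~ t_min)
  # summary.lm warns on exact traces (zero residual); the SE of 0 is correct
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["t_min", "Estimate"]
  if (slope < 0) warning("negative kinetic slope")
  list(slope = slope, se = co["t_min", "Std. Error"],
       intercept = co["(Intercept)", "Estimate"], n = length(t_min))
}

#' Surface/total expression ratio normalized to wild type
#'
#' Ratio of mean surface slope to mean total slope, expressed as percent of
#' the wild-type ratio measured on the same plate; also the total expression
#' as percent of wild-type total. Uncertainty is propagated from replicate
#' spread by the delta method (first-order, independent wells).
#'
#' @param surface,total Replicate slopes for the variant (AU/min).
#' @param wt_surface,wt_total Replicate slopes for wild type, same plate.
#' @return List with `ratio_pct_wt`, `ratio_sem`, `total_pct_wt`,
#'   `total_sem`, `n` (variant surface/total replicate counts).
#' @export
surface_total_ratio <- function(surface, total, wt_surface, wt_total) {
  ms <- mean(surface); mt <- mean(total)
  mws <- mean(wt_surface); mwt <- mean(wt_total)
  if (mt <= 0 || mwt <= 0) stop("non-positive mean total slope")
  if (mws <= 0) stop("non-positive mean wild-type surface slope")
  ratio <- (ms / mt) / (mws / mwt) * 100
  total_pct <- mt / mwt * 100
  relvar <- function(v) if (length(v) < 2) 0 else
    stats::var(v) / length(v) / mean(v)^2
  ratio_sem <- abs(ratio) * sqrt(relvar(surface) + relvar(total) +
                                   relvar(wt_surface) + relvar(wt_total))
  total_sem <- abs(total_pct) * sqrt(relvar(total) + relvar(wt_total))
  list(ratio_pct_wt = ratio, ratio_sem = ratio_sem,
       total_pct_wt = total_pct, total_sem = total_sem,
       n = c(surface = length(surface), total = length(total)))
}

#' Adhesion frequency with Wilson 95% confidence interval
#'
#' The adhesion frequency Pa is the number of binding events divided by the
#' number of repeated bead-cell contacts (nominally 50-100 touches per
#' pair). The Wilson score interval behaves sensibly at the 0 and 1
#' boundaries.
#'
#' @param n_adhesions Number of contacts that produced a tension (binding)
#'   event.
#' @param n_contacts Total contacts for the pair (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return List with `pa`, `ci` (length-2), `n_adhesions`, `n_contacts`.
#' @export
adhesion_frequency <- function(n_adhesions, n_contacts, conf = 0.95) {
  if (n_contacts < 1) stop("n_contacts must be >= 1")
  if (n_adhesions < 0 || n_adhesions > n_contacts)
    stop("n_adhesions must lie in [0, n_contacts]")
  p <- n_adhesions / n_contacts
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n_contacts
  center <- (p + z^2 / (2 * n_contacts)) / den
  half <- z * sqrt(p * (1 - p) / n_contacts + z^2 / (4 * n_contacts^2)) / den
  list(pa = p, ci = c(max(0, center - half), min(1, center + half)),
       n_adhesions = n_adhesions, n_contacts = n_contacts)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Compares condition means (e.g. adhesion frequencies across construct and
#' ligand-concentration conditions) with an unpaired one-way ANOVA followed
#' by Tukey honest-significant-difference pairwise comparisons, annotated
#' with the star tiers 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param values Numeric vector of observations.
#' @param condition Factor (or coercible) of the same length.
#' @return List with `anova` (F, df, p) and `comparisons` data frame
#'   (`pair`, `diff`, `lwr`, `upr`, `p_adjusted`, `stars`).
#' @export
compare_conditions <- function(values, condition) {
  condition <- factor(condition)
  if (nlevels(condition) < 2) stop("need >= 2 conditions")
  if (any(table(condition) < 2)) stop("every condition needs >= 2 observations")
  fit <- stats::aov(values ~ condition)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  stars <- cut(tk[, "p adj"], breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
               labels = c("****", "***", "**", "*", "ns"))
  comp <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     lwr = tk[, "lwr"], upr = tk[, "upr"],
                     p_adjusted = tk[, "p adj"],
                     stars = as.character(stars),
                     stringsAsFactors = FALSE)
  rownames(comp) <- NULL
  list(anova = list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
                    p = an$`Pr(>F)`[1]),
       comparisons = comp)
}
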