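# Two-electrode voltage-clamp quantification: difference currents,
# percent-of-maximum drug effects, Hill-model concentration-response fits,
# potency ratios, and log-potency group comparisons.

#' Constitutive (difference) current from ion substitution
#'
#' Replacing extracellular Na+ with impermeant NMDG+ abolishes the resting
#' Na+ influx through constitutively open channels; the difference between
#' the leak currents in the two solutions measures constitutive channel
#' activity. For an inward (negative) Na+ current the result is positive.
#'
#' @param I_Na Holding current in Na+ external solution (nA).
#' @param I_NMDG Holding current in NMDG+ external solution (nA), same cell
#'   and holding potential.
#' @return Difference current in nA (`I_NMDG - I_Na`); a negative value
#'   (outward difference) is returned as-is with a warning.
#' @export
difference_current <- function(I_Na, I_NMDG) {
  d <- I_NMDG - I_Na
  if (any(d < 0)) warning("outward difference current (I_NMDG more negative than I_Na)")
  d
}

#' Percent of maximum theoretical effect of a drug
#'
#' Expresses a drug-induced current change as a percentage of the full
#' Na+ -> NMDG+ difference current: 100 means the drug blocks all the way to
#' the NMDG+ floor, 0 means no effect, negative values mean potentiation.
#'
#' @param I_baseline Current before drug (nA, Na+ solution).
#' @param I_drug Current in drug (nA, Na+ solution).
#' @param I_NMDG Current in NMDG+ solution (nA).
#' @return Percent of maximum theoretical inhibition.
#' @export
percent_max_effect <- function(I_baseline, I_drug, I_NMDG) {
  if (any(I_baseline == I_NMDG))
    stop("I_baseline equals I_NMDG: no difference current, percent undefined")
  100 * (I_baseline - I_drug) / (I_baseline - I_NMDG)
}

#' Hill forward models
#'
#' Activation: `Response(%) = 100 / (1 + (EC50/[agonist])^nH)`.
#' Inhibition: `Response(%) = (100 - minimum) / (1 + ([conc]/IC50)^nH) +
#' minimum`. Midpoints are passed as log10 of the molar concentration.
#'
#' @param conc Concentration(s), molar.
#' @param logEC50,logIC50 log10 of the midpoint (molar).
#' @param nH Hill slope.
#' @param minimum Residual response (%) at saturating inhibitor.
#' @return Response in percent of maximum.
#' @export
hill_activation <- function(conc, logEC50, nH) {
  100 / (1 + 10^(nH * (logEC50 - log10(conc))))
}

#' @rdname hill_activation
#' @export
hill_inhibition <- function(conc, logIC50, nH, minimum) {
  (100 - minimum) / (1 + 10^(nH * (log10(conc) - logIC50))) + minimum
}

# Multi-start least squares on the log10-concentration axis; returns the
# best optim() result with hessian.
hill_ls <- function(x_log, y, kind, starts_mid, lower, upper) {
  obj <- if (kind == "activation") {
    function(p) sum((y - 100 / (1 + 10^(p[2] * (p[1] - x_log))))^2)
  } else {
    function(p) sum((y - ((100 - p[3]) / (1 + 10^(p[2] * (x_log - p[1]))) + p[3]))^2)
  }
  best <- NULL
  for (s in starts_mid) {
    p0 <- if (kind == "activation") c(s, 1) else c(s, 1, 5)
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  # polish + curvature at the optimum
  best2 <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, hessian = TRUE,
                 control = list(maxit = 500, factr = 1e1)),
    error = function(e) NULL)
  if (!is.null(best2) && best2$value <= best$value) best <- best2
  if (is.null(best$hessian))
    best$hessian <- stats::optimHess(best$par, obj)
  best
}

hill_fit_one <- function(conc, resp, kind) {
  x <- log10(conc)
  lo_c <- min(x); hi_c <- max(x)
  starts <- c(lo_c, (lo_c + hi_c) / 2, hi_c)
  if (kind == "activation") {
    lower <- c(lo_c - 3, 0.1); upper <- c(hi_c + 3, 10)
  } else {
    # minimum constrained to (0, 100); lower bound kept strictly positive
    lower <- c(lo_c - 3, 0.1, 1e-3); upper <- c(hi_c + 3, 10, 99.9)
  }
  fit <- hill_ls(x, resp, kind, starts, lower, upper)
  p <- fit$par
  n <- length(resp); npar <- length(p)
  sigma2 <- fit$value / max(n - npar, 1)
  vcov <- tryCatch(2 * sigma2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  se <- suppressWarnings(sqrt(diag(vcov)))
  list(par = p, se = se, rss = fit$value, sigma2 = sigma2, n = n,
       at_bound = kind == "inhibition" && p[3] <= lower[3] * 1.001)
}

#' Fit the activation Hill model to concentration-response data
#'
#' Least-squares fit of `Response(%) = 100 / (1 + (EC50/[agonist])^nH)` with
#' the midpoint optimized as log10(EC50). Three starts spanning the tested
#' concentration range guard against local minima. The 95% CI on
#' log10(EC50) comes from the curvature (Gauss-Newton) approximation at the
#' optimum, or - when at least `per_cell_min` cells are present and
#' `ci = "auto"` - from the t-distribution spread of per-cell midpoints
#' (sample size = cells, matching how n is reported for oocyte recordings).
#'
#' @param data Data frame with columns `concentration_M` (molar, > 0),
#'   `response_pct`, and optionally `cell_id`.
#' @param ci `"auto"`, `"curvature"`, or `"per_cell"`.
#' @param per_cell_min Minimum number of cells for the per-cell CI route.
#' @return A `hill_fit` object: list with `kind`, `log10_midpoint`,
#'   `midpoint` (molar), `ci_log10` (95%), `nH`, `n_cells`, `n_points`,
#'   `rss`, `se_log10`, `flags`.
#' @export
fit_hill_activation <- function(data, ci = c("auto", "curvature", "per_cell"),
                                per_cell_min = 5) {
  ci <- match.arg(ci)
  check_series(data, min_conc = 4)
  f <- hill_fit_one(data$concentration_M, data$response_pct, "activation")
  finish_hill_fit(data, f, kind = "activation", ci = ci,
                  per_cell_min = per_cell_min)
}

#' Fit the inhibition Hill model to concentration-response data
#'
#' Least-squares fit of
#' `Response(%) = (100 - minimum) / (1 + ([conc]/IC50)^nH) + minimum`, with
#' `minimum` (residual response at saturation) constrained to (0, 100); a
#' fit driven to the lower bound is flagged. Otherwise as
#' [fit_hill_activation()].
#'
#' @inheritParams fit_hill_activation
#' @return A `hill_fit` object (adds `minimum`).
#' @export
fit_hill_inhibition <- function(data, ci = c("auto", "curvature", "per_cell"),
                                per_cell_min = 5) {
  ci <- match.arg(ci)
  check_series(data, min_conc = 5)
  f <- hill_fit_one(data$concentration_M, data$response_pct, "inhibition")
  finish_hill_fit(data, f, kind = "inhibition", ci = ci,
                  per_cell_min = per_cell_min)
}

check_series <- function(data, min_conc) {
  stopifnot(all(c("concentration_M", "response_pct") %in% names(data)))
  if (any(data$concentration_M <= 0)) stop("concentrations must be positive")
  if (length(unique(data$concentration_M)) < min_conc)
    stop("need >= ", min_conc, " distinct concentrations")
  invisible(data)
}

finish_hill_fit <- function(data, f, kind, ci, per_cell_min) {
  cells <- if ("cell_id" %in% names(data)) unique(data$cell_id) else NULL
  n_cells <- if (is.null(cells)) NA_integer_ else length(cells)
  use_per_cell <- switch(ci,
    per_cell = TRUE,
    curvature = FALSE,
    auto = !is.null(cells) && length(cells) >= per_cell_min)
  flags <- character(0)
  if (isTRUE(f$at_bound)) flags <- c(flags, "minimum_at_bound")
  span <- range(log10(data$concentration_M))
  if (f$par[1] < span[1] || f$par[1] > span[2])
    flags <- c(flags, "midpoint_outside_tested_range")
  if (use_per_cell) {
    mids <- vapply(cells, function(cl) {
      d <- data[data$cell_id == cl, ]
      tryCatch(hill_fit_one(d$concentration_M, d$response_pct, kind)$par[1],
               error = function(e) NA_real_)
    }, numeric(1))
    mids <- mids[!is.na(mids)]
    m <- mean(mids); s <- stats::sd(mids) / sqrt(length(mids))
    tq <- stats::qt(0.975, df = length(mids) - 1)
    ci_log <- c(m - tq * s, m + tq * s)
    se_log <- s
  } else {
    se_log <- f$se[1]
    tq <- stats::qt(0.975, df = max(f$n - length(f$par), 1))
    ci_log <- f$par[1] + c(-1, 1) * tq * se_log
  }
  out <- list(
    kind = kind,
    log10_midpoint = f$par[1],
    midpoint = 10^f$par[1],
    nH = f$par[2],
    minimum = if (kind == "inhibition") f$par[3] else NULL,
    ci_log10 = ci_log,
    se_log10 = se_log,
    n_cells = n_cells,
    n_points = f$n,
    rss = f$rss,
    ci_method = if (use_per_cell) "per_cell" else "curvature",
    flags = flags
  )
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$kind == "activation") "EC50" else "IC50"
  cat("<hill_fit> ", x$kind, ": ", lab, " = ",
      signif(x$midpoint * 1e6, 3), " uM (log10 M ",
      round(x$log10_midpoint, 3), "), nH = ", round(x$nH, 2), sep = "")
  if (!is.null(x$minimum)) cat(", minimum = ", round(x$minimum, 1), "%", sep = "")
  cat("\n  95% CI log10: [", round(x$ci_log10[1], 3), ", ",
      round(x$ci_log10[2], 3), "] (", x$ci_method, ")", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ","), sep = "")
  cat("\n")
  invisible(x)
}

#' Potency ratio between a reference and a variant fit
#'
#' Fold-shift convention of the summary tables: `midpoint(ref) /
#' midpoint(variant)`, so values below 1 mean the variant is less potent
#' (larger midpoint) than the reference.
#'
#' @param fit_ref,fit_var `hill_fit` objects of the same kind (and, by
#'   convention, the same compound - checked when both carry a `compound`
#'   attribute).
#' @return A `potency_ratio` list with `ratio`, `direction` and ids.
#' @export
potency_ratio <- function(fit_ref, fit_var) {
  stopifnot(inherits(fit_ref, "hill_fit"), inherits(fit_var, "hill_fit"))
  if (!identical(fit_ref$kind, fit_var$kind))
    stop("fits are of different kinds (activation vs inhibition)")
  ca <- attr(fit_ref, "compound"); cb <- attr(fit_var, "compound")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop("potency ratio across different compounds: ", ca, " vs ", cb)
  r <- fit_ref$midpoint / fit_var$midpoint
  structure(list(
    ratio = r,
    direction = if (r > 1) "variant more potent" else if (r < 1)
      "variant less potent" else "equal",
    ref = attr(fit_ref, "construct"), variant = attr(fit_var, "construct")),
    class = "potency_ratio")
}

#' @export
print.potency_ratio <- function(x, ...) {
  cat("<potency_ratio> ", signif(x$ratio, 2), " (", x$direction, ")\n", sep = "")
  invisible(x)
}

#' Compare per-cell log potencies across constructs
#'
#' `mode = "dunnett"`: one-way ANOVA followed by Dunnett many-to-one
#' comparisons against the control; the adjusted p-value is the probability,
#' under the joint null, that the largest absolute Dunnett statistic exceeds
#' the observed one, evaluated by Monte-Carlo simulation of the exact
#' multivariate-t structure (shared control, pooled error df; 10^5 draws,
#' fixed internal seed, RNG state restored). `mode = "welch-bonferroni"`:
#' pairwise Welch t-tests against the control with Bonferroni-adjusted p.
#'
#' @param groups Named list of numeric vectors (per-cell log10 midpoints by
#'   construct), or a data frame with columns `construct` and `value`.
#' @param control Name of the control construct.
#' @param mode `"dunnett"` or `"welch-bonferroni"`.
#' @param alpha Significance threshold (default 0.05).
#' @param nsim Monte-Carlo draws for the Dunnett null (default 1e5).
#' @return List with `anova` (F, df, p; Dunnett mode), `comparisons` data
#'   frame (estimate, t, p_unadjusted, p_adjusted, significant), `mode`,
#'   `alpha`.
#' @export
compare_log_potency <- function(groups, control,
                                mode = c("dunnett", "welch-bonferroni"),
                                alpha = 0.05, nsim = 1e5) {
  mode <- match.arg(mode)
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$construct)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (!control %in% names(groups)) stop("control group '", control, "' absent")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 cells")
  trt <- setdiff(names(groups), control)
  y0 <- groups[[control]]; n0 <- length(y0)

  if (mode == "welch-bonferroni") {
    comp <- do.call(rbind, lapply(trt, function(g) {
      tt <- stats::t.test(groups[[g]], y0, var.equal = FALSE)
      data.frame(construct = g, estimate = mean(groups[[g]]) - mean(y0),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_unadjusted = tt$p.value,
                 p_adjusted = min(1, tt$p.value * length(trt)),
                 stringsAsFactors = FALSE)
    }))
    comp$significant <- comp$p_adjusted < alpha
    return(list(anova = NULL, comparisons = comp, mode = mode, alpha = alpha))
  }

  # one-way ANOVA
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(vals ~ fac)
  an <- summary(fit)[[1]]
  df_err <- an$Df[2]
  mse <- an$`Mean Sq`[2]

  tstat <- vapply(trt, function(g) {
    (mean(groups[[g]]) - mean(y0)) /
      sqrt(mse * (1 / length(groups[[g]]) + 1 / n0))
  }, numeric(1))

  # simulate the joint null of max |T| over the treated groups
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(20230711)
  ni <- lengths(groups[trt])
  z0 <- stats::rnorm(nsim, sd = sqrt(1 / n0))
  s2 <- stats::rchisq(nsim, df = df_err) / df_err
  Tmax <- rep(0, nsim)
  for (j in seq_along(trt)) {
    zj <- stats::rnorm(nsim, sd = sqrt(1 / ni[j]))
    Tj <- abs(zj - z0) / sqrt(s2 * (1 / ni[j] + 1 / n0))
    Tmax <- pmax(Tmax, Tj)
  }
  p_adj <- vapply(abs(tstat), function(t0) mean(Tmax >= t0), numeric(1))
  p_un <- 2 * stats::pt(abs(tstat), df = df_err, lower.tail = FALSE)
  comp <- data.frame(
    construct = trt,
    estimate = vapply(trt, function(g) mean(groups[[g]]) - mean(y0), numeric(1)),
    t = tstat, df = df_err,
    p_unadjusted = p_un,
    p_adjusted = pmax(p_adj, p_un),
    significant = pmax(p_adj, p_un) < alpha,
    stringsAsFactors = FALSE)
  rownames(comp) <- NULL
  list(anova = list(F = an$`F value`[1],
                    df = c(an$Df[1], df_err),
                    p = an$`Pr(>F)`[1]),
       comparisons = comp, mode = mode, alpha = alpha)
}

#' Summarize per-cell measurements by construct
#'
#' Mean, standard error of the mean, and cell count for each construct and
#' measure, in the layout of the constitutive-activity summary tables.
#' Positive values denote increases of activity, negative decreases.
#'
#' @param data Data frame with a `construct` column and one or more numeric
#'   measure columns.
#' @param measures Character vector of measure column names (default: all
#'   numeric columns).
#' @return Data frame `construct`, `measure`, `mean`, `sem` (`NA` with a
#'   single cell), `n`.
#' @export
summarize_constructs <- function(data, measures = NULL) {
  stopifnot("construct" %in% names(data))
  if (is.null(measures))
    measures <- names(data)[vapply(data, is.numeric, logical(1))]
  out <- list()
  for (m in measures) {
    sp <- split(data[[m]], data$construct)
    sp <- sp[lengths(sp) > 0]
    out[[m]] <- data.frame(
      construct = names(sp),
      measure = m,
      mean = vapply(sp, mean, numeric(1)),
      sem = vapply(sp, function(v) if (length(v) < 2) NA_real_ else
        stats::sd(v) / sqrt(length(v)), numeric(1)),
      n = lengths(sp),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
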