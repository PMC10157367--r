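#' Convert a percentage extent to 5%-unit increments
#'
#' Extents enter Cox models as unit increments of 5 percentage points, with
#' a compressed first unit: extents in \[0, 1\]% map to unit 0, (1, 5\]% to
#' unit 1, (5, 10\]% to unit 2, and so on up to unit 20 at 100%.
#'
#' @param extent_pct Numeric vector of extents in \[0, 100\].
#' @return Integer vector of unit covariates in 0..20.
#' @export
extent_to_units <- function(extent_pct) {
  if (any(!is.finite(extent_pct)) || any(extent_pct < 0 | extent_pct > 100)) {
    stop("extents must lie in [0, 100]")
  }
  u <- integer(length(extent_pct))
  u[extent_pct > 1 & extent_pct <= 5] <- 1L
  above <- extent_pct > 5
  u[above] <- 1L + as.integer(ceiling((extent_pct[above] - 5) / 5))
  u
}

#' Cox proportional-hazards fit on unit-increment covariates
#'
#' Maximum partial likelihood with Efron tie handling via
#' [survival::coxph()]. Univariate (the unit covariate alone) or
#' multivariate with IPI Risk Group (categorical, `Low` as reference) and
#' MYC FISH status (binary, `Negative` as reference) as adjustment
#' covariates; adjustment uses complete cases.
#'
#' @param units Numeric unit covariate (one value per patient).
#' @param times,events Follow-up times (months) and event indicators (1 =
#'   death).
#' @param ipi_group,myc_fish Optional adjustment covariates; supplying either
#'   switches to the multivariate model.
#' @return One-row data frame (the unit covariate's effect): `log_hr`, `se`,
#'   `hr`, `ci95_lo`, `ci95_hi`, `p` (Wald), `n`, `events`.
#' @export
fit_cox <- function(units, times, events, ipi_group = NULL, myc_fish = NULL) {
  stopifnot(length(units) == length(times), length(times) == length(events))
  if (sum(events) < 1) stop("no events in cohort; Cox model undefined")
  dat <- data.frame(units = units, times = times, events = events)
  terms <- "units"
  if (!is.null(ipi_group)) {
    dat$ipi_group <- factor(ipi_group, levels = c("Low", "Intermediate", "High"))
    terms <- c(terms, "ipi_group")
  }
  if (!is.null(myc_fish)) {
    dat$myc_fish <- factor(myc_fish, levels = c("Negative", "Positive"))
    terms <- c(terms, "myc_fish")
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (stats::sd(dat$units) == 0) stop("unit covariate is constant")
  fml <- stats::as.formula(paste("survival::Surv(times, events) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) && isTRUE(grepl("fail", fit$info))) {
    stop("Cox model failed to converge")
  }
  s <- summary(fit)
  i <- match("units", rownames(s$coefficients))
  log_hr <- s$coefficients[i, "coef"]
  se <- s$coefficients[i, "se(coef)"]
  data.frame(log_hr = log_hr, se = se, hr = exp(log_hr),
             ci95_lo = exp(log_hr - 1.96 * se),
             ci95_hi = exp(log_hr + 1.96 * se),
             p = s$coefficients[i, "Pr(>|z|)"],
             n = fit$n, events = fit$nevent)
}

#' Paule-Mandel random-effects pooling of Cox effects
#'
#' Finds the between-study variance tau^2 >= 0 solving the Paule-Mandel
#' moment equation `sum w_i (theta_i - theta_hat)^2 = k - 1` with
#' `w_i = 1 / (se_i^2 + tau^2)` and `theta_hat` the weighted mean, then
#' reports the pooled log hazard ratio, its standard error, the z-based
#' pooled p value, and the Bonferroni-adjusted p over the eight
#' subpopulation hypotheses. A single fit passes through with tau^2 = 0.
#'
#' @param fits Data frame of per-cohort fits with columns `log_hr`, `se`
#'   (e.g. rbind-ed [fit_cox()] rows).
#' @param n_hypotheses Bonferroni multiplier (default 8, the number of
#'   subpopulations tested).
#' @param p_method `"z"` (default; p from the random-effects z statistic) or
#'   `"stouffer"` (pooling the per-cohort one-sided p values by Stouffer's
#'   method, equal weights).
#' @return One-row data frame: `pooled_log_hr`, `pooled_se`, `pooled_hr`,
#'   `ci95_lo`, `ci95_hi`, `tau2`, `pooled_p`, `bonferroni_p`, `k`.
#' @export
pool_random_effects <- function(fits, n_hypotheses = 8,
                                p_method = c("z", "stouffer")) {
  p_method <- match.arg(p_method)
  theta <- fits$log_hr
  se <- fits$se
  if (any(se <= 0)) stop("all standard errors must be positive")
  k <- length(theta)
  if (k == 1) {
    tau2 <- 0
    pooled <- theta
    pooled_se <- se
  } else {
    q_stat <- function(tau2) {
      w <- 1 / (se^2 + tau2)
      th <- sum(w * theta) / sum(w)
      sum(w * (theta - th)^2) - (k - 1)
    }
    tau2 <- if (q_stat(0) <= 0) 0 else {
      hi <- stats::var(theta) + max(se)^2
      while (q_stat(hi) > 0) hi <- hi * 2
      stats::uniroot(q_stat, c(0, hi), tol = 1e-12)$root
    }
    w <- 1 / (se^2 + tau2)
    pooled <- sum(w * theta) / sum(w)
    pooled_se <- sqrt(1 / sum(w))
  }
  pooled_p <- if (p_method == "z") {
    2 * stats::pnorm(-abs(pooled / pooled_se))
  } else {
    z <- stats::qnorm(stats::pnorm(-theta / se))  # one-sided, direction-aware
    zs <- sum(z) / sqrt(k)
    2 * stats::pnorm(-abs(zs))
  }
  data.frame(pooled_log_hr = pooled, pooled_se = pooled_se,
             pooled_hr = exp(pooled),
             ci95_lo = exp(pooled - 1.96 * pooled_se),
             ci95_hi = exp(pooled + 1.96 * pooled_se),
             tau2 = tau2, pooled_p = pooled_p,
             bonferroni_p = min(1, n_hypotheses * pooled_p), k = k)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param times,events Follow-up times and event indicators.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List with `curves` (data frame: `group`, `time`, `surv`,
#'   `lower`, `upper` with Greenwood-based 95% CI), `logrank_p`, `chisq`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop("at least 2 non-empty groups are required")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  curves <- data.frame(group = sub("^groups=", "", as.character(sm$strata)),
                       time = sm$time, surv = sm$surv,
                       lower = sm$lower, upper = sm$upper)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(curves = curves,
       logrank_p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       chisq = sd$chisq)
}

#' Scan dichotomization cutoffs for the greatest prognostic effect
#'
#' For every candidate cutoff (default 1% steps over the observed extent
#' range), patients are dichotomized at extent >= cutoff and a two-group Cox
#' model is fitted; the optimal cutoff is the one with the largest hazard
#' ratio among cutoffs leaving at least `min_group_frac` of patients in each
#' group (alternatively the smallest p value).
#'
#' @param extents Percentage extents (or metric values) per patient.
#' @param times,events Survival columns.
#' @param step_pct Cutoff grid step (default 1).
#' @param min_group_frac Minimum fraction of patients per group (default 0.1).
#' @param optimal `"hr"` (default) or `"p"`.
#' @return List with `table` (cutoff, hr, ci, p, group sizes) and
#'   `optimal_cutoff`.
#' @export
scan_cutoff <- function(extents, times, events, step_pct = 1,
                        min_group_frac = 0.1, optimal = c("hr", "p")) {
  optimal <- match.arg(optimal)
  n <- length(extents)
  if (n < 20) stop("at least 20 patients are required for a cutoff scan")
  cuts <- seq(ceiling(min(extents)), floor(max(extents)), by = step_pct)
  rows <- lapply(cuts, function(cut) {
    high <- extents >= cut
    n_high <- sum(high)
    if (min(n_high, n - n_high) < min_group_frac * n) return(NULL)
    if (sum(events[high]) == 0 || sum(events[!high]) == 0) return(NULL)
    fit <- survival::coxph(survival::Surv(times, events) ~ high, ties = "efron")
    s <- summary(fit)$coefficients
    data.frame(cutoff = cut, hr = exp(s[1, "coef"]),
               ci95_lo = exp(s[1, "coef"] - 1.96 * s[1, "se(coef)"]),
               ci95_hi = exp(s[1, "coef"] + 1.96 * s[1, "se(coef)"]),
               p = s[1, "Pr(>|z|)"], n_high = n_high, n_low = n - n_high)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no cutoff satisfies the group-size guard")
  tab <- do.call(rbind, rows)
  best <- if (optimal == "hr") which.max(tab$hr) else which.min(tab$p)
  list(table = tab, optimal_cutoff = tab$cutoff[best])
}
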