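# Statistical plan: normality screen, nonparametric group tests, Spearman
# correlations, Cox proportional hazards (with the 300-day step function
# for postoperative KPS), Schoenfeld-residual proportionality checks and
# Kaplan-Meier curves. The machinery is the `survival` package and base
# `stats`; this module fixes the conventions (two-sided p, Efron ties,
# complete-case per model, half-open (start, stop] episodes).

#' Shapiro-Wilk normality screen
#'
#' @param values numeric vector, n >= 3, non-constant. For n > 5000 (the
#'   test's limit) a deterministic even thinning by index is applied.
#' @return list with `statistic`, `p` and `normal` (p >= 0.05)
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("normality_screen: need n >= 3")
  if (sd(values) == 0) stop("normality_screen: zero variance")
  if (length(values) > 5000) {
    values <- values[unique(as.integer(round(
      seq(1, length(values), length.out = 5000))))]
  }
  s <- shapiro.test(values)
  list(statistic = unname(s$statistic), p = s$p.value,
       normal = s$p.value >= 0.05)
}

#' Nonparametric group comparison
#'
#' Mann-Whitney U (two groups) or Kruskal-Wallis (three or more), selected
#' automatically -- the convention for non-normally distributed measures.
#'
#' @param values numeric vector
#' @param groups factor-like, same length; >= 2 groups, each non-empty
#' @return list with `test` ("mann_whitney"/"kruskal_wallis"),
#'   `statistic`, `p` (two-sided) and `group_medians`
#' @export
group_compare <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2) stop("group_compare: need at least 2 groups")
  med <- tapply(values, groups, median)
  if (k == 2) {
    w <- suppressWarnings(wilcox.test(values ~ groups))
    list(test = "mann_whitney", statistic = unname(w$statistic),
         p = w$p.value, group_medians = med)
  } else {
    kw <- kruskal.test(values, groups)
    list(test = "kruskal_wallis", statistic = unname(kw$statistic),
         p = kw$p.value, group_medians = med)
  }
}

#' Spearman rank correlation
#'
#' @param x,y paired numeric vectors, n >= 3 after removing incomplete
#'   pairs; neither may be constant
#' @return list with `rs`, `p` (two-sided, asymptotic with ties) and `n`
#' @export
spearman_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("spearman_corr: need n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("spearman_corr: constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rs = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Split follow-up into episodes at a landmark day
#'
#' Counting-process coding of the step function used to rescue the
#' proportional hazards assumption for postoperative KPS: follow-up is
#' split at `split_day` so KPS can receive one hazard ratio before and one
#' after. Intervals are half-open `(start, stop]`; an event exactly at the
#' split day belongs to the first episode. `kps_early` carries the KPS
#' value in the first episode and 0 in the second; `kps_late` vice versa.
#'
#' @param cohort data frame with `survival_days`, `event`, `kps_post` and
#'   any other covariates (carried through)
#' @param split_day landmark in days (default 300)
#' @return an episode data frame with `start`, `stop`,
#'   `event` (per episode), `kps_early`, `kps_late`
#' @export
build_episodes <- function(cohort, split_day = 300) {
  if (!all(c("survival_days", "event") %in% names(cohort))) {
    stop("build_episodes: cohort must have survival_days and event")
  }
  if (any(cohort$survival_days < 0)) stop("build_episodes: negative times")
  if (any(cohort$survival_days == 0)) {
    stop("build_episodes: zero follow-up time")
  }
  kps <- cohort$kps_post %||% rep(NA_real_, nrow(cohort))
  one <- cohort$survival_days <= split_day
  first <- cohort
  first$start <- 0
  first$stop <- pmin(cohort$survival_days, split_day)
  first$event <- cohort$event & one
  first$kps_early <- kps
  first$kps_late <- 0
  second <- cohort[!one, , drop = FALSE]
  if (nrow(second) > 0) {
    second$start <- split_day
    second$stop <- second$survival_days
    second$event <- cohort$event[!one]
    second$kps_early <- 0
    second$kps_late <- kps[!one]
  }
  out <- rbind(first, second)
  out[order(out$case_id, out$start), , drop = FALSE]
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood estimation with Efron tie handling by default,
#' Wald 95% confidence intervals and p-values, Harrell's C-index and
#' AIC (-2 log partial likelihood + 2k). Accepts either a plain cohort
#' (columns `survival_days`, `event`) or an episode table from
#' [build_episodes()] (columns `start`, `stop`, `event`), and fits
#' complete cases on the requested predictors.
#'
#' @param data cohort or episode data frame
#' @param predictors character vector of column names to enter linearly
#' @param ties "efron" (default) or "breslow"
#' @return a `cox_model_result`: `table` (one row per predictor: `hr`,
#'   `ci95_low`, `ci95_high`, `p`), `c_index`, `aic`, `n_used`,
#'   `n_events`; the underlying `coxph` fit is attached as attribute "fit"
#' @export
cox_fit <- function(data, predictors, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols) > 0) {
    stop("cox_fit: missing predictor columns: ",
         paste(missing_cols, collapse = ", "))
  }
  episodic <- all(c("start", "stop") %in% names(data))
  data <- data[complete.cases(data[, predictors, drop = FALSE]), ,
               drop = FALSE]
  n_used <- if (episodic && "case_id" %in% names(data)) {
    length(unique(data$case_id))
  } else {
    nrow(data)
  }
  if (sum(data$event) < 2) stop("cox_fit: need at least 2 events")
  const <- predictors[vapply(predictors,
                             function(p) {
                               v <- data[[p]]
                               if (!is.numeric(v)) v <- as.numeric(as.factor(v))
                               sd(v) == 0
                             }, TRUE)]
  if (length(const) > 0) {
    stop("cox_fit: constant predictor: ", paste(const, collapse = ", "))
  }
  surv <- if (episodic) "survival::Surv(start, stop, event)"
          else "survival::Surv(survival_days, event)"
  fml <- as.formula(paste(surv, "~", paste(predictors, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties, x = TRUE)
  beta <- coef(fit)
  if (any(is.na(beta))) {
    stop("cox_fit: estimation failed (separation or collinearity) for: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  se <- sqrt(diag(fit$var))
  z <- beta / se
  tab <- data.frame(
    predictor = names(beta),
    hr = exp(beta),
    ci95_low = exp(beta - qnorm(0.975) * se),
    ci95_high = exp(beta + qnorm(0.975) * se),
    p = 2 * pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE)
  res <- structure(
    list(table = tab,
         c_index = unname(fit$concordance["concordance"]),
         aic = AIC(fit),
         n_used = n_used,
         n_events = sum(data$event),
         ties = ties),
    class = "cox_model_result")
  attr(res, "fit") <- fit
  res
}

#' @export
print.cox_model_result <- function(x, ...) {
  cat(sprintf("Cox model (C-index = %.3f, AIC = %.0f) [n = %d, events = %d]\n",
              x$c_index, x$aic, x$n_used, x$n_events))
  tab <- x$table
  tab$hr <- sprintf("%.3f", tab$hr)
  tab$ci95 <- sprintf("%.3f-%.3f", x$table$ci95_low, x$table$ci95_high)
  tab$p <- format.pval(x$table$p, digits = 2)
  print(tab[, c("predictor", "hr", "ci95", "p")], row.names = FALSE)
  invisible(x)
}

#' Proportional hazards check (scaled Schoenfeld residuals)
#'
#' Per-predictor correlation of the scaled Schoenfeld residuals with
#' (Kaplan-Meier transformed) time, and the score test p-value of
#' `survival::cox.zph`. A predictor is flagged when p < 0.05.
#'
#' @param result a `cox_model_result` from [cox_fit()]
#' @return data frame: `predictor`, `rho`, `p`, `violated`
#' @export
proportionality_check <- function(result) {
  fit <- attr(result, "fit")
  if (is.null(fit)) stop("proportionality_check: no fitted model attached")
  z <- survival::cox.zph(fit, transform = "km")
  nm <- rownames(z$table)
  nm <- nm[nm != "GLOBAL"]
  rho <- vapply(seq_along(nm),
                function(j) suppressWarnings(cor(z$x, z$y[, j])), numeric(1))
  p <- z$table[nm, "p"]
  data.frame(predictor = nm, rho = rho, p = unname(p),
             violated = unname(p) < 0.05,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves by group
#'
#' Product-limit estimates per stratum plus the two-sided log-rank test.
#' Median splits use `<= median` vs `> median`, the usual biomarker
#' dichotomisation for display.
#'
#' @param cohort data frame with `survival_days`, `event` and the grouping
#'   column
#' @param group_by "median_split_csa", "median_split_si", "eor_category"
#'   or "custom"
#' @param custom_groups factor-like, required when `group_by = "custom"`
#' @return list of class `km_result`: `curves` (named list of data frames
#'   `time`, `surv`, `n_risk`), `medians` (KM median per group),
#'   `logrank_p`, `group_sizes`
#' @export
km_curves <- function(cohort,
                      group_by = c("median_split_csa", "median_split_si",
                                   "eor_category", "custom"),
                      custom_groups = NULL) {
  group_by <- match.arg(group_by)
  grp <- switch(group_by,
    median_split_csa = {
      m <- median(cohort$csa_cm2, na.rm = TRUE)
      factor(ifelse(cohort$csa_cm2 <= m, "low", "high"), c("low", "high"))
    },
    median_split_si = {
      m <- median(cohort$si, na.rm = TRUE)
      factor(ifelse(cohort$si <= m, "low", "high"), c("low", "high"))
    },
    eor_category = factor(ifelse(cohort$eor_percent >= 100, "GTR", "STR"),
                          c("GTR", "STR")),
    custom = {
      if (is.null(custom_groups)) stop("km_curves: custom_groups required")
      as.factor(custom_groups)
    })
  keep <- !is.na(grp) & is.finite(cohort$survival_days)
  cohort <- cohort[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  if (nlevels(grp) < 1) stop("km_curves: empty stratum")
  ev <- tapply(cohort$event, grp, sum)
  if (any(is.na(ev)) || any(ev < 1)) {
    stop("km_curves: every stratum needs at least one event")
  }
  d <- data.frame(survival_days = cohort$survival_days,
                  event = cohort$event, grp = grp)
  sf <- survival::survfit(survival::Surv(survival_days, event) ~ grp,
                          data = d)
  ssf <- summary(sf, censored = TRUE)
  stratum <- if (is.null(ssf$strata)) {
    rep(levels(grp)[1], length(ssf$time))
  } else {
    sub("^grp=", "", as.character(ssf$strata))
  }
  curves <- lapply(split(seq_along(ssf$time), stratum), function(i) {
    data.frame(time = ssf$time[i], surv = ssf$surv[i],
               n_risk = ssf$n.risk[i])
  })
  med <- summary(sf)$table
  medians <- if (is.null(dim(med))) unname(med["median"]) else {
    stats::setNames(med[, "median"], sub("^grp=", "", rownames(med)))
  }
  logrank_p <- NA_real_
  if (nlevels(grp) >= 2) {
    sd0 <- survival::survdiff(survival::Surv(survival_days, event) ~ grp,
                              data = d)
    logrank_p <- 1 - stats::pchisq(sd0$chisq, length(sd0$n) - 1)
  }
  structure(list(curves = curves, medians = medians,
                 logrank_p = logrank_p, group_sizes = table(grp)),
            class = "km_result")
}
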