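# Cohort-level analysis report: descriptive statistics, univariable
# screens, the two multivariable Cox models and Kaplan-Meier figure data.

measure_columns <- c(csa = "csa_cm2", volume = "volume_ml",
                     av = "av_per_cm", si = "si")

#' Full statistical report for a cohort
#'
#' Renders the pipeline's statistical plan on a cohort table:
#' \itemize{
#' \item descriptive medians and quartiles of the tumor measures, EOR and
#'   survival (months, days / 30.4375);
#' \item univariable screens: Spearman correlations of each measure (CSA,
#'   volume, A/V, SI) with age, EOR and KPS; Mann-Whitney comparisons by
#'   sex and MGMT status; univariable Cox models per measure;
#' \item two multivariable Cox models -- the "CSA model" and the "SI
#'   model" -- each adjusting for preoperative volume, MGMT methylation,
#'   age, postoperative KPS split at `split_day` (one HR before, one
#'   after) and EOR (as a 0-1 fraction);
#' \item Kaplan-Meier curves for CSA and SI median splits and for GTR vs
#'   STR, with log-rank p-values.
#' }
#' Model membership is fixed (not selected from the univariable screen);
#' missing data are handled complete-case per model; p-values are not
#' adjusted for multiplicity unless `p_adjust = "BH"`.
#'
#' @param cohort data frame; required columns: `case_id`, `age`, `sex`,
#'   `mgmt`, `kps_post`, `volume_ml`, `si`, `csa_cm2`, `av_per_cm`,
#'   `eor_percent`, `survival_days`, `event`
#' @param config list of options: `split_day` (300), `ties` ("efron"),
#'   `p_adjust` ("none" or "BH")
#' @return an `analysis_report` list: `descriptive`, `spearman`,
#'   `group_tests`, `cox_univariable`, `cox_csa_model`, `cox_si_model`,
#'   `proportionality`, `km`, `config`
#' @export
analysis_report <- function(cohort, config = list()) {
  cfg <- modifyList(list(split_day = 300, ties = "efron",
                         p_adjust = "none"), config)
  required <- c("case_id", "age", "sex", "mgmt", "kps_post", "volume_ml",
                "si", "csa_cm2", "av_per_cm", "eor_percent",
                "survival_days", "event")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("analysis_report: missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cohort <- cohort[order(cohort$case_id), , drop = FALSE]

  q13 <- function(x) {
    x <- x[is.finite(x)]
    c(median = median(x), q1 = unname(quantile(x, 0.25)),
      q3 = unname(quantile(x, 0.75)))
  }
  desc_vars <- c(tsa_cm2 = "tsa_cm2", csa_cm2 = "csa_cm2",
                 volume_ml = "volume_ml", av_per_cm = "av_per_cm",
                 si = "si", eor_percent = "eor_percent")
  desc_vars <- desc_vars[desc_vars %in% names(cohort)]
  desc <- do.call(rbind, lapply(names(desc_vars), function(v) {
    s <- q13(cohort[[desc_vars[[v]]]])
    data.frame(variable = v, median = s["median"], q1 = s["q1"],
               q3 = s["q3"], row.names = NULL)
  }))
  s <- q13(cohort$survival_days / DAYS_PER_MONTH)
  desc <- rbind(desc, data.frame(variable = "survival_months",
                                 median = s["median"], q1 = s["q1"],
                                 q3 = s["q3"], row.names = NULL))

  sp_rows <- list()
  for (m in names(measure_columns)) {
    for (v in c("age", "eor_percent", "kps_post")) {
      r <- tryCatch(spearman_corr(cohort[[measure_columns[[m]]]],
                                  cohort[[v]]),
                    error = function(e) list(rs = NA, p = NA, n = 0))
      sp_rows[[length(sp_rows) + 1]] <-
        data.frame(measure = m, against = v, rs = r$rs, p = r$p, n = r$n)
    }
  }
  spearman_tab <- do.call(rbind, sp_rows)

  gt_rows <- list()
  for (m in names(measure_columns)) {
    for (g in c("sex", "mgmt")) {
      r <- tryCatch(group_compare(cohort[[measure_columns[[m]]]],
                                  cohort[[g]]),
                    error = function(e) NULL)
      if (is.null(r)) next
      gt_rows[[length(gt_rows) + 1]] <- data.frame(
        measure = m, by = g, test = r$test, statistic = r$statistic,
        p = r$p,
        medians = paste(sprintf("%s=%.3g", names(r$group_medians),
                                r$group_medians), collapse = "; "))
    }
  }
  group_tab <- do.call(rbind, gt_rows)

  uni <- do.call(rbind, lapply(names(measure_columns), function(m) {
    f <- cox_fit(cohort, measure_columns[[m]], ties = cfg$ties)
    cbind(measure = m, f$table, n_used = f$n_used)
  }))

  cohort$mgmt_methylated <- as.numeric(cohort$mgmt == "methylated")
  cohort$eor_frac <- cohort$eor_percent / 100
  epi <- build_episodes(cohort, split_day = cfg$split_day)
  adjusters <- c("volume_ml", "mgmt_methylated", "age",
                 "kps_early", "kps_late", "eor_frac")
  csa_model <- cox_fit(epi, c("csa_cm2", adjusters), ties = cfg$ties)
  si_model <- cox_fit(epi, c("si", adjusters), ties = cfg$ties)
  prop <- list(csa_model = proportionality_check(csa_model),
               si_model = proportionality_check(si_model))

  if (cfg$p_adjust == "BH") {
    spearman_tab$p_adj <- stats::p.adjust(spearman_tab$p, "BH")
    group_tab$p_adj <- stats::p.adjust(group_tab$p, "BH")
  }

  km <- list(
    csa_median = km_curves(cohort, "median_split_csa"),
    si_median = km_curves(cohort, "median_split_si"),
    eor = tryCatch(km_curves(cohort, "eor_category"),
                   error = function(e) NULL))

  structure(list(descriptive = desc, spearman = spearman_tab,
                 group_tests = group_tab, cox_univariable = uni,
                 cox_csa_model = csa_model, cox_si_model = si_model,
                 proportionality = prop, km = km, config = cfg,
                 n = nrow(cohort)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("== analysis report (n = %d) ==\n\n", x$n))
  cat("Descriptive statistics (median [Q1-Q3]):\n")
  d <- x$descriptive
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-16s %8.3g [%.3g-%.3g]\n", d$variable[i], d$median[i],
                d$q1[i], d$q3[i]))
  }
  cat("\nCSA model:\n")
  print(x$cox_csa_model)
  cat("\nSI model:\n")
  print(x$cox_si_model)
  if (!is.null(x$km$csa_median)) {
    cat(sprintf("\nLog-rank p (CSA median split): %.4g\n",
                x$km$csa_median$logrank_p))
    cat(sprintf("Log-rank p (SI median split):  %.4g\n",
                x$km$si_median$logrank_p))
  }
  invisible(x)
}
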