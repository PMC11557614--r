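test_that("normality screen separates skewed from normal draws", {
  skewed <- local({ set.seed(42); rlnorm(5000, 0, 1) })
  expect_false(normality_screen(skewed)$normal)
  normalv <- local({ set.seed(42); rnorm(5000) })
  expect_true(normality_screen(normalv)$normal)
  expect_error(normality_screen(c(1, 2)), "n >= 3")
  expect_error(normality_screen(rep(1, 10)), "zero variance")
})

test_that("group comparison picks the right test and handles ties", {
  same <- c(1, 2, 3, 4, 5)
  r <- group_compare(c(same, same), rep(c("a", "b"), each = 5))
  expect_equal(r$test, "mann_whitney")
  expect_gt(r$p, 0.99)

  r2 <- group_compare(c(1, 2, 3, 101, 102, 103),
                      rep(c("a", "b"), each = 3))
  expect_equal(unname(r2$statistic), 0)     # U = 0
  expect_equal(r2$p, 0.1, tolerance = 1e-12)  # exact two-sided, n = 3,3
  expect_equal(as.numeric(r2$group_medians), c(2, 102))

  r3 <- group_compare(c(1, 2, 3, 4, 5, 6),
                      rep(c("a", "b", "c"), each = 2))
  expect_equal(r3$test, "kruskal_wallis")
  expect_error(group_compare(1:5, rep("a", 5)), "2 groups")
})

test_that("spearman matches the first-principles rank formula", {
  expect_equal(spearman_corr(1:7, (1:7)^3)$rs, 1)
  expect_equal(spearman_corr(1:7, -(1:7))$rs, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  expect_equal(spearman_corr(x, y)$rs, spearman_oracle(x, y),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(40); b <- a + rnorm(40)
    expect_equal(spearman_corr(a, b)$rs, spearman_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_corr(1:2, 1:2), "n >= 3")
})

test_that("episode splitting follows the (start, stop] convention", {
  coh <- data.frame(case_id = c("a", "b", "c"),
                    survival_days = c(100, 400, 300),
                    event = c(TRUE, FALSE, TRUE),
                    kps_post = c(80, 60, 70))
  epi <- build_episodes(coh, split_day = 300)
  a <- epi[epi$case_id == "a", ]
  expect_equal(nrow(a), 1)
  expect_equal(c(a$start, a$stop), c(0, 100))
  expect_true(a$event)
  expect_equal(a$kps_early, 80)
  expect_equal(a$kps_late, 0)

  b <- epi[epi$case_id == "b", ]
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(0, 300))
  expect_equal(b$stop, c(300, 400))
  expect_false(any(b$event))
  expect_equal(b$kps_early, c(60, 0))
  expect_equal(b$kps_late, c(0, 60))

  # boundary: event exactly at the split day stays in the first episode
  c3 <- epi[epi$case_id == "c", ]
  expect_equal(nrow(c3), 1)
  expect_equal(c(c3$start, c3$stop), c(0, 300))
  expect_true(c3$event)

  expect_error(build_episodes(data.frame(case_id = "x",
                                         survival_days = -1,
                                         event = TRUE, kps_post = 70)),
               "negative")
})

test_that("episodes conserve follow-up time and events", {
  coh <- toy_cohort(400, seed = 2, accrual = 1200)
  epi <- build_episodes(coh, 300)
  span <- tapply(epi$stop - epi$start, epi$case_id, sum)
  expect_equal(as.numeric(span[coh$case_id]), as.numeric(coh$survival_days))
  expect_equal(sum(epi$event), sum(coh$event))
  # at most one event per case, in its last episode
  last <- tapply(seq_len(nrow(epi)), epi$case_id, max)
  expect_true(all(!epi$event[-unname(last)]))
})

test_that("cox_fit matches the brute-force partial-likelihood oracle", {
  time <- c(1, 2, 3, 4)
  event <- rep(TRUE, 4)
  x <- c(1, 0, 1, 0)    # interleaved: finite maximiser
  beta_bf <- brute_force_cox(time, event, x)
  d <- data.frame(survival_days = time, event = event, g = x)
  fit <- cox_fit(d, "g")
  expect_equal(log(fit$table$hr), beta_bf, tolerance = 1e-4)
  # a perfectly separating instance has no finite MLE: oracle says so
  expect_true(is.na(brute_force_cox(time, event, c(1, 1, 0, 0))))
})

test_that("cox_fit reports errors, C-index and AIC sensibly", {
  d <- data.frame(survival_days = 1:10, event = rep(TRUE, 10),
                  g = rep(1, 10))
  expect_error(cox_fit(d, "g"), "constant predictor")
  d2 <- data.frame(survival_days = 1:10,
                   event = c(TRUE, rep(FALSE, 9)), g = rnorm(10))
  expect_error(cox_fit(d2, "g"), "2 events")
  expect_error(cox_fit(d2, "missing_col"), "missing predictor")

  # strong effect: C-index > 0.5 on a fresh draw; AIC improves vs weak fit
  coh <- toy_cohort(1000, seed = 5, log_hr = c(age = log(2) / 10))
  fit <- cox_fit(coh, "age")
  expect_gt(fit$c_index, 0.5)
  fresh <- toy_cohort(1000, seed = 6, log_hr = c(age = log(2) / 10))
  risk <- fresh$age  # per-subject linear predictor up to scale
  cc <- survival::concordance(
    survival::Surv(survival_days, event) ~ risk, data = fresh,
    reverse = TRUE)
  expect_gt(cc$concordance, 0.5)
  # AIC: adding the generating predictor beats a pure-noise predictor
  coh$noise <- local({ set.seed(1); rnorm(nrow(coh)) })
  expect_lt(cox_fit(coh, "age")$aic, cox_fit(coh, "noise")$aic)

  # n_used is complete-case
  coh2 <- coh
  coh2$age[1:25] <- NA
  expect_equal(cox_fit(coh2, "age")$n_used, nrow(coh) - 25)
})

test_that("proportionality check flags the decaying KPS effect only", {
  coh <- toy_cohort(2000, seed = 13,
                    log_hr = c(kps = log(0.934), si = log(2.223)),
                    shape = 1.2, scale = 579, accrual = 3652,
                    kps_decay_day = 300)
  fit <- cox_fit(coh, c("kps_post", "si"))
  z <- proportionality_check(fit)
  expect_true(z$violated[z$predictor == "kps_post"])
  expect_false(z$violated[z$predictor == "si"])
  epi <- build_episodes(coh, 300)
  fit2 <- cox_fit(epi, c("kps_early", "kps_late", "si"))
  z2 <- proportionality_check(fit2)
  expect_false(z2$violated[z2$predictor == "kps_early"])
  expect_false(z2$violated[z2$predictor == "kps_late"])
  # the split recovers the early effect and a near-null late effect
  tab <- fit2$table
  expect_lt(abs(log(tab$hr[tab$predictor == "kps_early"]) - log(0.934)),
            0.02)
  expect_lt(abs(log(tab$hr[tab$predictor == "kps_late"])), 0.01)
})

test_that("Kaplan-Meier estimates follow closed forms", {
  # all events, one group: steps of 1/n at each event time
  d <- data.frame(survival_days = c(3, 1, 4, 2, 5),
                  event = rep(TRUE, 5))
  km <- km_curves(d, "custom", custom_groups = rep("g", 5))
  cur <- km$curves[["g"]]
  expect_equal(cur$surv[order(cur$time)], seq(0.8, 0, by = -0.2),
               tolerance = 1e-12)

  # no censoring: KM equals the empirical survival function
  coh <- toy_cohort(300, seed = 17, accrual = 1e7)
  km2 <- km_curves(coh, "custom", custom_groups = rep("g", nrow(coh)))
  cur2 <- km2$curves[["g"]]
  emp <- vapply(cur2$time, function(t) mean(coh$survival_days > t),
                numeric(1))
  expect_equal(cur2$surv, emp, tolerance = 1e-12)

  # two identical groups: log-rank null
  dd <- rbind(coh, coh)
  grp <- rep(c("a", "b"), each = nrow(coh))
  expect_gt(km_curves(dd, "custom", custom_groups = grp)$logrank_p, 0.5)

  # survival non-increasing from 1
  for (cu in km2$curves) {
    expect_true(all(diff(cu$surv[order(cu$time)]) <= 0))
    expect_true(all(cu$surv <= 1))
  }
  expect_error(km_curves(coh[0, ], "custom", custom_groups = character(0)),
               "stratum")
})

test_that("analysis_report renders the full table structure", {
  coh <- simulate_cohort(cohort_spec(n = 500, seed = 33))
  rep <- analysis_report(coh)
  expect_equal(nrow(rep$cox_csa_model$table), 7)
  expect_equal(nrow(rep$cox_si_model$table), 7)
  expect_setequal(rep$cox_si_model$table$predictor,
                  c("si", "volume_ml", "mgmt_methylated", "age",
                    "kps_early", "kps_late", "eor_frac"))
  expect_equal(nrow(rep$spearman), 12)   # 4 measures x {age, EOR, KPS}
  expect_true(all(c("csa", "volume", "av", "si") %in%
                    rep$cox_univariable$measure))
  expect_s3_class(rep$km$csa_median, "km_result")

  # order invariance
  perm <- coh[rev(seq_len(nrow(coh))), ]
  rep2 <- analysis_report(perm)
  expect_equal(rep2$cox_si_model$table$hr, rep$cox_si_model$table$hr,
               tolerance = 1e-12)
  expect_equal(rep2$descriptive$median, rep$descriptive$median)

  # degenerate input propagates a cox error; missing columns are config errors
  expect_error(analysis_report(coh[1:2, ]), "cox_fit")
  expect_error(analysis_report(coh[, setdiff(names(coh), "age")]),
               "missing required columns: age")
})
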