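# Synthetic glioblastoma cohorts.
#
# Covariates are sampled to match the marginal structure reported for
# resected, unifocal, IDH-wildtype glioblastoma cohorts (median volume
# ~30.7 mL, median SI ~1.26, ~87% dura-contacting with a median 7.5% of the
# surface covered, ~60% male, ~46% MGMT methylated, EOR median ~98.4% with
# a GTR point mass). CSA is not sampled: it is derived through the exact
# geometric identity CSA = (1 - d) * SI * A_sphere(V), the same definition
# the morphometry uses. Survival is generated under a Weibull proportional
# hazards model with a configurable log-hazard vector (defaults follow the
# multivariable SI-model estimates: SI HR 2.223, MGMT 0.475, age 1.037 per
# year, KPS 0.934 per point, EOR 0.142 per unit fraction), with uniform
# accrual and a single administrative end of follow-up.

default_covariate_params <- function() {
  list(
    volume = list(meanlog = log(30.7), sdlog = 1.269),
    si = list(meanlog = log(0.26), sdlog = 0.83),          # SI = 1 + lognormal
    dural = list(p_contact = 0.87, meanlog = log(0.075), sdlog = 0.7,
                 cap = 0.6),
    age = list(mean = 65, sd = 10, min = 18, max = 90),
    sex = list(p_male = 163 / 271),
    mgmt = list(p_methylated = 122 / 265),
    kps = list(values = seq(40, 100, 10),
               probs = c(0.02, 0.04, 0.09, 0.15, 0.25, 0.30, 0.15)),
    eor = list(p_gtr = 0.30, meanlog = log(0.03), sdlog = 1.0, cap = 0.5)
  )
}

default_log_hr <- function() {
  c(si = log(2.223), volume = log(1.004), mgmt = log(0.475),
    age = log(1.037), kps = log(0.934), eor = log(0.142))
}

# fixed centring constants for the linear predictor (approximate
# distribution means under the default covariate parameters)
default_centers <- function() {
  c(si = 1.37, csa = 75, volume = 69, age = 65, mgmt = 0.46,
    kps = 78, eor = 0.93)
}

#' Specify a synthetic cohort
#'
#' @param n number of patients (>= 2)
#' @param log_hr named numeric vector of per-unit log hazard ratios; names
#'   among `si`, `csa`, `volume`, `age`, `mgmt`, `kps`, `eor` (`eor` is the
#'   0-1 resection fraction, `mgmt` the methylated indicator)
#' @param baseline_shape,baseline_scale_days Weibull baseline hazard
#'   parameters (shape 1.2 allows a rising hazard while keeping
#'   inverse-transform sampling closed-form; scale 579 days puts the
#'   null-covariate median at ~14 months)
#' @param accrual_window_days uniform accrual span before the single
#'   administrative end of follow-up (censoring time ~ U(0, window))
#' @param covariate_params distribution parameters, see
#'   `gliomorph:::default_covariate_params()` for the structure
#' @param centers named centring constants for the linear predictor
#' @param kps_decay_day if non-NULL, the KPS log hazard drops to 0 after
#'   this day (simulates the loss of prognostic value of a one-off
#'   postoperative performance score, i.e. a proportionality violation)
#' @param seed integer master seed
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n, log_hr = default_log_hr(),
                        baseline_shape = 1.2, baseline_scale_days = 579,
                        accrual_window_days = 3652,
                        covariate_params = list(),
                        centers = default_centers(),
                        kps_decay_day = NULL, seed = 1L) {
  if (n < 2) stop("cohort_spec: n must be >= 2")
  if (baseline_scale_days <= 0) stop("cohort_spec: baseline scale must be > 0")
  cp <- modifyList(default_covariate_params(), covariate_params)
  bad <- vapply(cp, function(p) any(!vapply(p, is.numeric, TRUE)), TRUE)
  if (any(bad)) stop("cohort_spec: non-numeric covariate parameters for ",
                     paste(names(cp)[bad], collapse = ", "))
  structure(list(n = as.integer(n), log_hr = log_hr,
                 baseline_shape = baseline_shape,
                 baseline_scale_days = baseline_scale_days,
                 accrual_window_days = accrual_window_days,
                 covariate_params = cp, centers = centers,
                 kps_decay_day = kps_decay_day, seed = as.integer(seed)),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Sample cohort covariates
#'
#' Draws all covariates independently except CSA, which is derived from
#' volume, SI and the dural fraction via the geometric identity
#' `CSA = (1 - d) * SI * A_sphere(V)`. Deterministic given the spec.
#'
#' @param spec a [cohort_spec()]
#' @return a data frame, one row per patient
#' @export
sample_covariates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cp <- spec$covariate_params
  n <- spec$n
  with_seed(derive_seed(spec$seed, "covariates"), {
    volume <- rlnorm(n, cp$volume$meanlog, cp$volume$sdlog)
    si <- 1 + rlnorm(n, cp$si$meanlog, cp$si$sdlog)
    contact <- rbinom(n, 1, cp$dural$p_contact) == 1
    dural <- ifelse(contact,
                    pmin(rlnorm(n, cp$dural$meanlog, cp$dural$sdlog),
                         cp$dural$cap), 0)
    age <- rtrunc_norm(n, cp$age$mean, cp$age$sd, cp$age$min, cp$age$max)
    sex <- ifelse(rbinom(n, 1, cp$sex$p_male) == 1, "male", "female")
    mgmt <- ifelse(rbinom(n, 1, cp$mgmt$p_methylated) == 1,
                   "methylated", "unmethylated")
    kps <- sample(cp$kps$values, n, replace = TRUE, prob = cp$kps$probs)
    gtr <- rbinom(n, 1, cp$eor$p_gtr) == 1
    resid <- ifelse(gtr, 0,
                    pmin(rlnorm(n, cp$eor$meanlog, cp$eor$sdlog), cp$eor$cap))
    eor <- 100 * (1 - resid)
    tsa <- si * sphere_area(volume)
    data.frame(
      case_id = sprintf("case_%05d", seq_len(n)),
      age = age, sex = sex, mgmt = mgmt, kps_post = kps,
      volume_ml = volume, si = si, dural_fraction = dural,
      tsa_cm2 = tsa, csa_cm2 = (1 - dural) * tsa,
      av_per_cm = tsa / volume, eor_percent = eor,
      stringsAsFactors = FALSE)
  })
}

# linear-predictor design columns for the named log-HR entries
cohort_design <- function(cohort, log_hr, centers) {
  cols <- list(
    si = function(d) d$si,
    csa = function(d) d$csa_cm2,
    volume = function(d) d$volume_ml,
    age = function(d) d$age,
    mgmt = function(d) as.numeric(d$mgmt == "methylated"),
    kps = function(d) d$kps_post,
    eor = function(d) d$eor_percent / 100)
  unknown <- setdiff(names(log_hr), names(cols))
  if (length(unknown) > 0) {
    stop("unknown predictor in log_hr: ", paste(unknown, collapse = ", "))
  }
  x <- vapply(names(log_hr), function(nm) cols[[nm]](cohort) - centers[[nm]],
              numeric(nrow(cohort)))
  matrix(x, nrow = nrow(cohort),
         dimnames = list(NULL, names(log_hr)))
}

#' Generate survival outcomes for a cohort
#'
#' Event times follow a Weibull proportional hazards model:
#' `S(t | x) = exp(-(t / scale)^shape * exp(eta))` with
#' `eta = sum_j beta_j (x_j - center_j)`, sampled by inverse transform.
#' With `kps_decay_day` set in the spec, the KPS contribution to `eta`
#' applies only before that day (piecewise inversion), so the generated
#' data violate proportional hazards for KPS exactly the way a one-off
#' postoperative score does. Administrative censoring: each patient's
#' follow-up is `U(0, accrual_window_days)` (uniform accrual, single fixed
#' end of study).
#'
#' @param cohort data frame from [sample_covariates()]
#' @param spec the same [cohort_spec()]
#' @return the cohort with `survival_days` (integer >= 1) and `event`
#'   (TRUE = death observed) appended
#' @export
sample_survival <- function(cohort, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- cohort_design(cohort, spec$log_hr, spec$centers)
  eta_full <- drop(x %*% spec$log_hr)
  k <- spec$baseline_shape
  lam <- spec$baseline_scale_days
  with_seed(derive_seed(spec$seed, "survival"), {
    e <- -log(runif(nrow(cohort)))
    if (is.null(spec$kps_decay_day) || !("kps" %in% colnames(x))) {
      t_event <- lam * (e * exp(-eta_full))^(1 / k)
    } else {
      t0 <- spec$kps_decay_day
      eta_late <- eta_full - x[, "kps"] * spec$log_hr[["kps"]]
      h0 <- (t0 / lam)^k
      cut <- h0 * exp(eta_full)   # cumulative hazard at the split
      t_event <- ifelse(
        e <= cut,
        lam * (e * exp(-eta_full))^(1 / k),
        lam * ((e - cut) * exp(-eta_late) + h0)^(1 / k))
    }
    cens <- runif(nrow(cohort), 0, spec$accrual_window_days)
    cohort$event <- t_event <= cens
    cohort$survival_days <- pmax(1L, as.integer(round(pmin(t_event, cens))))
  })
  cohort
}

#' Generate a full synthetic cohort
#'
#' [sample_covariates()] followed by [sample_survival()].
#'
#' @param spec a [cohort_spec()]
#' @return data frame with covariates and survival outcome
#' @export
simulate_cohort <- function(spec) {
  sample_survival(sample_covariates(spec), spec)
}
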