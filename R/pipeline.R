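# End-to-end orchestration: measure each case's masks, log exclusions the
# way an inclusion flowchart would, merge with clinical covariates, run the
# analysis, and write everything (plus the fully resolved config) beside
# the outputs so a run is reproducible from its own directory.

#' Build a pipeline configuration
#'
#' @param cases data frame with columns `case_id`, `pre` (path) and
#'   optionally `post`, `brain`; alternatively NULL with `mask_dir` set,
#'   in which case `<stem>_pre.nii[.gz]` files are discovered and matching
#'   `<stem>_post` / `<stem>_brain` volumes attached (case ids are the
#'   file stems; duplicate stems are an error)
#' @param mask_dir directory to scan when `cases` is NULL
#' @param covariates_csv optional CSV with `case_id` plus clinical columns
#'   (`age`, `sex`, `mgmt`, `kps_post`, `survival_days`, `event`)
#' @param out_dir output directory (created)
#' @param contact_tolerance_mm dural-contact distance threshold (1.0)
#' @param connectivity multifocality adjacency ("face-edge-vertex"/"face")
#' @param smooth_iters mesh relaxation iterations (100)
#' @param split_day KPS step-function landmark (300)
#' @param ties Cox tie handling ("efron")
#' @param seed master seed (stages derive their own sub-seeds)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(cases = NULL, mask_dir = NULL,
                            covariates_csv = NULL, out_dir = "gliomorph_out",
                            contact_tolerance_mm = 1.0,
                            connectivity = "face-edge-vertex",
                            smooth_iters = 100, split_day = 300,
                            ties = "efron", seed = 1L) {
  structure(list(cases = cases, mask_dir = mask_dir,
                 covariates_csv = covariates_csv, out_dir = out_dir,
                 contact_tolerance_mm = contact_tolerance_mm,
                 connectivity = connectivity, smooth_iters = smooth_iters,
                 split_day = split_day, ties = ties, seed = as.integer(seed),
                 version = as.character(utils::packageVersion("gliomorph"))),
            class = "pipeline_config")
}

discover_cases <- function(mask_dir) {
  pre <- list.files(mask_dir, pattern = "_pre\\.nii(\\.gz)?$",
                    full.names = TRUE)
  if (length(pre) == 0) stop("run_pipeline: no *_pre.nii[.gz] in ", mask_dir)
  stem <- sub("_pre\\.nii(\\.gz)?$", "", basename(pre))
  if (anyDuplicated(stem)) {
    stop("run_pipeline: duplicate case ids: ",
         paste(unique(stem[duplicated(stem)]), collapse = ", "))
  }
  find_side <- function(stems, suffix) {
    vapply(stems, function(s) {
      for (ext in c(".nii.gz", ".nii")) {
        p <- file.path(mask_dir, paste0(s, suffix, ext))
        if (file.exists(p)) return(p)
      }
      NA_character_
    }, character(1))
  }
  data.frame(case_id = stem, pre = pre,
             post = find_side(stem, "_post"),
             brain = find_side(stem, "_brain"),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Per case: read masks, apply the unifocality inclusion rule (multifocal
#' or empty masks are logged and skipped, not fatal), compute morphometry
#' and, when a postoperative mask is present, extent of resection. Then
#' merge with covariates and, when survival columns are available, run
#' [analysis_report()]. Writes `morphometry.csv`, `exclusions.csv`,
#' `resolved_config.json` and (when analysed) `cohort.csv` plus report
#' tables under `out_dir`. Reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()]
#' @return list: `morphometry` (data frame), `exclusions` (data frame),
#'   `cohort` (merged, or NULL), `report` (an `analysis_report`, or NULL),
#'   `counts` (entered / excluded / analyzed)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cases <- config$cases %||% discover_cases(config$mask_dir)
  if (anyDuplicated(cases$case_id)) {
    stop("run_pipeline: duplicate case ids in config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mcfg <- list(contact_tolerance_mm = config$contact_tolerance_mm,
               connectivity = config$connectivity,
               smooth_iters = config$smooth_iters)
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(cases))) {
    id <- cases$case_id[i]
    res <- tryCatch({
      pre <- if (inherits(cases$pre[[i]], "segmentation_mask")) {
        cases$pre[[i]]
      } else {
        read_mask(cases$pre[[i]], "tumor_pre")
      }
      post <- NULL
      if (!is.null(cases$post) && !is.na(cases$post[[i]][1])) {
        post <- if (inherits(cases$post[[i]], "segmentation_mask")) {
          cases$post[[i]]
        } else {
          read_mask(cases$post[[i]], "tumor_post")
        }
      }
      brain <- NULL
      if (!is.null(cases$brain) && !is.na(cases$brain[[i]][1])) {
        brain <- if (inherits(cases$brain[[i]], "segmentation_mask")) {
          cases$brain[[i]]
        } else {
          read_mask(cases$brain[[i]], "brain")
        }
      }
      morphometry_pipeline(pre, post = post, brain = brain, config = mcfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[id]] <- data.frame(case_id = id,
                               reason = conditionMessage(res),
                               n_components = NA_integer_)
    } else if (res$excluded) {
      excl[[id]] <- data.frame(case_id = id, reason = res$reason,
                               n_components = res$components$n_components)
    } else {
      m <- res$morphometry
      rows[[id]] <- data.frame(
        case_id = id, volume_ml = m$volume_ml, tsa_cm2 = m$tsa_cm2,
        csa_cm2 = m$csa_cm2, si = m$si, av_per_cm = m$av_per_cm,
        dural_fraction = m$dural_fraction,
        eor_percent = if (is.null(res$resection)) NA_real_
                      else res$resection$eor_percent,
        eor_category = if (is.null(res$resection)) NA_character_
                       else res$resection$category,
        stringsAsFactors = FALSE)
    }
  }
  morph <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0))
  rownames(morph) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(case_id = character(0), reason = character(0),
               n_components = integer(0))
  rownames(exclusions) <- NULL
  write.csv(morph, file.path(config$out_dir, "morphometry.csv"),
            row.names = FALSE)
  write.csv(exclusions, file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE)

  cohort <- NULL
  report <- NULL
  if (!is.null(config$covariates_csv)) {
    cov <- read.csv(config$covariates_csv, stringsAsFactors = FALSE)
    cohort <- merge(morph, cov, by = "case_id", sort = TRUE)
    if ("event" %in% names(cohort)) {
      cohort$event <- if (is.character(cohort$event)) {
        cohort$event %in% c("TRUE", "true", "1", "yes")
      } else {
        cohort$event != 0
      }
    }
    write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
              row.names = FALSE)
    if (all(c("survival_days", "event") %in% names(cohort)) &&
        nrow(cohort) > 0) {
      report <- analysis_report(cohort,
                                config = list(split_day = config$split_day,
                                              ties = config$ties))
      write_report_tables(report, config$out_dir)
    }
  }
  counts <- c(entered = nrow(cases), excluded = nrow(exclusions),
              analyzed = nrow(morph))
  resolved <- unclass(config)
  resolved$cases <- if (is.data.frame(cases) && is.character(cases$pre)) {
    cases
  } else {
    data.frame(case_id = cases$case_id)
  }
  resolved$counts <- as.list(counts)
  jsonlite::write_json(resolved,
                       file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  message(sprintf("run_pipeline: %d entered, %d excluded, %d analyzed",
                  counts["entered"], counts["excluded"], counts["analyzed"]))
  list(morphometry = morph, exclusions = exclusions, cohort = cohort,
       report = report, counts = counts)
}

write_report_tables <- function(report, out_dir) {
  write.csv(report$descriptive, file.path(out_dir, "table1_descriptive.csv"),
            row.names = FALSE)
  write.csv(report$spearman, file.path(out_dir, "table2_spearman.csv"),
            row.names = FALSE)
  write.csv(report$group_tests, file.path(out_dir, "table2_group_tests.csv"),
            row.names = FALSE)
  write.csv(report$cox_univariable,
            file.path(out_dir, "table2_cox_univariable.csv"),
            row.names = FALSE)
  mv <- rbind(cbind(model = "csa", report$cox_csa_model$table),
              cbind(model = "si", report$cox_si_model$table))
  write.csv(mv, file.path(out_dir, "table3_cox_multivariable.csv"),
            row.names = FALSE)
  summ <- list(
    n = report$n,
    csa_model = list(c_index = report$cox_csa_model$c_index,
                     aic = report$cox_csa_model$aic,
                     n_used = report$cox_csa_model$n_used),
    si_model = list(c_index = report$cox_si_model$c_index,
                    aic = report$cox_si_model$aic,
                    n_used = report$cox_si_model$n_used),
    logrank = list(csa_median = report$km$csa_median$logrank_p,
                   si_median = report$km$si_median$logrank_p))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
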