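# Size/shape measures: volume, TSA, CSA, SI, A/V, dural fraction, EOR.
# Units are mm internally and cm^2 / mL / cm^-1 at the record boundary
# (1 mL = 1000 mm^3 = 1 cm^3, 1 cm^2 = 100 mm^2).

#' Tumor volume from a mask
#'
#' Foreground voxel count times voxel volume -- exact for the digitized
#' object, matching label-map statistics conventions (the mesh is never
#' used for volume).
#'
#' @param mask a non-empty [segmentation_mask()]
#' @return volume in mL
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  n <- n_foreground(mask)
  if (n == 0L) stop("compute_volume: empty mask")
  n * prod(mask$spacing) / 1000
}

#' Sphericity index
#'
#' The quotient of the total surface area and the surface area of a sphere
#' of equal volume: \eqn{SI = TSA / (\pi^{1/3} (6V)^{2/3})}. 1 for a
#' perfect sphere, larger for irregular shapes (isoperimetric inequality).
#'
#' @param tsa_cm2 total surface area, cm^2 (> 0)
#' @param volume_ml tumor volume, mL (> 0)
#' @return dimensionless SI
#' @export
#' @examples
#' sphericity_index(24, 8) # 2 cm cube: (6/pi)^(1/3) ~ 1.2407
sphericity_index <- function(tsa_cm2, volume_ml) {
  if (any(!is.finite(tsa_cm2)) || any(tsa_cm2 <= 0)) {
    stop("sphericity_index: tsa_cm2 must be positive")
  }
  tsa_cm2 / sphere_area(volume_ml)
}

#' Area-to-volume ratio
#'
#' @inheritParams sphericity_index
#' @return A/V in cm^-1 (1 mL = 1 cm^3)
#' @export
area_volume_ratio <- function(tsa_cm2, volume_ml) {
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0)) {
    stop("area_volume_ratio: volume_ml must be positive")
  }
  tsa_cm2 / volume_ml
}

#' Extent of resection
#'
#' `EOR = 100 * (pre - post) / pre`. Gross total resection (GTR) is an EOR
#' of 100%; anything less is subtotal (STR). A postoperative volume below
#' one voxel (`gtr_tolerance_ml`) counts as zero, reflecting segmentation
#' granularity.
#'
#' @param pre_ml preoperative volume, mL (> 0)
#' @param post_ml postoperative (residual) volume, mL, in `[0, pre_ml]`
#' @param gtr_tolerance_ml residual volumes at or below this count as 0
#' @return a `resection_result`: `eor_percent` and `category` ("GTR"/"STR")
#' @export
extent_of_resection <- function(pre_ml, post_ml, gtr_tolerance_ml = 0) {
  if (!is.finite(pre_ml) || pre_ml <= 0) {
    stop("extent_of_resection: pre_ml must be positive")
  }
  if (!is.finite(post_ml) || post_ml < 0) {
    stop("extent_of_resection: post_ml must be >= 0")
  }
  if (post_ml > pre_ml) {
    stop("extent_of_resection: post > pre (growth or registration mismatch)")
  }
  if (post_ml <= gtr_tolerance_ml) post_ml <- 0
  eor <- 100 * (pre_ml - post_ml) / pre_ml
  structure(list(eor_percent = eor,
                 category = if (post_ml == 0) "GTR" else "STR"),
            class = "resection_result")
}

#' @export
print.resection_result <- function(x, ...) {
  cat(sprintf("<resection eor=%.1f%% category=%s>\n", x$eor_percent, x$category))
  invisible(x)
}

new_tumor_morphometry <- function(volume_ml, tsa_cm2, csa_cm2, si, av_per_cm,
                                  dural_fraction) {
  structure(list(volume_ml = volume_ml, tsa_cm2 = tsa_cm2, csa_cm2 = csa_cm2,
                 si = si, av_per_cm = av_per_cm,
                 dural_fraction = dural_fraction),
            class = "tumor_morphometry")
}

#' @export
print.tumor_morphometry <- function(x, ...) {
  cat(sprintf(
    "<tumor_morphometry V=%.2f mL TSA=%.2f cm2 CSA=%.2f cm2 SI=%.3f A/V=%.2f /cm dural=%.3f>\n",
    x$volume_ml, x$tsa_cm2, x$csa_cm2, x$si, x$av_per_cm, x$dural_fraction))
  invisible(x)
}

#' Morphometry of one case
#'
#' Composes the stages: unifocality check, isosurface extraction, TSA,
#' contact labelling against an optional brain mask, CSA, volume, SI, A/V
#' and (with a postoperative mask) extent of resection. Deterministic given
#' inputs and config. Errors from a stage are re-raised with the stage name.
#'
#' @param pre preoperative tumor [segmentation_mask()]
#' @param post optional postoperative mask (empty mask allowed: GTR)
#' @param brain optional brain mask for contact labelling
#' @param config list of options: `contact_tolerance_mm` (1.0),
#'   `connectivity` ("face-edge-vertex"), `smooth_iters` (100),
#'   `band` (0.3), `gaussian_sigma_vox` (0)
#' @return a list: `morphometry` (a `tumor_morphometry`), `resection`
#'   (a `resection_result` or NULL), `excluded` (logical) and `reason`;
#'   for an excluded case only `excluded`/`reason` are meaningful
#' @export
morphometry_pipeline <- function(pre, post = NULL, brain = NULL,
                                 config = list()) {
  cfg <- modifyList(list(contact_tolerance_mm = 1.0,
                         connectivity = "face-edge-vertex",
                         smooth_iters = 100, band = 0.3,
                         gaussian_sigma_vox = 0), config)
  rep <- tryCatch(validate_unifocal(pre, cfg$connectivity),
                  error = function(e) stage_error("validate_unifocal", e))
  if (rep$exclude) {
    return(list(morphometry = NULL, resection = NULL, excluded = TRUE,
                reason = rep$reason, components = rep))
  }
  mesh <- tryCatch(
    extract_mesh(pre, smooth_iters = cfg$smooth_iters, band = cfg$band,
                 gaussian_sigma_vox = cfg$gaussian_sigma_vox),
    error = function(e) stage_error("extract_mesh", e))
  tsa <- tryCatch(compute_tsa(mesh),
                  error = function(e) stage_error("compute_tsa", e))
  if (!is.null(brain)) {
    mesh <- tryCatch(
      label_contact(mesh, pre, brain, cfg$contact_tolerance_mm),
      error = function(e) stage_error("label_contact", e))
  }
  csa <- tryCatch(compute_csa(mesh),
                  error = function(e) stage_error("compute_csa", e))
  vol <- tryCatch(compute_volume(pre),
                  error = function(e) stage_error("compute_volume", e))
  si <- sphericity_index(tsa, vol)
  av <- area_volume_ratio(tsa, vol)
  res <- NULL
  if (!is.null(post)) {
    post_ml <- if (n_foreground(post) == 0L) 0 else compute_volume(post)
    res <- tryCatch(
      extent_of_resection(vol, post_ml,
                          gtr_tolerance_ml = prod(post$spacing) / 1000),
      error = function(e) stage_error("extent_of_resection", e))
  }
  list(morphometry = new_tumor_morphometry(vol, tsa, csa$csa_cm2, si, av,
                                           csa$dural_fraction),
       resection = res, excluded = FALSE, reason = NA_character_,
       mesh = mesh)
}
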