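#' Segmentation mask
#'
#' A 3D binary voxel grid with physical spacing. The container behind all
#' morphometry: `voxels` is an integer array of 0/1, `spacing` gives mm per
#' voxel along each axis, `origin_offset` places the grid in a common
#' physical frame (the centre of voxel `[i, j, k]`, 1-based, sits at
#' `(c(i, j, k) - 1) * spacing + origin_offset` mm).
#'
#' @param voxels 3D array; any nonzero value is treated as foreground
#' @param spacing numeric length-3, mm per voxel, all > 0
#' @param origin_offset numeric length-3, mm; default c(0, 0, 0)
#' @param role one of "tumor_pre", "tumor_post", "brain"
#' @return an object of class `segmentation_mask`
#' @export
segmentation_mask <- function(voxels, spacing,
                              origin_offset = c(0, 0, 0),
                              role = c("tumor_pre", "tumor_post", "brain")) {
  role <- match.arg(role)
  if (length(dim(voxels)) != 3L) {
    stop("segmentation_mask: voxels must be a 3D array, got ",
         length(dim(voxels)), " dims")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("segmentation_mask: spacing must be 3 positive finite values")
  }
  origin_offset <- as.numeric(origin_offset)
  if (length(origin_offset) != 3L || any(!is.finite(origin_offset))) {
    stop("segmentation_mask: origin_offset must be 3 finite values")
  }
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v, spacing = spacing,
                 origin_offset = origin_offset, role = role),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf(
    "<segmentation_mask role=%s dims=%s spacing=%s mm foreground=%d voxels>\n",
    x$role, paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing, digits = 4), collapse = "x"),
    n_foreground(x)))
  invisible(x)
}

#' @rdname segmentation_mask
#' @param x a `segmentation_mask`
#' @export
n_foreground <- function(x) {
  stopifnot(inherits(x, "segmentation_mask"))
  sum(x$voxels)
}

#' Connected components of a mask
#'
#' Labels maximal sets of foreground voxels mutually reachable under the
#' chosen adjacency. The default 26-neighbourhood treats diagonally touching
#' voxels as connected, so only tumor segments separated by a gap of one or
#' more background voxels count as separate foci (the multifocality
#' criterion); face (6) connectivity is stricter and splits corner contact.
#'
#' @param mask a `segmentation_mask`
#' @param connectivity `"face-edge-vertex"` (26, default) or `"face"` (6)
#' @return a `component_report`: `n_components`, `component_sizes`
#'   (voxel counts, descending) and `unifocal` (exactly one component)
#' @export
connected_components <- function(mask,
                                 connectivity = c("face-edge-vertex", "face")) {
  stopifnot(inherits(mask, "segmentation_mask"))
  connectivity <- match.arg(connectivity)
  conn <- if (connectivity == "face") 6L else 26L
  res <- cpp_label_components(as.integer(mask$voxels), dim(mask$voxels), conn)
  sizes <- sort(as.numeric(res$sizes), decreasing = TRUE)
  structure(list(n_components = res$n,
                 component_sizes = sizes,
                 unifocal = res$n == 1L,
                 connectivity = connectivity),
            class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  cat(sprintf("<component_report n=%d unifocal=%s sizes=%s>\n",
              x$n_components, x$unifocal,
              paste(head(x$component_sizes, 5), collapse = ",")))
  invisible(x)
}

#' Check the unifocality inclusion rule
#'
#' Cohort studies of unifocal tumors exclude multifocal cases (tumor
#' segments separated by a gap of one or more voxels). This wraps
#' [connected_components()] and returns an exclusion flag instead of
#' raising, so pipelines can log and drop the case.
#'
#' @inheritParams connected_components
#' @return the `component_report` with two extra fields: `exclude`
#'   (TRUE when the mask should be dropped) and `reason`
#'   (`"multifocal"`, `"empty"`, or `NA` when kept)
#' @export
validate_unifocal <- function(mask,
                              connectivity = c("face-edge-vertex", "face")) {
  rep <- connected_components(mask, connectivity)
  if (rep$n_components == 0L) {
    rep$exclude <- TRUE
    rep$reason <- "empty"
  } else if (!rep$unifocal) {
    rep$exclude <- TRUE
    rep$reason <- "multifocal"
  } else {
    rep$exclude <- FALSE
    rep$reason <- NA_character_
  }
  rep
}
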