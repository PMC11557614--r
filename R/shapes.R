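# Synthetic digitized solids with analytically known size and shape.
#
# These stand in for patient MRIs: balls, cubes and ellipsoids carry
# closed-form volume and area references; bumpy balls perturb the radius
# with a seeded, degree-limited angular harmonic field (smooth, star-shaped,
# unifocal) to mimic irregular glioblastoma margins; truncated balls model
# a tumor sitting flush against the dura.

#' Specify a synthetic shape
#'
#' @param kind one of "ball", "cube", "ellipsoid", "bumpy_ball",
#'   "truncated_ball"
#' @param radius_mm ball radius (ball, bumpy_ball, truncated_ball)
#' @param side_mm cube side length
#' @param semiaxes_mm length-3 ellipsoid semi-axes
#' @param bump_amplitude radial perturbation amplitude as a fraction of the
#'   radius, in `[0, 1)`; 0 gives an exact ball
#' @param bump_degree maximum angular degree of the perturbation (integer)
#' @param truncation_offset_mm signed distance of the cutting plane from
#'   the ball centre (the solid keeps `z <= offset`)
#' @param spacing voxel spacing, mm (scalar or length 3)
#' @param seed integer seed for the bump coefficients
#' @param margin_vox background margin around the solid (>= 3 keeps meshes
#'   closed and components well separated from the border)
#' @return a `shape_spec` list
#' @export
shape_spec <- function(kind = c("ball", "cube", "ellipsoid", "bumpy_ball",
                                "truncated_ball"),
                       radius_mm = 20, side_mm = 20,
                       semiaxes_mm = c(25, 20, 15),
                       bump_amplitude = 0, bump_degree = 0,
                       truncation_offset_mm = 0,
                       spacing = 1, seed = 1L, margin_vox = 3L) {
  kind <- match.arg(kind)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (bump_amplitude < 0 || bump_amplitude >= 1) {
    stop("shape_spec: bump_amplitude must be in [0, 1)")
  }
  if (kind == "truncated_ball" &&
      abs(truncation_offset_mm) >= radius_mm) {
    stop("shape_spec: |truncation_offset_mm| must be < radius_mm")
  }
  structure(list(kind = kind, radius_mm = radius_mm, side_mm = side_mm,
                 semiaxes_mm = semiaxes_mm, bump_amplitude = bump_amplitude,
                 bump_degree = as.integer(bump_degree),
                 truncation_offset_mm = truncation_offset_mm,
                 spacing = spacing, seed = as.integer(seed),
                 margin_vox = as.integer(margin_vox)),
            class = "shape_spec")
}

# Legendre polynomial P_l(x) by the three-term recurrence
legendre_p <- function(l, x) {
  if (l == 0L) return(rep(1, length(x)))
  if (l == 1L) return(x)
  pm2 <- rep(1, length(x))
  pm1 <- x
  for (n in 2:l) {
    p <- ((2 * n - 1) * x * pm1 - (n - 1) * pm2) / n
    pm2 <- pm1
    pm1 <- p
  }
  pm1
}

# roughly uniform unit directions (spherical Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# seeded degree-limited angular perturbation: a sum of rotated zonal
# harmonics sum_j c_j P_{l_j}(u_j . xhat), normalized to sup |f| = 1
make_bump_field <- function(degree, seed) {
  if (degree < 1L) return(function(xhat) rep(0, nrow(xhat)))
  with_seed(seed, {
    k <- max(4L, degree)
    ls <- sample(seq_len(degree), k, replace = TRUE)
    cs <- rnorm(k)
    us <- matrix(rnorm(3 * k), ncol = 3)
    us <- us / sqrt(rowSums(us^2))
    f0 <- function(xhat) {
      acc <- rep(0, nrow(xhat))
      for (j in seq_len(k)) {
        acc <- acc + cs[j] * legendre_p(ls[j], drop(xhat %*% us[j, ]))
      }
      acc
    }
    supv <- max(abs(f0(fibonacci_sphere(2000L))))
    function(xhat) f0(xhat) / supv
  })
}

#' Generate a digitized synthetic shape
#'
#' Rasterizes the analytic solid onto a voxel grid: a voxel is foreground
#' iff its centre lies inside the solid. The grid is sized automatically
#' (even counts per axis, half-integer centre) so the solid never clips and
#' always has a background margin. Deterministic given the spec (incl.
#' seed). Where closed forms exist, the analytic volume (mL) and area
#' (cm^2) are attached as `attr(mask, "reference")` (Knud Thomsen
#' approximation for the ellipsoid area).
#'
#' @param spec a [shape_spec()]
#' @return a `tumor_pre` [segmentation_mask()] with attributes
#'   `reference` (list or NULL), `center_mm` (shape centre in the grid's
#'   physical frame) and `spec`
#' @export
generate_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  sp <- spec$spacing
  half <- switch(spec$kind,
    ball = rep(spec$radius_mm, 3),
    cube = rep(spec$side_mm / 2, 3),
    ellipsoid = spec$semiaxes_mm,
    bumpy_ball = rep(spec$radius_mm * (1 + spec$bump_amplitude), 3),
    truncated_ball = rep(spec$radius_mm, 3))
  n <- 2L * (as.integer(ceiling(half / sp)) + spec$margin_vox)
  ctr <- (n - 1) / 2  # half-integer for even n
  ax <- lapply(1:3, function(a) (seq_len(n[a]) - 1 - ctr[a]) * sp[a])
  inside <- switch(spec$kind,
    ball = {
      d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
      d2 <= spec$radius_mm^2
    },
    cube = {
      h <- spec$side_mm / 2
      outer(outer(abs(ax[[1]]) < h, abs(ax[[2]]) < h, `&`),
            abs(ax[[3]]) < h, `&`)
    },
    ellipsoid = {
      s <- spec$semiaxes_mm
      d2 <- outer(outer((ax[[1]] / s[1])^2, (ax[[2]] / s[2])^2, `+`),
                  (ax[[3]] / s[3])^2, `+`)
      d2 <= 1
    },
    truncated_ball = {
      d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
      zok <- array(rep(ax[[3]] <= spec$truncation_offset_mm,
                       each = n[1] * n[2]), dim = n)
      d2 <= spec$radius_mm^2 & zok
    },
    bumpy_ball = {
      f <- make_bump_field(spec$bump_degree, spec$seed)
      g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
      r <- sqrt(rowSums(g^2))
      xhat <- g / ifelse(r > 0, r, 1)
      rad <- spec$radius_mm *
        (1 + spec$bump_amplitude * f(xhat))
      array(r <= rad, dim = n)
    })
  vox <- array(as.integer(inside), dim = n)
  if (sum(vox) == 0L) stop("generate_shape: spec produced an empty mask")
  shell <- sum(vox[c(1, n[1]), , ]) + sum(vox[, c(1, n[2]), ]) +
    sum(vox[, , c(1, n[3])])
  if (shell > 0) stop("generate_shape: solid clipped by the grid")
  ref <- switch(spec$kind,
    ball = list(volume_ml = 4 / 3 * pi * spec$radius_mm^3 / 1000,
                tsa_cm2 = 4 * pi * spec$radius_mm^2 / 100),
    cube = list(volume_ml = spec$side_mm^3 / 1000,
                tsa_cm2 = 6 * spec$side_mm^2 / 100),
    ellipsoid = {
      s <- spec$semiaxes_mm
      p <- 1.6075  # Knud Thomsen approximation
      a_mm2 <- 4 * pi * (((s[1] * s[2])^p + (s[1] * s[3])^p +
                            (s[2] * s[3])^p) / 3)^(1 / p)
      list(volume_ml = 4 / 3 * pi * prod(s) / 1000, tsa_cm2 = a_mm2 / 100)
    },
    truncated_ball = {
      R <- spec$radius_mm
      h <- R - spec$truncation_offset_mm    # height of the removed cap
      vol_mm3 <- 4 / 3 * pi * R^3 - pi * h^2 * (3 * R - h) / 3
      area_mm2 <- (4 * pi * R^2 - 2 * pi * R * h) +
        pi * (R^2 - spec$truncation_offset_mm^2)
      list(volume_ml = vol_mm3 / 1000, tsa_cm2 = area_mm2 / 100)
    },
    bumpy_ball = NULL)
  m <- segmentation_mask(vox, sp, role = "tumor_pre")
  attr(m, "reference") <- ref
  attr(m, "center_mm") <- ctr * sp
  attr(m, "spec") <- spec
  m
}

#' Generate a brain mask around a synthetic tumor
#'
#' Builds a brain mask in the tumor's physical frame: a large box fully
#' containing the tumor. With `contact = "none"` the brain boundary stays
#' at least `clearance_mm` from every tumor voxel, so no face is
#' contact-labelled. With `contact = "planar"` the brain occupies
#' `z <= z_c + offset_mm` (z_c = the shape centre), so a tumor truncated at
#' the same plane sits flush against the boundary -- a known spherical cap
#' abuts the dura surrogate.
#'
#' @param tumor a tumor [segmentation_mask()] (ideally from
#'   [generate_shape()], which records its centre)
#' @param contact "none" or "planar"
#' @param offset_mm signed plane offset from the shape centre (planar only)
#' @param clearance_mm minimum boundary clearance for "none" (default 10)
#' @return a brain-role [segmentation_mask()] on an expanded grid
#' @export
generate_brain_context <- function(tumor, contact = c("none", "planar"),
                                   offset_mm = 0, clearance_mm = 10) {
  stopifnot(inherits(tumor, "segmentation_mask"))
  contact <- match.arg(contact)
  sp <- tumor$spacing
  pad <- as.integer(ceiling((clearance_mm + 2) / min(sp)))
  nd <- dim(tumor$voxels) + 2L * pad
  origin <- tumor$origin_offset - pad * sp
  if (contact == "none") {
    vox <- array(1L, dim = nd)
  } else {
    ctr <- attr(tumor, "center_mm")
    if (is.null(ctr)) {
      idx <- which(tumor$voxels != 0, arr.ind = TRUE)
      ctr <- colMeans(sweep(idx - 1, 2, sp, `*`))
    }
    z_plane <- ctr[3] + tumor$origin_offset[3] + offset_mm
    z_brain <- (seq_len(nd[3]) - 1) * sp[3] + origin[3]
    vox <- array(rep(as.integer(z_brain <= z_plane + 1e-9),
                     each = nd[1] * nd[2]), dim = nd)
    # tumor voxels inside the brain?
    idx <- which(tumor$voxels != 0, arr.ind = TRUE)
    z_tum <- (idx[, 3] - 1) * sp[3] + tumor$origin_offset[3]
    if (!any(z_tum <= z_plane + 1e-9)) {
      stop("generate_brain_context: plane places the whole tumor outside the brain")
    }
  }
  segmentation_mask(vox, sp, origin_offset = origin, role = "brain")
}
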