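test_that("digitized ball matches closed-form volume, area and SI", {
  m <- ball_fixture(20, 1)
  ref <- attr(m, "reference")
  vol <- compute_volume(m)
  expect_lt(abs(vol / ref$volume_ml - 1), 0.02)
  mesh <- extract_mesh(m)
  expect_true(is_closed_mesh(mesh))
  tsa <- compute_tsa(mesh)
  expect_lt(abs(tsa / ref$tsa_cm2 - 1), 0.03)
  expect_lt(abs(sphericity_index(tsa, vol) - 1), 0.03)
})

test_that("single voxel yields a closed mesh and exact unit volume", {
  vox <- array(0L, c(5, 5, 5)); vox[3, 3, 3] <- 1L
  m <- segmentation_mask(vox, c(1, 1, 1))
  expect_equal(compute_volume(m), 0.001)
  mesh <- extract_mesh(m)
  expect_true(is_closed_mesh(mesh))
  expect_gt(compute_tsa(mesh), 0)
})

test_that("digitized cube: exact volume, area and SI near closed form", {
  m <- generate_shape(shape_spec("cube", side_mm = 20, spacing = 0.5))
  expect_equal(compute_volume(m), 8, tolerance = 1e-12)
  mesh <- extract_mesh(m)
  expect_true(is_closed_mesh(mesh))
  tsa <- compute_tsa(mesh)
  expect_lt(abs(tsa / 24 - 1), 0.05)   # 2400 mm^2, bevelled edges
  si <- sphericity_index(tsa, 8)
  expect_lt(abs(si / (6 / pi)^(1 / 3) - 1), 0.02)
})

test_that("ellipsoid agrees with Knud Thomsen area and exact volume", {
  m <- generate_shape(shape_spec("ellipsoid", semiaxes_mm = c(24, 16, 12)))
  ref <- attr(m, "reference")
  expect_lt(abs(compute_volume(m) / ref$volume_ml - 1), 0.02)
  expect_lt(abs(compute_tsa(extract_mesh(m)) / ref$tsa_cm2 - 1), 0.05)
})

test_that("compute_tsa sums triangle areas with unit conversion", {
  # 1x1 mm square from two right triangles (open mesh, area check only)
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mesh <- gliomorph:::surface_mesh(v, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(compute_tsa(mesh), 0.01, tolerance = 1e-12)
  # similarity scaling: vertices x2 -> area x4 exactly
  mesh2 <- mesh; mesh2$vertices <- 2 * mesh$vertices
  expect_equal(compute_tsa(mesh2), 4 * compute_tsa(mesh), tolerance = 1e-12)
  # degenerate face warns and contributes zero
  meshd <- gliomorph:::surface_mesh(v, rbind(c(1L, 2L, 3L), c(1L, 1L, 2L)))
  expect_warning(a <- compute_tsa(meshd), "degenerate")
  expect_equal(a, 0.005, tolerance = 1e-12)
})

test_that("sphericity index and A/V closed forms and scaling laws", {
  # sphere: definitionally 1
  R <- 1.7
  expect_equal(sphericity_index(4 * pi * R^2, 4 / 3 * pi * R^3), 1,
               tolerance = 1e-12)
  # cube side 2 cm
  expect_equal(sphericity_index(24, 8), (6 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(area_volume_ratio(24, 8), 3, tolerance = 1e-12)
  expect_equal(area_volume_ratio(4 * pi * R^2, 4 / 3 * pi * R^3), 3 / R,
               tolerance = 1e-12)
  # analytic similarity scaling by k: SI invariant, A/V ~ 1/k
  for (k in c(0.5, 2, 3.7)) {
    expect_lt(abs(sphericity_index(24 * k^2, 8 * k^3) -
                    sphericity_index(24, 8)), 1e-9)
    expect_lt(abs(area_volume_ratio(24 * k^2, 8 * k^3) -
                    area_volume_ratio(24, 8) / k), 1e-9)
  }
  expect_error(sphericity_index(0, 1), "positive")
  expect_error(sphericity_index(1, 0), "positive")
  expect_error(area_volume_ratio(1, 0), "positive")
})

test_that("contact labelling: interior, flush and strict-threshold cases", {
  m <- ball_fixture(8, 1)
  far <- generate_brain_context(m, "none")
  mesh <- label_contact(extract_mesh(m), m, far, 1.0)
  expect_equal(sum(mesh$face_contact), 0)
  cs <- compute_csa(mesh)
  expect_equal(cs$csa_cm2, compute_tsa(mesh), tolerance = 1e-12)
  expect_equal(cs$dural_fraction, 0)

  # tolerance 0 with the tumor one voxel inside the boundary: no contact
  hugging <- generate_brain_context(m, "planar", offset_mm = 9.5)
  mesh0 <- label_contact(extract_mesh(m), m, hugging, 0)
  expect_equal(sum(mesh0$face_contact), 0)

  # no brain mask: all interior with a warning
  expect_warning(mesh_nb <- label_contact(extract_mesh(m), m, NULL, 1.0),
                 "CSA = TSA")
  expect_equal(sum(mesh_nb$face_contact), 0)
})

test_that("hemisphere decomposition: dural fraction and exact CSA split", {
  R <- 20
  h <- generate_shape(shape_spec("truncated_ball", radius_mm = R,
                                 truncation_offset_mm = 0))
  ref <- attr(h, "reference")
  expect_lt(abs(compute_volume(h) / ref$volume_ml - 1), 0.02)
  brain <- generate_brain_context(h, "planar", offset_mm = 0)
  tol <- 1.0
  mesh <- label_contact(extract_mesh(h), h, brain, tol)
  expect_true(is_closed_mesh(mesh))
  tsa <- compute_tsa(mesh)
  expect_lt(abs(tsa / ref$tsa_cm2 - 1), 0.03)
  cs <- compute_csa(mesh)
  # oracle: flat disc pi R^2 plus the spherical zone within `tol` of the
  # plane (zone area 2 pi R tol), over the hemisphere total 3 pi R^2
  frac_oracle <- (pi * R^2 + 2 * pi * R * tol) / (3 * pi * R^2)
  expect_lt(abs(cs$dural_fraction - frac_oracle), 0.03)
  # decomposition is exact by construction: same mesh, same summation
  expect_equal(cs$csa_cm2 + cs$contact_cm2, tsa, tolerance = 1e-12)
})

test_that("per-voxel contact labels reproduce a manual dura workflow", {
  m <- ball_fixture(10, 1)
  lab <- array(0L, dim(m$voxels))
  zc <- attr(m, "center_mm")[3]
  zidx <- (seq_len(dim(lab)[3]) - 1) * m$spacing[3]
  lab[, , zidx < zc] <- 2L       # everything below the equator marked
  mesh <- label_contact_voxels(extract_mesh(m), lab, m)
  frac <- compute_csa(mesh)$dural_fraction
  expect_lt(abs(frac - 0.5), 0.05)
  # round-trip through a multi-label NIfTI
  lm <- m; lm$voxels <- array(1L, dim(lab))
  path <- tempfile(fileext = ".nii")
  write_mask(lm, path)
  r <- readBin(path, "raw", file.size(path))
  r[352 + seq_along(lab)] <- as.raw(lab)
  writeBin(r, path)
  back <- read_mask(path, binarize = FALSE)
  expect_identical(attr(back, "labels"), lab)
  mesh2 <- label_contact_voxels(extract_mesh(m), back, m)
  expect_identical(mesh2$face_contact, mesh$face_contact)
  expect_error(label_contact_voxels(extract_mesh(m), lab[, , 1:3], m),
               "does not match")
})

test_that("fully contact-labelled mesh gives CSA 0 and fraction 1", {
  m <- ball_fixture(6, 1)
  mesh <- extract_mesh(m)
  mesh$face_contact <- rep(TRUE, nrow(mesh$faces))
  cs <- compute_csa(mesh)
  expect_equal(cs$csa_cm2, 0)
  expect_equal(cs$dural_fraction, 1)
})

test_that("extent of resection arithmetic, tolerance and errors", {
  expect_equal(extent_of_resection(30, 0)$eor_percent, 100)
  expect_equal(extent_of_resection(30, 0)$category, "GTR")
  r <- extent_of_resection(30, 3)
  expect_equal(r$eor_percent, 90)
  expect_equal(r$category, "STR")
  r0 <- extent_of_resection(30, 30)
  expect_equal(r0$eor_percent, 0)
  expect_equal(r0$category, "STR")
  # sub-voxel residue counts as GTR
  expect_equal(extent_of_resection(30, 0.0005,
                                   gtr_tolerance_ml = 0.001)$category, "GTR")
  expect_error(extent_of_resection(30, 31), "growth")
  expect_error(extent_of_resection(0, 0), "positive")
})

test_that("EOR is invariant under post-mask relabeling", {
  pre <- ball_fixture(10, 1)
  vox <- array(0L, c(9, 9, 9)); vox[4:6, 4:6, 4:6] <- 1L
  post1 <- segmentation_mask(vox, c(1, 1, 1), role = "tumor_post")
  post2 <- segmentation_mask(vox * 7L, c(1, 1, 1), role = "tumor_post")
  e1 <- extent_of_resection(compute_volume(pre), compute_volume(post1))
  e2 <- extent_of_resection(compute_volume(pre), compute_volume(post2))
  expect_identical(e1, e2)
})

test_that("isoperimetric and resolution properties of the SI estimate", {
  # SI >= 0.97 for every generated shape
  shapes <- list(
    ball_fixture(12, 1),
    generate_shape(shape_spec("ellipsoid", semiaxes_mm = c(18, 12, 9))),
    generate_shape(shape_spec("bumpy_ball", radius_mm = 14,
                              bump_amplitude = 0.2, bump_degree = 4,
                              seed = 3)),
    generate_shape(shape_spec("bumpy_ball", radius_mm = 14,
                              bump_amplitude = 0.35, bump_degree = 6,
                              seed = 9)))
  for (m in shapes) {
    si <- sphericity_index(compute_tsa(extract_mesh(m)), compute_volume(m))
    expect_gte(si, 0.97)
  }
  # ball SI error decreases monotonically with radius (in voxels)
  errs <- vapply(c(5, 10, 20, 40),
                 function(r) abs(measure_ball_si(r, 1) - 1), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("morphometry_pipeline composes stages and excludes correctly", {
  m <- ball_fixture(10, 1)
  brain <- generate_brain_context(m, "none")
  res <- morphometry_pipeline(m, brain = brain)
  expect_false(res$excluded)
  expect_lt(abs(res$morphometry$si - 1), 0.03)
  expect_equal(res$morphometry$dural_fraction, 0)
  expect_equal(res$morphometry$csa_cm2, res$morphometry$tsa_cm2,
               tolerance = 1e-12)
  expect_null(res$resection)

  # with a post mask: empty post is GTR
  post <- segmentation_mask(array(0L, c(5, 5, 5)), c(1, 1, 1),
                            role = "tumor_post")
  res2 <- morphometry_pipeline(m, post = post)
  expect_equal(res2$resection$category, "GTR")

  bf <- morphometry_pipeline(bifocal_fixture())
  expect_true(bf$excluded)
  expect_equal(bf$reason, "multifocal")

  empty <- segmentation_mask(array(0L, c(5, 5, 5)), c(1, 1, 1))
  expect_true(morphometry_pipeline(empty)$excluded)
  expect_error(extract_mesh(empty), "no tumor voxels")
})

test_that("hemisphere pipeline record matches the per-stage values", {
  h <- generate_shape(shape_spec("truncated_ball", radius_mm = 16,
                                 truncation_offset_mm = 0))
  brain <- generate_brain_context(h, "planar", offset_mm = 0)
  res <- morphometry_pipeline(h, brain = brain)
  expect_false(res$excluded)
  mesh <- label_contact(extract_mesh(h), h, brain, 1.0)
  expect_equal(res$morphometry$tsa_cm2, compute_tsa(mesh),
               tolerance = 1e-12)
  expect_equal(res$morphometry$csa_cm2, compute_csa(mesh)$csa_cm2,
               tolerance = 1e-12)
  expect_equal(res$morphometry$volume_ml, compute_volume(h))
})
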