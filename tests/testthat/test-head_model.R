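test_that("layered sphere reproduces analytic shell volumes and layering", {
  h <- build_layered_sphere(50, c(scalp = 6.9, skull = 6.1, csf = 2, gray = 4),
                            voxel_size = 1)
  th <- c(6.9, 6.1, 2, 4)
  expect_equal(sum(th[1:2]), 13)       # overlying scalp+skull thickness
  radii <- c(50, 50 - cumsum(th))      # outer radii of the 5 layers
  expect_equal(radii[5], 31)           # white core radius

  counts <- tabulate(h$labels + 1L, nbins = 6)[2:6]
  vol_sphere <- function(r) 4 / 3 * pi * r^3
  analytic <- vol_sphere(radii[1:5]) - c(vol_sphere(radii[2:5]), 0)
  # discretization bound: one voxel layer over each bounding surface
  bound <- 4 * pi * radii[1:5]^2 + c(4 * pi * radii[2:5]^2, 0)
  expect_true(all(abs(counts - analytic) <= bound))

  ctr <- (dim(h$labels) + 1) %/% 2
  expect_identical(h$labels[ctr[1], ctr[2], ctr[3]], 5L)  # centre is white

  # conservation: per-label counts account for every non-air voxel
  expect_identical(sum(counts), sum(h$labels != 0L))
})

test_that("layered slab stacks tissues by depth and honours zero layers", {
  s <- build_layered_slab(c(100, 100, 60), c(scalp = 7, skull = 6, csf = 2,
                                             gray = 4), voxel_size = 1)
  col <- s$labels[52, 52, ]
  depth <- seq_along(col) - 1.5   # mm depth of each voxel centre
  expect_true(all(col[depth > 0 & depth < 7] == 1))
  expect_true(all(col[depth > 7 & depth < 13] == 2))
  expect_true(all(col[depth > 13 & depth < 15] == 3))
  expect_true(all(col[depth > 15 & depth < 19] == 4))
  expect_true(all(col[depth > 19 & depth < 60] == 5))
  expect_true(all(col[depth < 0 | depth > 60] == 0))

  s4 <- build_layered_slab(c(30, 30, 30), c(scalp = 7, skull = 6, csf = 0,
                                            gray = 4))
  expect_identical(sum(s4$labels == 3L), 0L)
  expect_gt(sum(s4$labels == 4L), 0L)

  expect_error(build_layered_slab(c(30, 30, 10), c(scalp = 7, skull = 6,
                                                   csf = 2, gray = 4)),
               "exceeds")
  expect_error(build_layered_slab(c(30, 30, 30), c(scalp = 0.5, skull = 6,
                                                   csf = 2, gray = 4)),
               "thinner than one voxel")
})

test_that("label volumes round-trip through NIfTI and reject bad input", {
  h <- build_layered_sphere(9, c(scalp = 2, skull = 2, csf = 1, gray = 1))
  path <- tempfile(fileext = ".nii.gz")
  save_label_volume(h, path)
  h2 <- load_label_volume(path)
  expect_identical(h2$labels, h$labels)
  expect_equal(h2$voxel_size, h$voxel_size)

  bad <- h
  bad$labels[2, 2, 2] <- 7L
  p2 <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(bad$labels)
  RNifti::pixdim(img) <- c(1, 1, 1)
  RNifti::writeNifti(img, p2, datatype = "int16")
  expect_error(load_label_volume(p2), "7")

  p3 <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(h$labels)
  RNifti::pixdim(img) <- c(1, 1, 2)
  RNifti::writeNifti(img, p3, datatype = "int16")
  expect_error(load_label_volume(p3), "anisotropic")
})

test_that("surface point placement is near-uniform, surface-bound and deterministic", {
  h <- build_layered_sphere(40, voxel_size = 1)
  pts <- place_surface_points(h, spacing = 5, sphere_radius = 95)
  # a 5 mm lattice on a 95 mm sphere holds about five thousand points
  expect_gt(nrow(pts), 4500)
  expect_lt(nrow(pts), 5600)

  # halving the lattice radius quarters the point count
  pts2 <- place_surface_points(h, spacing = 5, sphere_radius = 47.5)
  expect_equal(nrow(pts) / nrow(pts2), 4, tolerance = 0.05)

  # every point on an air-adjacent tissue voxel, every direction unit norm
  surf <- nindepth:::scalp_surface_mask(h$labels)
  lin <- pts$i + dim(surf)[1] * (pts$j - 1) + prod(dim(surf)[1:2]) * (pts$k - 1)
  expect_true(all(surf[lin]))
  expect_equal(sqrt(pts$dx^2 + pts$dy^2 + pts$dz^2), rep(1, nrow(pts)))

  expect_identical(pts, place_surface_points(h, spacing = 5,
                                             sphere_radius = 95))

  expect_error(place_surface_points(h, spacing = 1000), "fewer than 2")
})

test_that("axis-threshold pruning filters surface points", {
  h <- build_layered_sphere(30, c(scalp = 3, skull = 3, csf = 2, gray = 3))
  all_pts <- place_surface_points(h, spacing = 8)
  pruned <- place_surface_points(h, spacing = 8,
                                 axis_limits = list(z = c(-10, Inf)))
  expect_lt(nrow(pruned), nrow(all_pts))
  expect_true(all(pruned$z >= -10))
})

test_that("planar erosion yields exact 2 mm shells on a 42 mm slab", {
  # laterally unbounded slab: tissue reaches the grid edges, so erosion
  # proceeds only from the inner skull surface downwards
  lab <- array(0L, c(30, 30, 56))
  layer <- function(ks, code) lab[, , ks] <<- code
  layer(2:8, 1L); layer(9:14, 2L); layer(15:16, 3L)
  layer(17:20, 4L); layer(21:56, 5L)
  s <- nindepth:::new_head_volume(lab, 1, rep(-0.5, 3))
  # intracranial depth = 42 mm
  sh <- compute_shells(s, n_shells = 21, step_voxels = 2)
  expect_identical(sh$n_shells, 21L)
  expect_false(sh$exhausted)
  expect_equal(sh$mean_thickness, rep(2, 21), tolerance = 1e-6)

  # shells (plus any residual core) exactly exhaust the intracranial
  # volume, and each voxel belongs to exactly one partition code
  ic <- s$labels >= 3L
  expect_identical(which(sh$partition >= 3L), which(ic))
  expect_true(all(sh$partition[ic] >= 3L))
  expect_identical(sum(tabulate(sh$partition[ic])), sum(ic))
})

test_that("spherical shells erode ~1.4 voxels of depth per erosion step", {
  # 26-connected erosion recedes oblique surfaces faster than axis-aligned
  # ones; on a sphere the mean Euclidean step is ~1.4 x the nominal one
  h <- build_layered_sphere(46, c(scalp = 2, skull = 2, csf = 1, gray = 1))
  sh <- compute_shells(h, n_shells = 10, step_voxels = 2)
  expect_gte(sh$n_shells, 8)
  expect_true(all(sh$mean_thickness[1:5] > 2.4))
  expect_true(all(sh$mean_thickness[1:5] < 3.4))
  # depth strictly increasing with shell index
  expect_true(all(diff(sh$depth_mm) > 0))

  # 6-connected alternative erodes more slowly than its nominal step
  sh6 <- compute_shells(h, n_shells = 10, step_voxels = 2, connectivity = 6)
  expect_lt(mean(sh6$mean_thickness[1:5]), 2)
})

test_that("shell computation flags an exhausted intracranial mask", {
  h <- build_layered_sphere(20, c(scalp = 3, skull = 3, csf = 1, gray = 2))
  expect_warning(sh <- compute_shells(h, n_shells = 21, step_voxels = 2),
                 "exhausted")
  expect_lt(sh$n_shells, 21)
  expect_true(sh$exhausted)
})
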