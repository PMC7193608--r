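# fixtures shared across blocks in this file
pts_interior <- local({
  set.seed(41)
  p <- matrix(rnorm(90), ncol = 3)
  p <- p / sqrt(rowSums(p^2)) * runif(30, 4, 40)
  p
})

test_that("Legendre series matches the homogeneous-sphere closed form", {
  vs <- analytic_shell_potential(44, 0.1, pts_interior,
                                 source_dir = c(0, 0, 1),
                                 sink_dir = c(0, 0, -1),
                                 n_max = 2000, series_tol = 1e-12)
  vc <- homogeneous_sphere_potential(44, 0.1, pts_interior,
                                     c(0, 0, 1), c(0, 0, -1))
  expect_lt(max(abs(vs - vc) / abs(vc)), 1e-6)

  # equal conductivities in all shells degenerate to the homogeneous case
  v4 <- analytic_shell_potential(beagle_radii, rep(0.1, 4), pts_interior,
                                 c(0, 0, 1), c(0, 0, -1),
                                 n_max = 2000, series_tol = 1e-12)
  expect_lt(max(abs(v4 - vc) / abs(vc)), 1e-6)
})

test_that("series evaluation rejects source points and flags truncation", {
  expect_error(analytic_shell_potential(44, 0.1, matrix(c(0, 0, 44), 1),
                                        c(0, 0, 1), c(0, 0, -1)),
               "source point")
  expect_warning(
    v <- analytic_shell_potential(44, 0.1, matrix(c(0, 0, 43), 1),
                                  c(0, 0, 1), c(0, 0, -1), n_max = 12),
    "not converged")
  expect_false(attr(v, "converged"))
})

test_that("slab solution reproduces the series-resistor closed form", {
  sig <- conductivity_set(c(scalp = 0.0004, skull = 0.004, brain = 0.0988,
                            CSF = 2, gray_matter = 0.0988,
                            white_matter = 0.0626))
  m <- build_slab(c(scalp = 2, skull = 2, brain = 40), sig)
  sol <- solve_potential(m, current_density_A_m2 = 1)
  # J / sigma, with 1 V/m == 1 mV/mm
  expect_equal(unname(sol$layer_field_mV_mm["brain"]), 1 / 0.0988,
               tolerance = 1e-12)
  expect_equal(unname(sol$layer_field_mV_mm["scalp"]), 2500)
  # field ratio between layers is the inverse conductivity ratio
  expect_equal(sol$layer_field_mV_mm[["skull"]] /
                 sol$layer_field_mV_mm[["brain"]],
               0.0988 / 0.004, tolerance = 1e-12)
})

test_that("voxel solver matches the homogeneous-sphere closed form away from sources", {
  m <- homogeneous_voxel_sphere(radius_mm = 20, voxel_mm = 1, sigma = 0.1)
  mont <- place_montage(m, list(
    electrode_patch(c(0, 0, 20), 0.1, "scalp-surface", "active", 1),
    electrode_patch(c(0, 0, -20), 0.1, "scalp-surface", "reference", -1)))
  sol <- solve_potential(m, mont)
  th <- seq(0.5, pi - 0.5, length.out = 25)
  pts <- cbind(12 * sin(th), 0, 12 * cos(th))
  vf <- shuntfield:::interp_trilinear(sol, pts)
  vc <- homogeneous_sphere_potential(20, 0.1, pts, c(0, 0, 1), c(0, 0, -1))
  vf <- vf - mean(vf); vc <- vc - mean(vc)
  expect_lt(sqrt(sum((vf - vc)^2) / sum(vc^2)), 0.02)
})

test_that("solutions are exactly linear in the injected current", {
  m <- small_voxel_sphere()
  m1 <- shell_pair_on_voxels(m, "skull-surface", current_mA = 1)
  m2 <- shell_pair_on_voxels(m, "skull-surface", current_mA = 2)
  s1 <- solve_potential(m, m1, tolerance = 1e-10)
  s2 <- solve_potential(m, m2, tolerance = 1e-10)
  v1 <- s1$potential_V[!is.na(s1$potential_V)]
  v2 <- s2$potential_V[!is.na(s2$potential_V)]
  expect_equal(v2, 2 * v1, tolerance = 1e-6)

  # analytic path: exact linearity
  sm <- beagle_shells()
  strip <- strip_on_inner_surface(sm, 8)
  p1 <- field_along_strip(solve_potential(sm, shell_pair(sm, "skull-surface",
                                                         current_mA = 1)),
                          strip)
  p2 <- field_along_strip(solve_potential(sm, shell_pair(sm, "skull-surface",
                                                         current_mA = 2)),
                          strip)
  expect_equal(as.numeric(p2), 2 * as.numeric(p1), tolerance = 1e-9)
})

test_that("electric field of synthetic potentials behaves as a gradient", {
  m <- small_voxel_sphere()
  dims <- dim(m$labels)
  # linear ramp: 1 mV per mm along x
  xs <- (seq_len(dims[1]) - 0.5) * m$voxel_mm + m$origin_mm[1]
  V <- array(rep(xs * 1e-3, times = prod(dims[2:3])), dim = dims)
  V[m$labels == 0L] <- NA
  sol <- shuntfield:::new_field_solution("voxels", m, NULL, potential_V = V,
                                         residual = 0, iterations = 0L)
  sol <- electric_field(sol)
  mag <- sol$field_magnitude
  expect_equal(max(abs(mag[!is.na(mag)] - 1)), 0, tolerance = 1e-9)

  V0 <- array(0.5, dim = dims); V0[m$labels == 0L] <- NA
  sol0 <- shuntfield:::new_field_solution("voxels", m, NULL,
                                          potential_V = V0,
                                          residual = 0, iterations = 0L)
  sol0 <- electric_field(sol0)
  expect_equal(max(abs(sol0$field_magnitude), na.rm = TRUE), 0)
})

test_that("strip sampling reflects field geometry and linearity", {
  m <- small_voxel_sphere()
  dims <- dim(m$labels)
  xs <- (seq_len(dims[1]) - 0.5) * m$voxel_mm + m$origin_mm[1]
  # uniform 1 mV/mm field along x, strip along x at the center
  V <- array(rep(xs * 1e-3, times = prod(dims[2:3])), dim = dims)
  sol <- shuntfield:::new_field_solution("voxels", m, NULL, potential_V = V,
                                         residual = 0, iterations = 0L)
  contacts <- cbind(seq(-8, 8, by = 5), 0, 0)
  strip <- strip_spec(contacts, spacing_mm = 5)
  v <- field_along_strip(sol, strip)
  expect_equal(diff(as.numeric(v)) * 1000, rep(5, 3), tolerance = 1e-9)
  expect_equal(strip_pair_fields(v), rep(1, 3), tolerance = 1e-9)

  # field perpendicular to the strip: zero adjacent differences
  strip_y <- strip_spec(cbind(0, seq(-8, 8, by = 5), 0), spacing_mm = 5)
  vy <- field_along_strip(sol, strip_y)
  expect_equal(strip_pair_fields(vy), rep(0, 3), tolerance = 1e-9)

  expect_error(field_along_strip(sol, strip_spec(cbind(c(0, 100), 0, 0))),
               "outside")
})

test_that("depth profiles decrease under the electrode and are flat in slabs", {
  sm <- beagle_shells()
  ses <- solve_potential(sm, shell_pair(sm, "skull-surface"))
  dp <- depth_profile(ses, c(0, 0, beagle_radii[1] - 0.2), c(0, 0, -1),
                      max_depth_mm = 10, step_mm = 1)
  expect_true(all(diff(dp$field_mV_mm) < 0))

  tes <- solve_potential(sm, shell_pair(sm, "scalp-surface"))
  dt <- depth_profile(tes, c(0, 0, beagle_radii[1] - 0.2), c(0, 0, -1),
                      max_depth_mm = 10, step_mm = 1)
  expect_gt(dp$field_mV_mm[1], dt$field_mV_mm[1])

  # a profile that exits the model is truncated and flagged
  short <- depth_profile(ses, c(0, 0, 30), c(0, 0, 1),
                         max_depth_mm = 20, step_mm = 1)
  expect_true(attr(short, "truncated"))
})

test_that("injected current is conserved across separating planes", {
  m <- small_voxel_sphere()
  sol <- solve_potential(m, shell_pair_on_voxels(m, "scalp-surface"),
                         tolerance = 1e-10)
  for (z0 in c(-10, 0, 10)) {
    I <- current_through_plane(sol, 3, z0)
    expect_lt(abs(abs(I) - 1), 0.01)
  }
})

test_that("transfer impedances are reciprocal", {
  m <- small_voxel_sphere()
  p <- function(dir, role, cur)
    electrode_patch(dir * 20, 0.3, "scalp-surface", role, cur)
  mA <- place_montage(m, list(p(c(0, 0, 1), "active", 1),
                              p(c(0, 0, -1), "reference", -1)))
  mB <- place_montage(m, list(p(c(1, 0, 0), "active", 1),
                              p(c(-1, 0, 0), "reference", -1)))
  sA <- solve_potential(m, mA, tolerance = 1e-10)
  sB <- solve_potential(m, mB, tolerance = 1e-10)
  vmean <- function(sol, mont, i)
    mean(sol$potential_V[arrayInd(mont$footprints[[i]]$voxels,
                                  dim(m$labels))])
  tAB <- vmean(sA, mB, 1) - vmean(sA, mB, 2)
  tBA <- vmean(sB, mA, 1) - vmean(sB, mA, 2)
  expect_lt(abs(tAB - tBA) / abs(tAB), 1e-6)
})

test_that("inner-surface field is non-increasing in scalp conductivity", {
  fields <- vapply(c(4e-4, 4e-3, 4e-2, 0.4), function(ss) {
    sig <- unclass(optimized_conductivities())
    sig[["scalp"]] <- ss
    m <- build_shell_model(beagle_radii, conductivity_set(sig))
    strip <- strip_on_inner_surface(m, 8)
    sol <- solve_potential(m, shell_pair(m, "scalp-surface"))
    max(strip_pair_fields(field_along_strip(sol, strip)))
  }, numeric(1))
  expect_true(all(diff(fields) <= 0))
})

test_that("skull-surface injection beats scalp-surface injection at the inner surface", {
  m <- beagle_shells()   # optimized conductivities: scalp 4e-4, skull 4e-3
  strip <- strip_on_inner_surface(m, 8)
  f_ses <- strip_pair_fields(field_along_strip(
    solve_potential(m, shell_pair(m, "skull-surface")), strip))
  f_tes <- strip_pair_fields(field_along_strip(
    solve_potential(m, shell_pair(m, "scalp-surface")), strip))
  expect_gt(max(f_ses), max(f_tes))
})

test_that("voxel solver agrees with the shell series oracle and refines", {
  # thicker layers so that a 2 mm -> 1 mm refinement pair is legal
  layers <- c(scalp = 4, skull = 4, CSF = 4)
  radii <- c(34, 38, 42, 46)
  sig4 <- as.numeric(optimized_conductivities()[c("brain", "CSF", "skull",
                                                  "scalp")])
  err <- vapply(c(2, 1), function(vox) {
    m <- build_voxel_head(rep(46, 3), layers = layers, voxel_mm = vox,
                          conductivities = optimized_conductivities(),
                          core_tissue = "brain")
    mont <- place_montage(m, list(
      electrode_patch(c(0, 0, 42), 0.25, "skull-surface", "active", 1),
      electrode_patch(c(0, 0, -42), 0.25, "skull-surface", "reference", -1)))
    sol <- solve_potential(m, mont)
    th <- seq(0.1, pi - 0.1, length.out = 60)
    w <- sin(th)
    pts <- cbind(33 * sin(th), 0, 33 * cos(th))
    va <- analytic_shell_potential(radii, sig4, pts, c(0, 0, 1), c(0, 0, -1),
                                   source_radius = 42, sink_radius = 42,
                                   n_max = 600)
    vf <- shuntfield:::interp_trilinear(sol, pts)
    va <- va - weighted.mean(va, w)
    vf <- vf - weighted.mean(vf, w)
    sqrt(sum(w * (vf - va)^2) / sum(w * va^2))
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1])   # error decreases under refinement
})

test_that("solver reports non-convergence with the residual", {
  m <- small_voxel_sphere()
  expect_error(solve_potential(m, shell_pair_on_voxels(m, "scalp-surface"),
                               tolerance = 1e-12, max_iterations = 3L),
               "did not converge")
})
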