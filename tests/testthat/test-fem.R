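# Slab geometry: 20 x 20 x 10 mm box, full-face plates at z = 0 / z = 10.
# With sigma = 0.275 S/m and 1 V across 10 mm the analytic field is a
# uniform 100 V/m and the current is sigma * A * dV / d = 11 mA.
slab_case <- function() {
  mesh <- build_slab(20, 20, 10, nx = 4, ny = 4, nz = 5)
  sol <- solve_potential(mesh, dirichlet = list(z1 = 1, z0 = 0))
  list(mesh = mesh, sol = sol)
}

test_that("homogeneous slab with plate electrodes gives a uniform field", {
  cs <- slab_case()
  expect_lt(max(abs(cs$sol$magnitude - 100)) / 100, 1e-6)
  # any interior ROI mean equals the uniform field exactly
  roi <- roi_spec(c(10, 10, 5), radius = 4)
  expect_equal(roi_mean_magnitude(cs$mesh, cs$sol, roi), 100,
               tolerance = 1e-9)
})

test_that("slab injected current matches the hand formula and conserves", {
  cs <- slab_case()
  I1 <- sum(cs$sol$nodal_current[cs$mesh$node_sets$z1]) * 1e3
  I0 <- sum(cs$sol$nodal_current[cs$mesh$node_sets$z0]) * 1e3
  expect_lt(abs(I1 - 11) / 11, 1e-6)         # sigma * A * dV / d
  expect_lt(abs(I1 + I0) / abs(I1), 1e-9)    # charge conservation
})

test_that("interior-surface flux equals the electrode current (brute force)", {
  cs <- slab_case()
  mesh <- cs$mesh
  # element-loop oracle: accumulate nodal currents r_i = sum_e sigma
  # vol_e grad(phi_e) . grad(N_i) without the sparse stiffness machinery
  g <- tdcsfield:::element_gradients(mesh)
  sig <- conductivity_defaults()[mesh$tissue]
  phi <- cs$sol$phi
  r <- numeric(nrow(mesh$nodes))
  for (e in seq_len(nrow(mesh$elements))) {
    nd <- mesh$elements[e, ]
    G <- rbind(g$gx[e, ], g$gy[e, ], g$gz[e, ])
    gp <- G %*% phi[nd]
    r[nd] <- r[nd] + sig[e] * g$vol[e] * as.numeric(crossprod(G, gp))
  }
  # flux out of the node set above the mid-plane = anode-side current
  above <- which(mesh$nodes[, 3] > 5)
  I_flux <- sum(r[above]) * 1e3
  I_anode <- sum(cs$sol$nodal_current[mesh$node_sets$z1]) * 1e3
  expect_lt(abs(I_flux - I_anode) / abs(I_anode), 1e-9)
})

test_that("swapping anode and cathode negates the field", {
  mesh <- build_slab(20, 20, 10, nx = 3, ny = 3, nz = 4)
  s1 <- solve_potential(mesh, dirichlet = list(z1 = 1, z0 = -1))
  s2 <- solve_potential(mesh, dirichlet = list(z1 = -1, z0 = 1))
  expect_equal(s1$E, -s2$E, tolerance = 1e-9)
  expect_equal(s1$magnitude, s2$magnitude, tolerance = 1e-9)
})

test_that("current scaling is exactly linear", {
  cs <- slab_case()
  sol <- cs$sol
  sol$injected_mA <- sum(sol$nodal_current[cs$mesh$node_sets$z1]) * 1e3
  s2 <- scale_to_current(sol, 2)
  expect_lt(abs(s2$injected_mA - 2) / 2, 0.005)
  s4 <- scale_to_current(sol, 4)
  expect_equal(s4$magnitude, 2 * s2$magnitude, tolerance = 1e-12)
  expect_error(scale_to_current(sol, 0), "degenerate")
  sol$injected_mA <- 0
  expect_error(scale_to_current(sol, 2), "degenerate")
})

test_that("ROI extraction is volume weighted and fails on empty ROIs", {
  ph <- test_phantom()
  m2 <- attach_electrodes(ph, standard_montage("fp1fp2"))
  sol <- scale_to_current(solve_potential(m2), 2)
  roi <- dlpfc_targets(attr(ph, "layers"))$left
  got <- roi_mean_magnitude(m2, sol, roi)
  # brute-force oracle over an exhaustively scanned element list
  cen <- tet_centroids(m2)
  d <- sqrt(colSums((t(cen) - roi$center)^2))
  inside <- d <= roi$radius & m2$tissue == "gray_matter"
  v <- tet_volumes(m2)[inside]
  expect_equal(got, sum(v * sol$magnitude[inside]) / sum(v),
               tolerance = 1e-12)
  expect_gt(sum(inside), 0)
  expect_error(
    roi_mean_magnitude(m2, sol, roi_spec(c(500, 0, 0), 10)),
    "empty-ROI")
  # tissue filter: scalp ROI centred in gray matter is empty
  expect_error(
    roi_mean_magnitude(m2, sol, roi_spec(roi$center, 5, tissue = "scalp")),
    "empty-ROI")
})

test_that("solution energy is positive and solve errors are raised", {
  cs <- slab_case()
  expect_gt(dissipated_power(cs$mesh, cs$sol), 0)
  mesh <- cs$mesh
  expect_error(solve_potential(mesh, cond = c(gray_matter = 0.3),
                               dirichlet = list(nope = 1, z0 = 0)),
               "unknown")
  expect_error(solve_potential(mesh, cond = c(scalp = 0.465),
                               dirichlet = list(z1 = 1, z0 = 0)),
               "configuration error")
  expect_error(solve_potential(mesh, cond = c(gray_matter = -1),
                               dirichlet = list(z1 = 1, z0 = 0)),
               "conductivities must be > 0")
})

test_that("sphere solution converges towards the analytic series with mesh
           refinement", {
  radii <- c(scalp = 50, skull = 44, gray_matter = 40)
  sig <- conductivity_defaults()[names(radii)]
  ser <- sphere_cap_potential(radii, sig, cap_angle_deg = 20)
  err <- vapply(c(10, 6), function(h) {
    m <- add_polar_caps(build_shell_sphere(radii, edge_length = h), 20)
    sol <- solve_potential(m, sig,
                           dirichlet = list(cap_pos = 1, cap_neg = -1))
    r <- sqrt(rowSums(m$nodes^2))
    ct <- ifelse(r > 0, m$nodes[, 3] / r, 0)
    sel <- which(r > 1 & abs(ct) <= cos(30 * pi / 180))
    ref <- ser$predict(m$nodes[sel, ])
    sqrt(sum((sol$phi[sel] - ref)^2) / sum(ref^2))
  }, numeric(1))
  expect_lt(err[2], err[1])          # refinement reduces the error
  expect_lt(err[2], 0.05)
})

test_that("analytic series oracle is self-consistent", {
  radii <- c(scalp = 50, skull = 44, gray_matter = 40)
  sig <- conductivity_defaults()[names(radii)]
  s <- sphere_cap_potential(radii, sig, cap_angle_deg = 20)
  # boundary condition reproduced at the cap centre
  expect_equal(s$predict(rbind(c(0, 0, 49.999))), 1, tolerance = 1e-2)
  # antisymmetry
  p <- rbind(c(10, 8, 30))
  expect_equal(s$predict(p), -s$predict(-p), tolerance = 1e-12)
  # equator is an equipotential at 0
  expect_equal(s$predict(rbind(c(25, 0, 0), c(0, 40, 0))), c(0, 0),
               tolerance = 1e-12)
})

test_that("Legendre recurrence matches closed forms", {
  x <- seq(-1, 1, length.out = 11)
  P <- legendre_p(3, x)
  expect_equal(P[, 3], (3 * x^2 - 1) / 2, tolerance = 1e-14)
  expect_equal(P[, 4], (5 * x^3 - 3 * x) / 2, tolerance = 1e-14)
})
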