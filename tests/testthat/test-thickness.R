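test_that("flat five-layer slab thicknesses are exact", {
  sl <- test_slab()
  tp <- thickness_profile(sl, c(20, 20, 28), radius = 12)
  expect_equal(tp$scalp, 7, tolerance = 1e-12)
  expect_equal(tp$skull, 6, tolerance = 1e-12)
  expect_equal(tp$CSF, 2, tolerance = 1e-12)
  expect_equal(tp$cortex, 3, tolerance = 1e-12)
  expect_identical(tp$scalp_to_cortex, tp$scalp + tp$skull + tp$CSF)
})

test_that("sphere phantom recovers the layer thicknesses within half an
           edge length", {
  ph <- test_phantom(6)
  loc <- 78 * direction_deg(-25)
  tp <- thickness_profile(ph, loc, radius = 10)
  tol <- ph$edge_length / 2
  expect_lt(abs(tp$scalp - 7), tol)
  expect_lt(abs(tp$skull - 6), tol)
  expect_lt(abs(tp$CSF - 2), tol)
  expect_lt(abs(tp$cortex - 3), tol)
  expect_lt(abs(tp$scalp_to_cortex - 15), 3 * tol)
  expect_identical(tp$scalp_to_cortex, tp$scalp + tp$skull + tp$CSF)
  expect_true(all(tp$n_used >= 1))
})

test_that("scalp ROI selection matches a brute-force scan and is monotone", {
  ph <- test_phantom()
  loc <- 78 * direction_deg(30)
  r10 <- select_scalp_roi(ph, loc, 10)
  r5 <- select_scalp_roi(ph, loc, 5)
  expect_true(all(r5 %in% r10))
  cen <- tet_centroids(ph)
  expect_true(all(sqrt(colSums((t(cen[r10, ]) - loc)^2)) <= 10))
  # oracle: scan every scalp element with an exterior face
  surf <- outer_surface(ph)
  outer_scalp <- unique(surf$elem[ph$tissue[surf$elem] == "scalp"])
  d <- sqrt(colSums((t(cen[outer_scalp, ]) - loc)^2))
  expect_setequal(r10, outer_scalp[d <= 10])
})

test_that("ROI and layer preconditions raise informative errors", {
  ph <- test_phantom()
  expect_error(select_scalp_roi(ph, c(0, 0, 0), 10), "placement error")
  expect_error(select_scalp_roi(ph, 78 * direction_deg(10), -1), "radius")
  # mesh without a CSF layer: the CSF step must name the missing layer
  no_csf <- build_shell_sphere(
    c(scalp = 78, skull = 71, gray_matter = 63, white_matter = 60),
    edge_length = 10)
  expect_error(thickness_profile(no_csf, c(0, 0, 78)), "CSF")
})

test_that("tightening the perpendicularity tolerance barely moves the
           sphere estimate", {
  ph <- test_phantom(6)
  loc <- 78 * direction_deg(-25)
  roi <- select_scalp_roi(ph, loc, 10)
  t90 <- layer_thickness(ph, roi, "skull", angle_tol = 90)
  t30 <- layer_thickness(ph, roi, "skull", angle_tol = 30)
  expect_lt(abs(t30$mean_mm / t90$mean_mm - 1), 0.02)
})

test_that("thickness estimates are invariant under rigid rotation", {
  ph <- test_phantom()
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  Rot <- R2 %*% R
  phr <- rotate_mesh(ph, Rot)
  loc <- 78 * direction_deg(-25)
  t1 <- thickness_profile(ph, loc, radius = 10)
  t2 <- thickness_profile(phr, as.numeric(Rot %*% loc), radius = 10)
  for (nm in c("scalp", "skull", "CSF", "cortex", "scalp_to_cortex"))
    expect_equal(t1[[nm]], t2[[nm]], tolerance = 1e-6)
})

test_that("reported scalp thickness is monotone in the generating BMI", {
  # two phantoms whose scalp layer comes from the BMI link at zero noise
  th <- scalp_thickness_from_bmi(c(20, 35), noise_sd = 0)
  mk <- function(t) suppressWarnings(build_layered_sphere(
    layer_spec(scalp = 71 + t, skull = 71, CSF = 65, gray_matter = 63,
               white_matter = 60, edge_length = 8)))
  loc1 <- (71 + th[1]) * direction_deg(0)
  loc2 <- (71 + th[2]) * direction_deg(0)
  tp1 <- thickness_profile(mk(th[1]), loc1)
  tp2 <- thickness_profile(mk(th[2]), loc2)
  expect_gt(tp2$scalp, tp1$scalp)
})
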