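test_that("layered-sphere phantom satisfies its construction invariants", {
  ph <- test_phantom()
  expect_setequal(unique(ph$tissue), head_tissues())
  v <- tet_volumes(ph)
  expect_true(all(v > 0))
  # shell volumes close to the analytic 4/3 pi r^3 differences
  r <- attr(ph, "layers")$radii
  shell_true <- -diff(c(4 / 3 * pi * r^3, 0))
  shell_mesh <- tapply(v, ph$tissue, sum)[names(r)]
  expect_true(all(abs(shell_mesh / shell_true - 1) < 0.02))
  # label-shell consistency: centroid radius within the label band (+- edge)
  rc <- sqrt(rowSums(tet_centroids(ph)^2))
  bands <- cbind(lo = c(r[-1], 0), hi = r)
  rownames(bands) <- names(r)
  edge <- ph$edge_length
  for (t in names(r)) {
    rr <- rc[ph$tissue == t]
    expect_true(all(rr > bands[t, "lo"] - edge & rr < bands[t, "hi"] + edge))
  }
})

test_that("phantom construction is deterministic", {
  ls_ <- suppressWarnings(layer_spec(edge_length = 12))
  m1 <- build_layered_sphere(ls_, seed = 3)
  m2 <- build_layered_sphere(ls_, seed = 3)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$tissue, m2$tissue)
})

test_that("invalid layer specifications are rejected", {
  expect_error(layer_spec(scalp = 70, skull = 71), "strictly decreasing")
  expect_error(layer_spec(edge_length = 0), "edge_length")
  expect_error(layer_spec(edge_length = -3), "edge_length")
  expect_warning(layer_spec(edge_length = 10), "thinnest layer")
})

test_that("scalp shell thickness is recovered by radial centroid sampling", {
  ph <- test_phantom()
  rc <- sqrt(rowSums(tet_centroids(ph)[ph$tissue == "scalp", ]^2))
  # brute-force oracle: scalp centroids span the 71..78 mm band
  expect_lt(max(rc), 78)
  expect_gt(min(rc), 71)
  measured <- max(rc) - min(rc) # span of the sampled band
  expect_lt(abs((78 - 71) - measured), ph$edge_length)
})

test_that("electrode patches have the sponge footprint area and node sets", {
  ph <- test_phantom()
  mon <- standard_montage("fp1fp2")
  m2 <- attach_electrodes(ph, mon)
  for (role in c("anode", "cathode")) {
    area <- electrode_patch_area(m2, role)
    expect_lt(abs(area / 2500 - 1), 0.10) # 25 cm^2 within 10%
    expect_gt(length(m2$node_sets[[paste0(role, "_contact")]]), 0)
  }
  # original head elements unchanged
  n_head <- nrow(ph$elements)
  expect_identical(m2$elements[seq_len(n_head), ], ph$elements)
  expect_identical(m2$tissue[seq_len(n_head)], ph$tissue)
  expect_true(all(m2$tissue[-seq_len(n_head)] == "electrode"))
})

test_that("patch area equals an independent facet-area summation", {
  ph <- test_phantom()
  mon <- standard_montage("f3fp2")
  m2 <- attach_electrodes(ph, mon)
  # oracle: recompute the anode footprint by scanning all exterior scalp
  # faces with an independently coded geodesic-square test
  surf <- outer_surface(ph)
  keep <- ph$tissue[surf$elem] == "scalp"
  face <- surf$face[keep, , drop = FALSE]
  cen <- (ph$nodes[face[, 1], ] + ph$nodes[face[, 2], ] +
            ph$nodes[face[, 3], ]) / 3
  u <- cen / sqrt(rowSums(cen^2))
  c0 <- mon$anode$direction
  R <- 78
  e1 <- c(0, 0, 1) - sum(c(0, 0, 1) * c0) * c0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c0[2] * e1[3] - c0[3] * e1[2], c0[3] * e1[1] - c0[1] * e1[3],
          c0[1] * e1[2] - c0[2] * e1[1])
  al <- acos(pmax(-1, pmin(1, u %*% c0)))
  s <- sqrt((u %*% e1)^2 + (u %*% e2)^2)
  x <- ifelse(s > 0, R * al * (u %*% e1) / s, 0)
  y <- ifelse(s > 0, R * al * (u %*% e2) / s, 0)
  sel <- abs(x) <= 25 & abs(y) <= 25
  ab <- ph$nodes[face[sel, 2], ] - ph$nodes[face[sel, 1], ]
  ac <- ph$nodes[face[sel, 3], ] - ph$nodes[face[sel, 1], ]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  oracle_area <- sum(sqrt(rowSums(cr^2)) / 2)
  expect_equal(electrode_patch_area(m2, "anode"), oracle_area,
               tolerance = 1e-12)
})

test_that("montage invariants are enforced", {
  ph <- test_phantom()
  a <- electrode_spec(c(0, 0, 1), role = "anode")
  a2 <- electrode_spec(c(0, 0, -1), role = "anode")
  c1 <- electrode_spec(c(0, 0, -1), role = "cathode")
  expect_error(montage(a, a2), "montage error")
  expect_error(montage(a, c1, current_mA = 0), "target_current")
  # overlapping footprints
  c_close <- electrode_spec(direction_deg(-30), role = "cathode")
  a_close <- electrode_spec(direction_deg(-35), role = "anode")
  expect_error(attach_electrodes(ph, montage(a_close, c_close)),
               "overlap")
})

test_that("BMI-linked scalp thickness follows the linear link", {
  expect_equal(scalp_thickness_from_bmi(25, slope = 0.15, intercept = 2.5,
                                        noise_sd = 0), 6.25)
  expect_gt(scalp_thickness_from_bmi(35, noise_sd = 0),
            scalp_thickness_from_bmi(20, noise_sd = 0))
  expect_error(scalp_thickness_from_bmi(25, slope = -1), "slope")
  expect_error(scalp_thickness_from_bmi(25, floor_mm = 0), "floor")
  # floor clamps extreme negative noise
  set.seed(1)
  th <- scalp_thickness_from_bmi(rep(10, 2000), slope = 0, intercept = 2.1,
                                 noise_sd = 3, floor_mm = 2)
  expect_true(all(th >= 2))
})

test_that("group BMI difference propagates to scalp thickness (Monte Carlo)", {
  co <- simulate_cohort(10000, 10000, 0, seed = 99)
  th <- scalp_thickness_from_bmi(co$BMI, noise_sd = 0.5, seed = 7)
  d <- mean(th[co$group == "psychosis"]) - mean(th[co$group == "control"])
  expect_gt(d, 0)
})
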