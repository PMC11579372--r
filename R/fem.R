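#' Default tissue conductivities
#'
#' Isotropic conductivities in S/m for the head tissues and the sponge
#' electrode, following standard tDCS simulation practice (scalp 0.465,
#' compact-bone skull 0.010, CSF 1.654, gray matter 0.275, white matter
#' 0.126, saline sponge 1.0). All values are exposed so alternatives can be
#' supplied to [solve_potential()].
#'
#' @return named numeric vector, S/m.
#' @export
conductivity_defaults <- function() {
  c(scalp = 0.465, skull = 0.010, CSF = 1.654,
    gray_matter = 0.275, white_matter = 0.126, electrode = 1.0)
}

# Per-element P1 shape-function gradients and volumes, SI units (metres).
# Returns list(g: list of three m x 4 matrices (x,y,z), vol_m3).
element_gradients <- function(mesh) {
  X <- mesh$nodes * 1e-3                      # mm -> m
  el <- mesh$elements
  p1 <- X[el[, 1L], , drop = FALSE]
  a <- X[el[, 2L], , drop = FALSE] - p1
  b <- X[el[, 3L], , drop = FALSE] - p1
  c_ <- X[el[, 4L], , drop = FALSE] - p1
  det <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
         a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
         a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  # rows of inv(M) for M = [a; b; c] (M maps local to global): grad of
  # barycentric coords 2..4 are rows of inv(M^T) = columns of inv(M).
  # inv(M)^T rows via cross products:
  cr <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  g2 <- cr(b, c_) / det
  g3 <- cr(c_, a) / det
  g4 <- cr(a, b) / det
  g1 <- -(g2 + g3 + g4)
  gx <- cbind(g1[, 1L], g2[, 1L], g3[, 1L], g4[, 1L])
  gy <- cbind(g1[, 2L], g2[, 2L], g3[, 2L], g4[, 2L])
  gz <- cbind(g1[, 3L], g2[, 3L], g3[, 3L], g4[, 3L])
  list(gx = gx, gy = gy, gz = gz, vol = abs(det) / 6)
}

# Sparse conductivity-weighted stiffness matrix (Siemens).
assemble_stiffness <- function(mesh, cond, grad = NULL) {
  missing_t <- setdiff(unique(mesh$tissue), names(cond))
  if (length(missing_t))
    stop("configuration error: no conductivity for tissue(s): ",
         paste(missing_t, collapse = ", "))
  if (any(cond[unique(mesh$tissue)] <= 0))
    stop("configuration error: conductivities must be > 0")
  if (is.null(grad)) grad <- element_gradients(mesh)
  sig <- unname(cond[mesh$tissue])
  w <- sig * grad$vol
  el <- mesh$elements
  m <- nrow(el)
  ii <- jj <- integer(16L * m)
  xx <- numeric(16L * m)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- k * m + seq_len(m)
    ii[idx] <- el[, i]
    jj[idx] <- el[, j]
    xx[idx] <- w * (grad$gx[, i] * grad$gx[, j] +
                    grad$gy[, i] * grad$gy[, j] +
                    grad$gz[, i] * grad$gz[, j])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
}

# Solve a sparse SPD system: Jacobi-preconditioned CG for large systems,
# sparse Cholesky for small ones or on request.
solve_spd <- function(A, b, method = "auto", rtol = 1e-10, maxit = 20000L) {
  if (method == "auto") method <- if (length(b) > 2000L) "cg" else "direct"
  if (method == "direct") {
    out <- tryCatch(
      as.numeric(Matrix::solve(Matrix::forceSymmetric(A), b)),
      error = function(e) stop("solver error: system is singular or ",
                               "ill-conditioned (", conditionMessage(e), ")"))
    return(out)
  }
  d <- Matrix::diag(A)
  if (any(d <= 0))
    stop("solver error: system is singular or ill-conditioned ",
         "(non-positive diagonal; disconnected electrode set?)")
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= rtol * nb) return(x)
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop("solver error: conjugate gradients did not converge in ", maxit,
       " iterations (ill-conditioned or disconnected electrode set?)")
}

resolve_node_set <- function(mesh, x, what = "node set") {
  if (is.character(x)) {
    if (is.null(mesh$node_sets[[x]]))
      stop("unknown ", what, ": '", x, "'")
    x <- mesh$node_sets[[x]]
  }
  x <- as.integer(x)
  if (!length(x)) stop("empty ", what)
  x
}

#' Solve the quasi-static tDCS potential problem
#'
#' First-order (P1) finite element solution of the conductivity-weighted
#' Laplace problem `div(sigma grad phi) = 0` with Dirichlet boundary
#' conditions on electrode contact node sets; the electric field is
#' `E = -grad phi`, constant within each element. By default the two
#' contact sets of an attached montage are held at +1 V (anode) and -1 V
#' (cathode); the solution is subsequently rescaled to a target injected
#' current with [scale_to_current()].
#'
#' @param mesh a [tet_mesh()] with electrode contact node sets (or any node
#'   sets named in `dirichlet`).
#' @param cond named conductivity vector in S/m, see
#'   [conductivity_defaults()].
#' @param dirichlet named list mapping node-set names to fixed potentials
#'   in volts. Default: `list(anode_contact = 1, cathode_contact = -1)`.
#' @param method linear solver: Jacobi-preconditioned conjugate gradients
#'   (`"cg"`, default for systems above ~2000 unknowns), sparse Cholesky
#'   (`"direct"`), or `"auto"`.
#' @param rtol relative residual tolerance for the iterative solver.
#' @return object of class `field_solution`: `phi` (V per node), `E`
#'   (m x 3, V/m per element), `magnitude` (V/m), `injected_mA`, the
#'   residual vector `nodal_current` (A), and `dirichlet_nodes`.
#' @export
solve_potential <- function(mesh, cond = conductivity_defaults(),
                            dirichlet = list(anode_contact = 1,
                                             cathode_contact = -1),
                            method = c("auto", "cg", "direct"),
                            rtol = 1e-10) {
  method <- match.arg(method)
  grad <- element_gradients(mesh)
  K <- assemble_stiffness(mesh, cond, grad)
  n <- nrow(mesh$nodes)
  fixed <- integer(0)
  vals <- numeric(0)
  sets <- vector("list", length(dirichlet))
  names(sets) <- names(dirichlet)
  if (is.null(names(dirichlet)) || any(!nzchar(names(dirichlet))))
    stop("`dirichlet` must be a named list: node-set name -> potential")
  for (nm in names(dirichlet)) {
    ids <- resolve_node_set(mesh, nm, what = "electrode node set")
    sets[[nm]] <- ids
    fixed <- c(fixed, ids)
    vals <- c(vals, rep(as.numeric(dirichlet[[nm]]), length(ids)))
  }
  if (anyDuplicated(fixed)) stop("montage error: electrode node sets overlap")
  free <- setdiff(seq_len(n), fixed)
  phi <- numeric(n)
  phi[fixed] <- vals
  Kff <- K[free, free, drop = FALSE]
  rhs <- as.numeric(-K[free, fixed, drop = FALSE] %*% vals)
  phi[free] <- solve_spd(Kff, rhs, method = method, rtol = rtol)
  # element fields: E = -grad(phi), V/m
  el <- mesh$elements
  P <- cbind(phi[el[, 1L]], phi[el[, 2L]], phi[el[, 3L]], phi[el[, 4L]])
  E <- -cbind(rowSums(P * grad$gx), rowSums(P * grad$gy), rowSums(P * grad$gz))
  r <- as.numeric(K %*% phi)               # nodal currents, A
  anode_ids <- sets[["anode_contact"]]
  inj <- if (!is.null(anode_ids)) sum(r[anode_ids]) * 1e3 else {
    pos <- names(dirichlet)[which.max(unlist(dirichlet))]
    sum(r[sets[[pos]]]) * 1e3
  }
  structure(
    list(phi = phi, E = E, magnitude = sqrt(rowSums(E^2)),
         injected_mA = inj, nodal_current = r,
         dirichlet_sets = sets, montage = attr(mesh, "montage")),
    class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat("field_solution:", length(x$phi), "node potentials,",
      nrow(x$E), "element fields\n")
  cat(sprintf("injected current: %.4f mA; |E| range %.4g..%.4g V/m\n",
              x$injected_mA, min(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Injected current through an electrode
#'
#' Discrete flux through a contact node set, computed from the stiffness
#' residual (equivalent nodal currents); positive out of the anode.
#'
#' @param sol a `field_solution`.
#' @param electrode node-set name used at solve time (or integer node ids).
#' @return current in mA.
#' @export
injected_current <- function(sol, electrode = "anode_contact") {
  ids <- if (is.character(electrode)) {
    if (is.null(sol$dirichlet_sets[[electrode]]))
      stop("unknown electrode node set: '", electrode, "'")
    sol$dirichlet_sets[[electrode]]
  } else as.integer(electrode)
  if (!length(ids)) stop("empty electrode node set")
  sum(sol$nodal_current[ids]) * 1e3
}

#' Rescale a solution to a target injected current
#'
#' The problem is linear, so potentials, fields and nodal currents scale by
#' `target_mA / injected_mA`.
#'
#' @param sol a `field_solution` with nonzero injected current.
#' @param target_mA target current in mA (e.g. 2).
#' @return rescaled `field_solution`.
#' @export
scale_to_current <- function(sol, target_mA) {
  if (!is.finite(target_mA) || target_mA <= 0)
    stop("degenerate-solution error: target current must be > 0")
  if (!is.finite(sol$injected_mA) || abs(sol$injected_mA) < 1e-300)
    stop("degenerate-solution error: solution has zero injected current")
  s <- target_mA / sol$injected_mA
  sol$phi <- sol$phi * s
  sol$E <- sol$E * s
  sol$magnitude <- sol$magnitude * abs(s)
  sol$nodal_current <- sol$nodal_current * s
  sol$injected_mA <- sol$injected_mA * s
  sol
}

#' Region-of-interest specification
#'
#' A spherical ROI in mesh coordinates, by default restricted to gray
#' matter, matching a 10 mm averaging sphere around a stimulation target
#' (a 20 mm variant is common for robustness checks).
#'
#' @param center length-3 numeric, mm.
#' @param radius mm, > 0 (default 10).
#' @param tissue tissue filter label, or `NULL` to include all tissues.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(center, radius = 10, tissue = "gray_matter") {
  if (!is.finite(radius) || radius <= 0) stop("ROI radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 tissue = tissue), class = "roi_spec")
}

#' Mean field magnitude in an ROI
#'
#' Volume-weighted mean of element |E| over elements whose centroid lies
#' within the ROI radius of its centre (centroids exactly on the radius are
#' included) and whose tissue passes the filter. An unweighted mean is
#' available for sensitivity checks.
#'
#' @param mesh the [tet_mesh()] the solution was computed on.
#' @param sol a `field_solution`.
#' @param roi a [roi_spec()].
#' @param weighted volume-weighted (default) or plain mean.
#' @return mean |E| in V/m.
#' @export
roi_mean_magnitude <- function(mesh, sol, roi, weighted = TRUE) {
  cen <- tet_centroids(mesh)
  d2 <- (cen[, 1L] - roi$center[1L])^2 + (cen[, 2L] - roi$center[2L])^2 +
        (cen[, 3L] - roi$center[3L])^2
  inside <- d2 <= roi$radius^2
  if (!is.null(roi$tissue)) inside <- inside & mesh$tissue == roi$tissue
  if (!any(inside))
    stop("empty-ROI error: no ", if (is.null(roi$tissue)) "" else
      paste0(roi$tissue, " "), "element centroid within ", roi$radius,
      " mm of the ROI centre")
  if (weighted) {
    v <- tet_volumes(mesh)[inside]
    sum(v * sol$magnitude[inside]) / sum(v)
  } else mean(sol$magnitude[inside])
}

#' Dissipated power of a solution
#'
#' `sum(sigma |E|^2 vol)` over elements, in watts; strictly positive for
#' any nonzero boundary condition (coercivity check).
#'
#' @inheritParams roi_mean_magnitude
#' @param cond conductivity vector used at solve time.
#' @return power in W.
#' @export
dissipated_power <- function(mesh, sol, cond = conductivity_defaults()) {
  v <- tet_volumes(mesh) * 1e-9             # mm^3 -> m^3
  sum(unname(cond[mesh$tissue]) * sol$magnitude^2 * v)
}

#' dlPFC-analogue ROI targets on the phantom
#'
#' Left and right gray-matter targets at mid-gray-matter radius, at -25 and
#' +25 degrees from the vertex in the montage plane (the anode is on the
#' left, negative-x side).
#'
#' @param layers the [layer_spec()] of the phantom.
#' @param radius ROI radius in mm (10 default, 20 variant).
#' @return named list of two [roi_spec()]s, `left` and `right`.
#' @export
dlpfc_targets <- function(layers, radius = 10) {
  rmid <- (layers$radii[["gray_matter"]] + layers$radii[["white_matter"]]) / 2
  list(left = roi_spec(rmid * direction_deg(-25), radius),
       right = roi_spec(rmid * direction_deg(25), radius))
}

#' Simulate one montage on one phantom
#'
#' Convenience wrapper: attach electrodes, solve, rescale to the montage
#' current, and extract ROI means.
#'
#' @param mesh a layered-sphere phantom without electrodes.
#' @param montage a [montage()].
#' @param cond conductivities, S/m.
#' @param rois named list of [roi_spec()]s.
#' @return list with `solution`, `mesh` (with electrodes) and `roi_mean`
#'   (named vector, V/m).
#' @export
simulate_montage <- function(mesh, montage, cond = conductivity_defaults(),
                             rois = dlpfc_targets(attr(mesh, "layers"))) {
  m2 <- attach_electrodes(mesh, montage)
  sol <- scale_to_current(solve_potential(m2, cond), montage$current_mA)
  roi_mean <- vapply(rois, function(r) roi_mean_magnitude(m2, sol, r),
                     numeric(1))
  list(solution = sol, mesh = m2, roi_mean = roi_mean)
}

#' ROI field across a scalp-thickness ladder
#'
#' Builds a series of phantoms whose scalp shell thickness increases while
#' all inner layers stay fixed, simulates the montage at its target
#' current on each, and records the ROI mean |E|. This realizes the
#' monotone field-attenuation property of increasing scalp (and hence
#' scalp-to-cortex) thickness, and provides the calibration grid for the
#' cohort field surrogate.
#'
#' @param scalp_thicknesses numeric vector of scalp thicknesses, mm.
#' @param base_layers [layer_spec()] providing the inner radii and edge
#'   length; its scalp radius is replaced by `skull + thickness`.
#' @param montage a [montage()].
#' @param cond conductivities.
#' @param roi_radius ROI radius, mm.
#' @return data.frame with `scalp_mm`, `scalp_to_cortex_mm`, `E_left`,
#'   `E_right` (V/m).
#' @export
attenuation_ladder <- function(scalp_thicknesses,
                               base_layers = layer_spec(),
                               montage = standard_montage("fp1fp2"),
                               cond = conductivity_defaults(),
                               roi_radius = 10) {
  r <- base_layers$radii
  out <- lapply(scalp_thicknesses, function(t) {
    ls_t <- suppressWarnings(
      layer_spec(scalp = r[["skull"]] + t, skull = r[["skull"]],
                 CSF = r[["CSF"]], gray_matter = r[["gray_matter"]],
                 white_matter = r[["white_matter"]],
                 edge_length = base_layers$edge_length))
    ph <- build_layered_sphere(ls_t)
    sim <- simulate_montage(ph, montage, cond,
                            rois = dlpfc_targets(ls_t, roi_radius))
    c(E_left = unname(sim$roi_mean["left"]),
      E_right = unname(sim$roi_mean["right"]))
  })
  E <- do.call(rbind, out)
  s2c <- scalp_thicknesses + (r[["skull"]] - r[["CSF"]]) +
    (r[["CSF"]] - r[["gray_matter"]])
  data.frame(scalp_mm = scalp_thicknesses, scalp_to_cortex_mm = s2c,
             E_left = E[, "E_left"], E_right = E[, "E_right"])
}
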