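#' Legendre polynomials
#'
#' Evaluates `P_l(x)` for `l = 0..lmax` by the three-term recurrence.
#'
#' @param lmax highest degree.
#' @param x numeric vector in `[-1, 1]`.
#' @return matrix, `length(x)` rows by `lmax + 1` columns (degree `l` in
#'   column `l + 1`).
#' @export
legendre_p <- function(lmax, x) {
  P <- matrix(0, length(x), lmax + 1L)
  P[, 1L] <- 1
  if (lmax >= 1L) P[, 2L] <- x
  if (lmax >= 2L) for (l in 2:lmax)
    P[, l + 1L] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1L]) / l
  P
}

# Radial mode functions for a concentric-shell conductor.
# radii: outer radii mm, outermost first; sigma: matching conductivities.
# For each degree l returns shell coefficients (A_j, B_j) of
# u_l(t) = A_j t^l + B_j t^-(l+1), t = r/R1, normalized to u_l(1) = 1,
# plus du = u_l'(1) (d/dt at the outer surface).
shell_radial_modes <- function(radii, sigma, ls) {
  ns <- length(radii)
  t_if <- radii[-1L] / radii[1L]          # interface radii, outer shell first
  out <- lapply(ls, function(l) {
    A <- numeric(ns); B <- numeric(ns)
    A[ns] <- 1; B[ns] <- 0
    if (ns >= 2L) for (j in (ns - 1L):1L) {
      t <- t_if[j]                        # interface between shell j, j+1
      val <- A[j + 1L] * t^l + B[j + 1L] * t^(-(l + 1))
      der <- sigma[j + 1L] / sigma[j] *
        (A[j + 1L] * l * t^(l - 1) - B[j + 1L] * (l + 1) * t^(-(l + 2)))
      # solve A t^l + B t^-(l+1) = val ; A l t^(l-1) - B (l+1) t^-(l+2) = der
      # in closed form (the 2x2 system is ill-scaled at high degree)
      A[j] <- ((l + 1) * val + t * der) * t^(-l) / (2 * l + 1)
      B[j] <- (l * val - t * der) * t^(l + 1) / (2 * l + 1)
    }
    u1 <- A[1L] + B[1L]
    list(A = A / u1, B = B / u1,
         du = (A[1L] * l - B[1L] * (l + 1)) / u1)
  })
  names(out) <- as.character(ls)
  out
}

#' Analytic series solution for antipodal cap electrodes on a shell sphere
#'
#' Semi-analytic reference for the mixed boundary-value problem the FEM
#' solver poses on a concentric-shell sphere: two antipodal spherical-cap
#' electrodes on the outer surface held at +1 V (cap around `+z`) and -1 V
#' (around `-z`), insulated elsewhere. The potential is expanded in odd
#' zonal harmonics whose radial parts satisfy the interface conditions
#' exactly (shell recursion); the outer-boundary mixed condition is imposed
#' by least-squares collocation on a Gauss-Legendre grid. Entirely
#' independent of the finite element machinery (no mesh, no sparse
#' algebra), it serves as a validation oracle for [solve_potential()].
#'
#' The boundary potential is found variationally: the Dirichlet energy of a
#' trace `f = sum_l a_l P_l` is the explicit quadratic form
#' `sum_l a_l^2 u'_l(1) / (2l + 1)` (up to a constant factor), and the true
#' solution minimizes it subject to `f = 1` on the cap; the insulation
#' condition off the cap is the natural condition of this minimization and
#' is not imposed explicitly. The cap constraint is enforced by a quadratic
#' penalty on a Gauss grid over the cap. The injected current is evaluated
#' as the (smooth, fast-converging) flux through the equatorial plane.
#'
#' @param radii named numeric vector of outer shell radii in mm, outermost
#'   first; names are tissue labels.
#' @param sigma conductivities in S/m matching `radii` (by name if both are
#'   named, else by position).
#' @param cap_angle_deg angular radius of each cap electrode, degrees.
#' @param lmax highest harmonic degree (odd degrees up to `lmax` are used).
#' @param n_cap number of Gauss points on the cap for the constraint.
#' @param penalty penalty weight on the cap potential constraint.
#' @return object of class `sphere_series` with elements `predict`
#'   (function mapping an n x 3 matrix of mm coordinates to potentials in
#'   V) and `injected_mA`, the total current through the positive cap.
#' @export
sphere_cap_potential <- function(radii, sigma, cap_angle_deg = 20,
                                 lmax = 801L, n_cap = 200L,
                                 penalty = 1e6) {
  if (!is.null(names(sigma)) && !is.null(names(radii)))
    sigma <- sigma[names(radii)]
  sigma <- unname(sigma); radii <- unname(radii)
  if (length(sigma) != length(radii))
    stop("`sigma` must match `radii`")
  ls <- seq(1L, lmax, by = 2L)
  modes <- shell_radial_modes(radii, sigma, ls)
  du <- vapply(modes, `[[`, numeric(1), "du")
  d <- du / (2 * ls + 1)                      # energy quadratic form
  alpha <- cap_angle_deg * pi / 180
  gl <- gauss_legendre(n_cap)
  thc <- (gl$x + 1) / 2 * alpha
  wc <- gl$w * alpha / 2 * sin(thc)           # surface-measure weights
  C <- legendre_p(lmax, cos(thc))[, ls + 1L, drop = FALSE] * sqrt(wc)
  a <- solve(diag(d) + penalty * crossprod(C),
             penalty * as.numeric(crossprod(C, sqrt(wc))))
  shell_A <- vapply(modes, `[[`, numeric(length(radii)), "A")
  shell_B <- vapply(modes, `[[`, numeric(length(radii)), "B")
  if (length(radii) == 1L) {
    shell_A <- matrix(shell_A, 1L); shell_B <- matrix(shell_B, 1L)
  }
  radial_eval <- function(t, j) {
    # u_l(t) within shell j for all degrees; t = r/R1 (vector)
    Aj <- shell_A[j, ]; Bj <- shell_B[j, ]
    U <- outer(t, ls, `^`) * rep(Aj, each = length(t))
    nz <- Bj != 0                              # innermost shell has B = 0
    if (any(nz))
      U[, nz] <- U[, nz, drop = FALSE] +
        outer(t, -(ls[nz] + 1), `^`) * rep(Bj[nz], each = length(t))
    U
  }
  # injected current = flux through the equatorial plane:
  # I = 2 pi |sum_l a_l P'_l(0) int_0^R sigma(r) u_l(r/R) dr|
  dP0 <- local({
    P <- numeric(lmax + 1L); dP <- numeric(lmax + 1L)
    P[1L] <- 1; if (lmax >= 1L) { P[2L] <- 0; dP[2L] <- 1 }
    for (l in 2:lmax) {
      P[l + 1L] <- -(l - 1) * P[l - 1L] / l
      dP[l + 1L] <- ((2 * l - 1) * P[l] - (l - 1) * dP[l - 1L]) / l
    }
    dP[ls + 1L]
  })
  g40 <- gauss_legendre(40L)
  bnd_m <- c(radii, 0) * 1e-3
  tot <- numeric(length(ls))
  for (j in seq_along(radii)) {
    r1 <- bnd_m[j + 1L]; r2 <- bnd_m[j]
    rr <- (g40$x + 1) / 2 * (r2 - r1) + r1
    ww <- g40$w * (r2 - r1) / 2
    tot <- tot + sigma[j] * as.numeric(ww %*% radial_eval(rr / bnd_m[1L], j))
  }
  inj <- abs(2 * pi * sum(a * tot * dP0)) * 1e3  # mA
  predict_fun <- function(points) {
    points <- as.matrix(points)
    r <- sqrt(rowSums(points^2))
    ct <- ifelse(r > 0, points[, 3L] / r, 0)
    Pl <- legendre_p(lmax, ct)[, ls + 1L, drop = FALSE]
    t <- pmin(r / radii[1L], 1)
    shell <- findInterval(-r, -c(radii, 0), rightmost.closed = TRUE)
    shell <- pmin(pmax(shell, 1L), length(radii))
    phi <- numeric(length(r))
    for (j in seq_along(radii)) {
      sel <- shell == j
      if (!any(sel)) next
      U <- radial_eval(t[sel], j)
      phi[sel] <- as.numeric((Pl[sel, , drop = FALSE] * U) %*% a)
    }
    phi
  }
  structure(list(predict = predict_fun, injected_mA = inj,
                 coefficients = a, degrees = ls, radii = radii,
                 sigma = sigma, cap_angle_deg = cap_angle_deg),
            class = "sphere_series")
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1L, ]^2)
}

#' Add antipodal polar cap node sets to a sphere mesh
#'
#' Marks outer-surface nodes within `cap_angle_deg` of the +z and -z poles
#' as node sets `"cap_pos"` / `"cap_neg"`, for use as Dirichlet electrode
#' sets in the analytic validation problem.
#'
#' @param mesh a sphere mesh from [build_shell_sphere()].
#' @param cap_angle_deg angular cap radius in degrees.
#' @return mesh with the two node sets added.
#' @export
add_polar_caps <- function(mesh, cap_angle_deg = 20) {
  surf <- outer_surface(mesh)
  ids <- unique(as.vector(surf$face))
  p <- mesh$nodes[ids, , drop = FALSE]
  r <- sqrt(rowSums(p^2))
  ct <- p[, 3L] / r
  ca <- cos(cap_angle_deg * pi / 180)
  mesh$node_sets$cap_pos <- ids[ct >= ca]
  mesh$node_sets$cap_neg <- ids[ct <= -ca]
  if (!length(mesh$node_sets$cap_pos) || !length(mesh$node_sets$cap_neg))
    stop("cap angle too small: no surface nodes selected")
  mesh
}
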