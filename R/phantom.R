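#' Layer specification for a layered-sphere head phantom
#'
#' Outer radii (mm) of the five concentric tissue shells, strictly
#' decreasing from scalp to white matter, plus a target edge length for the
#' surface triangulation and radial subdivision. Defaults approximate adult
#' frontal anatomy: scalp ~7 mm, skull ~6 mm, CSF ~2 mm, gray matter ~3 mm
#' over a 60 mm white-matter core.
#'
#' @param scalp,skull,CSF,gray_matter,white_matter outer radius of each
#'   shell in mm.
#' @param edge_length target element edge length in mm.
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(scalp = 78, skull = 71, CSF = 65, gray_matter = 63,
                       white_matter = 60, edge_length = 5) {
  r <- c(scalp = scalp, skull = skull, CSF = CSF,
         gray_matter = gray_matter, white_matter = white_matter)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("invalid layers: radii must be positive and finite")
  if (any(diff(r) >= 0))
    stop("invalid layers: radii must be strictly decreasing from scalp to white matter")
  if (!is.finite(edge_length) || edge_length <= 0)
    stop("parameter error: edge_length must be > 0")
  thin <- min(-diff(r))
  if (edge_length >= 2 * thin)
    warning("edge_length is large relative to the thinnest layer (",
            signif(thin, 3), " mm); thin shells get a single radial element")
  structure(list(radii = r, edge_length = edge_length), class = "layer_spec")
}

# Icosahedron subdivided `subdiv` times and projected to the unit sphere.
icosphere <- function(subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    n <- nrow(v)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    key <- pmin(e[, 1L], e[, 2L]) * (n + 1) + pmax(e[, 1L], e[, 2L])
    uk <- unique(key)
    mid_id <- match(key, uk) + n
    ue <- e[match(uk, key), , drop = FALSE]
    mids <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[seq_len(nrow(f)) + nrow(f)]
    m31 <- mid_id[seq_len(nrow(f)) + 2L * nrow(f)]
    f <- rbind(
      cbind(f[, 1L], m12, m31),
      cbind(f[, 2L], m23, m12),
      cbind(f[, 3L], m31, m23),
      cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

# Split triangular prisms into 3 tets each, conforming across shared quad
# faces via the smallest-global-index diagonal rule. `bottom`/`top` are
# k x 3 global node-id matrices; top[i, j] sits above bottom[i, j].
split_prisms <- function(bottom, top) {
  V <- cbind(bottom, top)  # V1 V2 V3 V4 V5 V6 with V(i+3) above Vi
  amin <- max.col(-V, ties.method = "first")
  perms <- rbind(
    c(1L, 2L, 3L, 4L, 5L, 6L),   # min at V1
    c(2L, 3L, 1L, 5L, 6L, 4L),   # min at V2
    c(3L, 1L, 2L, 6L, 4L, 5L),   # min at V3
    c(4L, 6L, 5L, 1L, 3L, 2L),   # min at V4 (flip)
    c(5L, 4L, 6L, 2L, 1L, 3L),   # min at V5
    c(6L, 5L, 4L, 3L, 2L, 1L))   # min at V6
  k <- nrow(V)
  W <- matrix(0L, k, 6L)
  for (cse in 1:6) {
    rows <- amin == cse
    if (any(rows)) W[rows, ] <- V[rows, perms[cse, ], drop = FALSE]
  }
  # third quad face is (W2, W3, W6, W5); diagonal through its smallest vertex
  useW2W6 <- pmin(W[, 2L], W[, 6L]) < pmin(W[, 3L], W[, 5L])
  tets <- matrix(0L, 3L * k, 4L)
  i1 <- seq_len(k)
  a <- which(useW2W6)
  if (length(a)) {
    tets[a, ]          <- W[a, c(1L, 2L, 3L, 6L), drop = FALSE]
    tets[k + a, ]      <- W[a, c(1L, 2L, 6L, 5L), drop = FALSE]
    tets[2L * k + a, ] <- W[a, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  b <- which(!useW2W6)
  if (length(b)) {
    tets[b, ]          <- W[b, c(1L, 2L, 3L, 5L), drop = FALSE]
    tets[k + b, ]      <- W[b, c(1L, 5L, 3L, 6L), drop = FALSE]
    tets[2L * k + b, ] <- W[b, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  tets
}

#' Build a labeled layered-sphere head phantom
#'
#' Constructs a tetrahedral mesh of a ball with concentric shells whose
#' boundaries coincide exactly with the radii in `layers`: an icosphere
#' surface triangulation is extruded radially ("onion" mesh), with node
#' shells placed on every tissue boundary and intermediate shells so that
#' radial spacing does not exceed the target edge length. Elements are
#' labeled by the radial band containing their centroid. The construction
#' is fully deterministic; `seed` is accepted for interface uniformity and
#' recorded, but no randomness is used.
#'
#' @param layers a [layer_spec()].
#' @param seed integer, recorded in the mesh metadata.
#' @return a [tet_mesh()] with attributes `layers`, `seed`.
#' @export
build_layered_sphere <- function(layers, seed = 1L) {
  if (!inherits(layers, "layer_spec")) stop("`layers` must be a layer_spec")
  mesh <- build_shell_sphere(layers$radii, layers$edge_length)
  attr(mesh, "layers") <- layers
  attr(mesh, "seed") <- seed
  mesh
}

#' Generic concentric-shell sphere mesh
#'
#' Like [build_layered_sphere()] but for an arbitrary number of labeled
#' shells (e.g. a classic 3-shell scalp/skull/brain validation sphere).
#'
#' @param radii named numeric vector of strictly decreasing outer radii in
#'   mm; names are tissue labels (outermost first).
#' @param edge_length target edge length in mm.
#' @return a [tet_mesh()].
#' @export
build_shell_sphere <- function(radii, edge_length) {
  r <- radii
  if (is.null(names(r)) || any(!names(r) %in% all_tissues()))
    stop("`radii` must be named with tissue labels")
  if (any(diff(r) >= 0) || any(r <= 0))
    stop("invalid layers: radii must be positive and strictly decreasing")
  h <- edge_length
  if (!is.finite(h) || h <= 0) stop("parameter error: edge_length must be > 0")
  R <- unname(r[1L])
  # icosahedron edge on the unit sphere is ~1.0515; halves per subdivision
  subdiv <- max(0L, ceiling(log2(1.05146 * R / h)))
  ico <- icosphere(subdiv)
  bounds <- sort(unname(r))               # increasing: wm, gm, csf, skull, scalp
  radii <- numeric(0)
  prev <- 0
  for (b in bounds) {
    nseg <- max(1L, ceiling((b - prev) / h))
    radii <- c(radii, prev + (b - prev) * seq_len(nseg) / nseg)
    prev <- b
  }
  nv <- nrow(ico$vertices)
  nshell <- length(radii)
  nodes <- matrix(0, 1L + nv * nshell, 3L)
  for (s in seq_len(nshell))
    nodes[1L + (s - 1L) * nv + seq_len(nv), ] <- radii[s] * ico$vertices
  shell_ids <- function(s) 1L + (s - 1L) * nv + seq_len(nv)
  # innermost: tets from the centre node to shell 1
  f1 <- matrix(shell_ids(1L)[ico$faces], ncol = 3L)
  tets <- cbind(1L, f1)
  for (s in seq_len(nshell - 1L)) {
    bot <- matrix(shell_ids(s)[ico$faces], ncol = 3L)
    top <- matrix(shell_ids(s + 1L)[ico$faces], ncol = 3L)
    tets <- rbind(tets, split_prisms(bot, top))
  }
  cen <- (nodes[tets[, 1L], , drop = FALSE] + nodes[tets[, 2L], , drop = FALSE] +
          nodes[tets[, 3L], , drop = FALSE] + nodes[tets[, 4L], , drop = FALSE]) / 4
  rc <- sqrt(rowSums(cen^2))
  band <- findInterval(rc, bounds) + 1L  # 1..n from centre outwards
  lab <- rev(names(r))[band]
  tet_mesh(nodes, tets, lab, edge_length = h)
}

#' Electrode and montage specification
#'
#' Sponge electrodes are square patches projected geodesically onto the
#' scalp, extruded radially. `center_direction` is a unit vector from the
#' sphere centre; `side` the square side in mm (default 50 mm, i.e. a
#' 25 cm^2 sponge); `thickness` the sponge thickness in mm.
#'
#' @param center_direction length-3 numeric, normalized internally.
#' @param side electrode side length, mm.
#' @param thickness sponge thickness, mm.
#' @param role `"anode"` or `"cathode"`.
#' @return object of class `electrode_spec`.
#' @export
electrode_spec <- function(center_direction, side = 50, thickness = 5,
                           role = c("anode", "cathode")) {
  role <- match.arg(role)
  d <- as.numeric(center_direction)
  if (length(d) != 3L || !all(is.finite(d)) || sum(d^2) == 0)
    stop("center_direction must be a nonzero length-3 vector")
  structure(list(direction = d / sqrt(sum(d^2)), side = side,
                 thickness = thickness, role = role),
            class = "electrode_spec")
}

#' @rdname electrode_spec
#' @param anode,cathode [electrode_spec()] objects with matching roles.
#' @param current_mA target injected current in mA (default 2 mA).
#' @param name montage name, e.g. `"fp1fp2"`.
#' @return `montage()`: object of class `montage`.
#' @export
montage <- function(anode, cathode, current_mA = 2, name = "custom") {
  if (!inherits(anode, "electrode_spec") || !inherits(cathode, "electrode_spec"))
    stop("anode and cathode must be electrode_spec objects")
  if (anode$role != "anode" || cathode$role != "cathode")
    stop("montage error: need exactly one anode and one cathode")
  if (!is.finite(current_mA) || current_mA <= 0)
    stop("montage error: target_current must be > 0")
  structure(list(anode = anode, cathode = cathode,
                 current_mA = current_mA, name = name),
            class = "montage")
}

#' Unit direction in the montage plane
#'
#' Unit vector at `a` degrees from the vertex (+z) in the x-z plane;
#' negative angles are the "left" (anode) side. Used to place electrodes
#' and ROI targets on the spherical phantom.
#'
#' @param a angle in degrees.
#' @return length-3 unit vector.
#' @export
direction_deg <- function(a) c(sin(a * pi / 180), 0, cos(a * pi / 180))

#' Standard frontal montages on the spherical phantom
#'
#' Analogues of the two frontal 10-10 montages used for dlPFC stimulation:
#' a symmetric forehead pair (`"fp1fp2"`, anode left at -35 deg, cathode
#' right at +35 deg from the vertex) and an asymmetric pair (`"f3fp2"`,
#' anode left at -60 deg). Anode left in both, 25 cm^2 sponges, 5 mm thick,
#' 2 mA.
#'
#' @param name `"fp1fp2"` or `"f3fp2"`.
#' @param current_mA target current in mA.
#' @return a [montage()].
#' @export
standard_montage <- function(name = c("fp1fp2", "f3fp2"), current_mA = 2) {
  name <- match.arg(name)
  a <- switch(name, fp1fp2 = -35, f3fp2 = -60)
  montage(
    electrode_spec(direction_deg(a), role = "anode"),
    electrode_spec(direction_deg(35), role = "cathode"),
    current_mA = current_mA, name = name)
}

# geodesic square membership: local azimuthal-equidistant coordinates of
# unit vectors `u` about centre direction `c0`; returns k x 2 matrix (mm).
geodesic_xy <- function(u, c0, R) {
  c0 <- c0 / sqrt(sum(c0^2))
  ref <- if (abs(c0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * c0) * c0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
          c0[3] * e1[1] - c0[1] * e1[3],
          c0[1] * e1[2] - c0[2] * e1[1])
  ca <- pmin(1, pmax(-1, u %*% c0))
  alpha <- acos(drop(ca))
  t1 <- drop(u %*% e1); t2 <- drop(u %*% e2)
  s <- sqrt(t1^2 + t2^2)
  fac <- ifelse(s > 0, R * alpha / s, 0)
  cbind(fac * t1, fac * t2)
}

#' Attach sponge electrodes to a phantom
#'
#' Selects outer-scalp surface triangles whose centroids fall inside each
#' electrode's geodesic square footprint, extrudes them radially by the
#' sponge thickness as electrode-labeled elements, and records the outer
#' (contact) node sets as `"anode_contact"` / `"cathode_contact"`. Head
#' tissue elements are left untouched.
#'
#' @param mesh a layered-sphere [tet_mesh()] (scalp outermost).
#' @param montage a [montage()].
#' @return a [tet_mesh()] with electrode elements, contact node sets, and
#'   an `electrode_areas` attribute (footprint areas in mm^2).
#' @export
attach_electrodes <- function(mesh, montage) {
  if (!inherits(montage, "montage")) stop("`montage` must be a montage")
  surf <- outer_surface(mesh)
  scalp_surf <- mesh$tissue[surf$elem] == "scalp"
  face <- surf$face[scalp_surf, , drop = FALSE]
  if (!nrow(face)) stop("placement error: mesh has no exterior scalp surface")
  cen <- triangle_centroids(mesh$nodes, face)
  R <- mean(sqrt(rowSums(mesh$nodes[unique(as.vector(face)), , drop = FALSE]^2)))
  u <- cen / sqrt(rowSums(cen^2))
  pick <- function(el) {
    xy <- geodesic_xy(u, el$direction, R)
    which(abs(xy[, 1L]) <= el$side / 2 & abs(xy[, 2L]) <= el$side / 2)
  }
  sel <- list(anode = pick(montage$anode), cathode = pick(montage$cathode))
  for (nm in names(sel))
    if (!length(sel[[nm]]))
      stop("placement error: ", nm, " footprint does not intersect the scalp surface")
  if (length(intersect(sel$anode, sel$cathode)))
    stop("montage error: electrode footprints overlap")
  nodes <- mesh$nodes
  elements <- mesh$elements
  tissue <- mesh$tissue
  node_sets <- mesh$node_sets
  areas <- c(anode = NA_real_, cathode = NA_real_)
  for (nm in names(sel)) {
    f <- face[sel[[nm]], , drop = FALSE]
    areas[nm] <- sum(triangle_areas(mesh$nodes, f))
    thick <- (if (nm == "anode") montage$anode else montage$cathode)$thickness
    vids <- sort(unique(as.vector(f)))
    dirs <- nodes[vids, , drop = FALSE]
    dirs <- dirs / sqrt(rowSums(dirs^2))
    new_ids <- nrow(nodes) + seq_along(vids)
    nodes <- rbind(nodes, nodes[vids, , drop = FALSE] + thick * dirs)
    top <- matrix(new_ids[match(as.vector(f), vids)], ncol = 3L)
    tets <- split_prisms(f, top)
    elements <- rbind(elements, tets)
    tissue <- c(tissue, rep("electrode", nrow(tets)))
    node_sets[[paste0(nm, "_contact")]] <- new_ids
  }
  out <- tet_mesh(nodes, elements, tissue, node_sets,
                  edge_length = mesh$edge_length)
  attr(out, "layers") <- attr(mesh, "layers")
  attr(out, "seed") <- attr(mesh, "seed")
  attr(out, "electrode_areas") <- areas
  attr(out, "montage") <- montage
  out
}

#' Electrode footprint area
#'
#' @param mesh mesh returned by [attach_electrodes()].
#' @param role `"anode"` or `"cathode"`.
#' @return footprint area in mm^2.
#' @export
electrode_patch_area <- function(mesh, role = c("anode", "cathode")) {
  role <- match.arg(role)
  a <- attr(mesh, "electrode_areas")
  if (is.null(a)) stop("mesh has no attached electrodes")
  unname(a[role])
}

#' BMI-linked scalp thickness
#'
#' Linear link from body mass index to scalp thickness with Gaussian noise:
#' `thickness = intercept + slope * BMI + N(0, noise_sd)`, clamped below at
#' `floor_mm` so extreme noise cannot produce degenerate layers. With zero
#' noise the link is monotone nondecreasing in BMI.
#'
#' @param bmi numeric vector, kg/m^2.
#' @param slope mm per BMI unit (must be >= 0).
#' @param intercept mm.
#' @param noise_sd mm.
#' @param floor_mm positive lower clamp, mm.
#' @param seed optional integer seed.
#' @return numeric vector of thicknesses, mm.
#' @export
scalp_thickness_from_bmi <- function(bmi, slope = 0.15, intercept = 2.5,
                                     noise_sd = 0.5, floor_mm = 2,
                                     seed = NULL) {
  if (slope < 0) stop("parameter error: slope must be >= 0")
  if (floor_mm <= 0) stop("parameter error: thickness floor must be positive")
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(length(bmi), 0, noise_sd) else 0
  pmax(floor_mm, intercept + slope * bmi + eps)
}
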