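#' Labeled tetrahedral meshes
#'
#' A `tet_mesh` is the substrate for field simulation and tissue-thickness
#' geometry: node coordinates in millimetres, 4-node tetrahedral elements,
#' a tissue label per element, and optional named node-sets (used for
#' electrode contact surfaces).
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm.
#' @param elements integer matrix, m x 4, 1-based node indices.
#' @param tissue character vector of length m; each entry one of
#'   [head_tissues()] or `"electrode"`.
#' @param node_sets named list of integer vectors (node indices).
#' @param edge_length nominal edge length in mm (metadata used for
#'   tolerance heuristics); may be `NA`.
#'
#' @return an object of class `tet_mesh` with positively oriented elements.
#' @export
tet_mesh <- function(nodes, elements, tissue, node_sets = list(),
                     edge_length = NA_real_) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must be an n x 3 matrix")
  if (ncol(elements) != 4L) stop("`elements` must be an m x 4 matrix")
  tissue <- as.character(tissue)
  if (length(tissue) != nrow(elements))
    stop("`tissue` must have one entry per element")
  bad <- setdiff(unique(tissue), all_tissues())
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (min(elements) < 1L || max(elements) > nrow(nodes))
    stop("element node indices out of range")
  mesh <- structure(
    list(nodes = nodes, elements = elements, tissue = tissue,
         node_sets = node_sets, edge_length = edge_length),
    class = "tet_mesh")
  orient_elements(mesh)
}

#' Head tissue labels
#'
#' The five head tissues, ordered from the outside in.
#' @return character vector.
#' @export
head_tissues <- function() {
  c("scalp", "skull", "CSF", "gray_matter", "white_matter")
}

all_tissues <- function() c(head_tissues(), "electrode")

# Reorder nodes of negatively oriented tets so all signed volumes are > 0.
orient_elements <- function(mesh) {
  v <- tet_signed_volumes(mesh)
  if (any(v == 0)) stop("mesh contains degenerate (zero-volume) elements")
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- mesh$elements[neg, 3L]
    mesh$elements[neg, 3L] <- mesh$elements[neg, 4L]
    mesh$elements[neg, 4L] <- tmp
  }
  mesh
}

tet_signed_volumes <- function(mesh) {
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1L], , drop = FALSE]
  a <- mesh$nodes[el[, 2L], , drop = FALSE] - p1
  b <- mesh$nodes[el[, 3L], , drop = FALSE] - p1
  c <- mesh$nodes[el[, 4L], , drop = FALSE] - p1
  det <- a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
         a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
         a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  det / 6
}

#' Element volumes and centroids
#'
#' @param mesh a [tet_mesh()].
#' @return `tet_volumes`: numeric vector of element volumes in mm^3.
#' @export
tet_volumes <- function(mesh) abs(tet_signed_volumes(mesh))

#' @rdname tet_volumes
#' @return `tet_centroids`: m x 3 matrix of element centroids in mm.
#' @export
tet_centroids <- function(mesh) {
  el <- mesh$elements
  (mesh$nodes[el[, 1L], , drop = FALSE] + mesh$nodes[el[, 2L], , drop = FALSE] +
   mesh$nodes[el[, 3L], , drop = FALSE] + mesh$nodes[el[, 4L], , drop = FALSE]) / 4
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$elements), "elements\n")
  print(table(x$tissue))
  if (length(x$node_sets))
    cat("node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

# All element faces as sorted node triples plus owner bookkeeping.
# Returns list(face = k x 3 sorted, elem = owner element id, key = numeric key).
element_faces <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  # local faces opposite each vertex
  idx <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  fa <- rbind(el[, idx[1L, ]], el[, idx[2L, ]], el[, idx[3L, ]], el[, idx[4L, ]])
  # sort each row (3 columns) without apply()
  lo <- pmin(fa[, 1L], fa[, 2L], fa[, 3L])
  hi <- pmax(fa[, 1L], fa[, 2L], fa[, 3L])
  mid <- fa[, 1L] + fa[, 2L] + fa[, 3L] - lo - hi
  srt <- cbind(lo, mid, hi)
  K <- nrow(mesh$nodes) + 1
  key <- (as.numeric(lo) * K + mid) * K + hi
  list(face = srt, elem = rep.int(seq_len(m), 4L), key = key)
}

# Face adjacency: for every unique face, its one or two owning elements.
# Returns data.frame(key, e1, e2) with e2 = NA for boundary faces, plus
# node triples for e1's copy.
face_adjacency <- function(mesh) {
  ef <- element_faces(mesh)
  o <- order(ef$key)
  key <- ef$key[o]; elem <- ef$elem[o]; face <- ef$face[o, , drop = FALSE]
  n <- length(key)
  first <- c(TRUE, key[-1L] != key[-n])
  grp <- cumsum(first)
  e1 <- elem[first]
  e2 <- rep(NA_integer_, length(e1))
  dup <- which(!first)
  e2[grp[dup]] <- elem[dup]
  list(face = face[first, , drop = FALSE], e1 = e1, e2 = e2)
}

#' Exterior surface of a mesh
#'
#' Triangular faces belonging to exactly one tetrahedron.
#'
#' @param mesh a [tet_mesh()].
#' @return list with `face` (k x 3 node triples) and `elem` (owning element).
#' @export
outer_surface <- function(mesh) {
  adj <- face_adjacency(mesh)
  b <- is.na(adj$e2)
  list(face = adj$face[b, , drop = FALSE], elem = adj$e1[b])
}

# Faces on the boundary of `tissue`, i.e. faces of tets labeled `tissue`
# whose neighbour is absent or labeled differently. If `neighbor` is given,
# keep only faces whose other side is that tissue ("exterior" for none).
tissue_boundary_faces <- function(mesh, tissue, neighbor = NULL) {
  adj <- face_adjacency(mesh)
  t1 <- mesh$tissue[adj$e1]
  t2 <- ifelse(is.na(adj$e2), NA_character_, mesh$tissue[adj$e2])
  # orient so that `elem` is the element inside `tissue`
  in1 <- t1 == tissue & (is.na(t2) | t2 != tissue)
  in2 <- !is.na(t2) & t2 == tissue & t1 != tissue
  keep <- in1 | in2
  elem <- ifelse(in1, adj$e1, adj$e2)[keep]
  other <- ifelse(in1, t2, t1)[keep]
  face <- adj$face[keep, , drop = FALSE]
  if (!is.null(neighbor)) {
    sel <- if (identical(neighbor, "exterior")) is.na(other) else
      (!is.na(other) & other == neighbor)
    face <- face[sel, , drop = FALSE]; elem <- elem[sel]; other <- other[sel]
  }
  list(face = face, elem = elem, neighbor = other)
}

triangle_centroids <- function(nodes, face) {
  (nodes[face[, 1L], , drop = FALSE] + nodes[face[, 2L], , drop = FALSE] +
   nodes[face[, 3L], , drop = FALSE]) / 3
}

triangle_areas <- function(nodes, face) {
  a <- nodes[face[, 2L], , drop = FALSE] - nodes[face[, 1L], , drop = FALSE]
  b <- nodes[face[, 3L], , drop = FALSE] - nodes[face[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

triangle_normals <- function(nodes, face) {
  a <- nodes[face[, 2L], , drop = FALSE] - nodes[face[, 1L], , drop = FALSE]
  b <- nodes[face[, 3L], , drop = FALSE] - nodes[face[, 1L], , drop = FALSE]
  n <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n / sqrt(rowSums(n^2))
}

#' Structured tetrahedral slab mesh
#'
#' A rectangular box `[0,lx] x [0,ly] x [0,lz]` meshed with a Kuhn
#' (6-tet-per-cube) triangulation; useful as an analytic validation
#' geometry: full-face plate electrodes at `z = 0` and `z = lz` produce a
#' uniform field. `z_labels` assigns tissue labels by z-bands, e.g.
#' `c(scalp = 3, skull = 6)` labels `z` in `[0,3)` scalp and `[3,6)` skull
#' (upper boundaries; the last band absorbs `z = lz`). Node sets `"z0"` and
#' `"z1"` hold the two face node sets.
#'
#' @param lx,ly,lz box dimensions in mm.
#' @param nx,ny,nz number of cells per axis.
#' @param z_labels named numeric vector of band upper bounds (mm), in
#'   increasing order; names are tissue labels. Default: all gray matter.
#' @return a [tet_mesh()].
#' @export
build_slab <- function(lx, ly, lz, nx = 4L, ny = 4L, nz = 4L,
                       z_labels = c(gray_matter = Inf)) {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  v000 <- nid(cells$i,      cells$j,      cells$k)
  v100 <- nid(cells$i + 1L, cells$j,      cells$k)
  v010 <- nid(cells$i,      cells$j + 1L, cells$k)
  v110 <- nid(cells$i + 1L, cells$j + 1L, cells$k)
  v001 <- nid(cells$i,      cells$j,      cells$k + 1L)
  v101 <- nid(cells$i + 1L, cells$j,      cells$k + 1L)
  v011 <- nid(cells$i,      cells$j + 1L, cells$k + 1L)
  v111 <- nid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  # Kuhn subdivision along main diagonal v000-v111 (conforming across cubes)
  tets <- rbind(
    cbind(v000, v100, v110, v111),
    cbind(v000, v110, v010, v111),
    cbind(v000, v010, v011, v111),
    cbind(v000, v011, v001, v111),
    cbind(v000, v001, v101, v111),
    cbind(v000, v101, v100, v111))
  zc <- (nodes[tets[, 1L], 3L] + nodes[tets[, 2L], 3L] +
         nodes[tets[, 3L], 3L] + nodes[tets[, 4L], 3L]) / 4
  ub <- c(z_labels)
  lab <- names(z_labels)[pmin(findInterval(zc, ub) + 1L, length(ub))]
  node_sets <- list(
    z0 = which(nodes[, 3L] == 0),
    z1 = which(nodes[, 3L] == lz))
  tet_mesh(nodes, tets, lab, node_sets,
           edge_length = max(lx / nx, ly / ny, lz / nz))
}

#' Rigidly rotate a mesh
#'
#' Applies a 3x3 rotation matrix to node coordinates (used for invariance
#' checks).
#' @param mesh a [tet_mesh()].
#' @param R 3x3 rotation matrix.
#' @return rotated [tet_mesh()].
#' @export
rotate_mesh <- function(mesh, R) {
  mesh$nodes <- mesh$nodes %*% t(R)
  mesh
}
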