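#' Select scalp elements in a surface ROI
#'
#' Outermost scalp elements (those with a face on the exterior surface)
#' whose centroid lies within `radius` of a surface point. The ROI ball is
#' Euclidean; at 10 mm on head-scale curvature the difference from a
#' geodesic ball is negligible.
#'
#' @param mesh a [tet_mesh()].
#' @param center length-3 surface point, mm; must lie within about one edge
#'   length of the outer scalp surface.
#' @param radius ROI radius, mm.
#' @return integer vector of element ids.
#' @export
select_scalp_roi <- function(mesh, center, radius = 10) {
  if (!is.finite(radius) || radius <= 0) stop("ROI radius must be > 0")
  bf <- tissue_boundary_faces(mesh, "scalp", neighbor = "exterior")
  if (!nrow(bf$face)) stop("mesh has no exterior scalp surface")
  fc <- triangle_centroids(mesh$nodes, bf$face)
  center <- as.numeric(center)
  dc <- sqrt(colSums((t(fc) - center)^2))
  edge <- mesh$edge_length
  if (!is.finite(edge))
    edge <- sqrt(2 * mean(triangle_areas(mesh$nodes, bf$face)))
  if (min(dc) > 1.5 * edge)
    stop("placement error: ROI centre is ", signif(min(dc), 3),
         " mm from the outer scalp surface")
  ids <- unique(bf$elem)
  cen <- tet_centroids(mesh)[ids, , drop = FALSE]
  d <- sqrt(colSums((t(cen) - center)^2))
  out <- sort(ids[d <= radius])
  if (!length(out))
    stop("empty-ROI error: no outer scalp element centroid within ",
         radius, " mm of the ROI centre")
  out
}

# Nearest point on each triangle (a,b,c) to a single point p.
# Vectorized over triangles (Ericson, Real-Time Collision Detection).
point_triangle_nearest <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- matrix(p, nrow(a), 3L, byrow = TRUE) - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(a), 3L, byrow = TRUE) - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(a), 3L, byrow = TRUE) - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- matrix(NA_real_, nrow(a), 3L)
  done <- rep(FALSE, nrow(a))
  set <- function(m, val) {
    m <- m & !done
    out[m, ] <<- val[m, , drop = FALSE]
    done <<- done | m
  }
  set(d1 <= 0 & d2 <= 0, a)
  set(d3 >= 0 & d4 <= d3, b)
  v <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + v * ab)
  set(d6 >= 0 & d5 <= d6, c)
  w <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + w * ac)
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + w2 * (c - b))
  denom <- 1 / (va + vb + vc)
  set(rep(TRUE, nrow(a)), a + (vb * denom) * ab + (vc * denom) * ac)
  out
}

# outward orientation sign of face normals relative to owning elements
oriented_inward_normals <- function(mesh, face, elem) {
  n <- triangle_normals(mesh$nodes, face)
  fc <- triangle_centroids(mesh$nodes, face)
  ec <- tet_centroids(mesh)[elem, , drop = FALSE]
  s <- sign(rowSums(n * (fc - ec)))          # +1 if n points out of elem
  -n * s                                     # inward = into the element
}

#' Minimum-distance layer thickness along verified normals
#'
#' For each source measurement point, finds the minimum distance to the
#' boundary surface of the target tissue, accepting a candidate only if the
#' direction from the source point to its foot point is within `angle_tol`
#' degrees of the source's inward normal (the paper-style perpendicularity
#' verification); reports the mean of accepted distances. Sources are
#' specified as elements plus per-element measurement origins and inward
#' normals; [thickness_profile()] derives these from interface faces and
#' chains layers. Nearest-candidate ties are broken by lowest face index.
#'
#' @param mesh a [tet_mesh()].
#' @param source_elements integer element ids.
#' @param target_tissue tissue label to measure towards.
#' @param angle_tol acceptance half-angle in degrees (default 45).
#' @param origins optional k x 3 matrix of measurement origins (defaults to
#'   centroids of the source elements' boundary faces with `outer_tissue`).
#' @param normals optional k x 3 matrix of inward normals (same default).
#' @param outer_tissue tissue on the far side of the source elements used
#'   to derive default origins/normals; `"exterior"` (default) means the
#'   mesh surface.
#' @return list with `mean_mm`, per-source `distances_mm`, `accepted`
#'   logical, `foot_elements`, `foot_faces` (h x 3 node ids), `foot_points`
#'   (h x 3), and `n_used`.
#' @export
layer_thickness <- function(mesh, source_elements, target_tissue,
                            angle_tol = 45, origins = NULL, normals = NULL,
                            outer_tissue = "exterior") {
  if (!length(source_elements)) stop("source element set is empty")
  if (!target_tissue %in% mesh$tissue)
    stop("thickness error: tissue '", target_tissue,
         "' absent from mesh")
  if (is.null(origins) || is.null(normals)) {
    bf <- tissue_boundary_faces(mesh, mesh$tissue[source_elements[1L]],
                                neighbor = outer_tissue)
    keep <- bf$elem %in% source_elements
    if (!any(keep))
      stop("source elements have no boundary face with ",
           outer_tissue)
    # one face per element (lowest face order wins)
    el <- bf$elem[keep]
    fa <- bf$face[keep, , drop = FALSE]
    first <- !duplicated(el)
    el <- el[first]; fa <- fa[first, , drop = FALSE]
    o <- order(el)
    source_elements <- el[o]
    fa <- fa[o, , drop = FALSE]
    origins <- triangle_centroids(mesh$nodes, fa)
    normals <- oriented_inward_normals(mesh, fa, source_elements)
  }
  tb <- tissue_boundary_faces(mesh, target_tissue)
  fc <- triangle_centroids(mesh$nodes, tb$face)
  a <- mesh$nodes[tb$face[, 1L], , drop = FALSE]
  b <- mesh$nodes[tb$face[, 2L], , drop = FALSE]
  c_ <- mesh$nodes[tb$face[, 3L], , drop = FALSE]
  k <- length(source_elements)
  ncand <- min(nrow(fc), 80L)
  dist <- rep(NA_real_, k)
  foot_face <- rep(NA_integer_, k)
  foot_pt <- matrix(NA_real_, k, 3L)
  ctol <- cos(angle_tol * pi / 180)
  for (i in seq_len(k)) {
    p <- origins[i, ]
    dc <- colSums((t(fc) - p)^2)
    cand <- order(dc)[seq_len(ncand)]
    np <- point_triangle_nearest(p, a[cand, , drop = FALSE],
                                 b[cand, , drop = FALSE],
                                 c_[cand, , drop = FALSE])
    dd <- sqrt(rowSums((np - matrix(p, ncand, 3L, byrow = TRUE))^2))
    o <- order(dd, cand)                     # tie-break: lowest face index
    for (j in o) {
      d <- dd[j]
      if (d <= 0) next
      dir <- (np[j, ] - p) / d
      if (sum(dir * normals[i, ]) >= ctol) {
        dist[i] <- d
        foot_face[i] <- cand[j]
        foot_pt[i, ] <- np[j, ]
        break
      }
    }
  }
  acc <- !is.na(dist)
  if (!any(acc))
    stop("perpendicularity-failure error: no accepted source-target pair ",
         "towards '", target_tissue, "' within ", angle_tol, " degrees")
  list(mean_mm = mean(dist[acc]),
       distances_mm = dist,
       accepted = acc,
       foot_elements = tb$elem[foot_face[acc]],
       foot_faces = tb$face[foot_face[acc], , drop = FALSE],
       foot_points = foot_pt[acc, , drop = FALSE],
       n_used = sum(acc))
}

# collapse chained foot points to unique elements (lowest element id order),
# returning origins (face centroids) and inward normals for the next layer
chain_sources <- function(mesh, lt) {
  el <- lt$foot_elements
  fa <- lt$foot_faces
  first <- !duplicated(el)
  el <- el[first]; fa <- fa[first, , drop = FALSE]
  o <- order(el)
  el <- el[o]; fa <- fa[o, , drop = FALSE]
  list(elements = el,
       origins = triangle_centroids(mesh$nodes, fa),
       normals = oriented_inward_normals(mesh, fa, el))
}

#' Chained tissue-thickness profile at a scalp location
#'
#' Implements the normal-vector thickness algorithm: scalp elements in a
#' surface ROI are measured to the nearest skull surface along verified
#' inward normals; the skull foot-point elements are then measured to the
#' CSF surface, those to the gray-matter surface, and the gray-matter
#' foot-points to the white-matter surface (cortical thickness). Each
#' layer's normals are re-derived from that layer's interface faces. The
#' scalp-to-cortex aggregate is the sum of the scalp, skull and CSF means
#' (cortex is reported but excluded from the aggregate).
#'
#' @param mesh a [tet_mesh()] containing all five head tissues.
#' @param location length-3 scalp surface point, mm.
#' @param radius scalp ROI radius, mm (default 10).
#' @param angle_tol perpendicularity tolerance, degrees (default 45).
#' @param label optional location label carried into the report.
#' @return object of class `thickness_report`: a list with `location`,
#'   per-layer thicknesses `scalp`, `skull`, `CSF`, `cortex` (mm),
#'   `scalp_to_cortex = scalp + skull + CSF`, and per-layer element counts
#'   `n_used`.
#' @export
thickness_profile <- function(mesh, location, radius = 10, angle_tol = 45,
                              label = NULL) {
  steps <- list(
    scalp = "skull",
    skull = "CSF",
    CSF = "gray_matter",
    cortex = "white_matter")
  for (t in c(head_tissues()))
    if (!t %in% mesh$tissue)
      stop("thickness error: tissue '", t, "' absent from mesh")
  roi <- select_scalp_roi(mesh, location, radius)
  res <- list()
  src <- list(elements = roi, origins = NULL, normals = NULL)
  for (nm in names(steps)) {
    lt <- tryCatch(
      layer_thickness(mesh, src$elements, steps[[nm]],
                      angle_tol = angle_tol,
                      origins = src$origins, normals = src$normals),
      error = function(e)
        stop(nm, " layer: ", conditionMessage(e), call. = FALSE))
    res[[nm]] <- lt
    src <- chain_sources(mesh, lt)
  }
  structure(
    list(location = if (is.null(label)) as.numeric(location) else label,
         scalp = res$scalp$mean_mm,
         skull = res$skull$mean_mm,
         CSF = res$CSF$mean_mm,
         cortex = res$cortex$mean_mm,
         scalp_to_cortex = res$scalp$mean_mm + res$skull$mean_mm +
           res$CSF$mean_mm,
         n_used = vapply(res, `[[`, numeric(1), "n_used")),
    class = "thickness_report")
}

#' @export
print.thickness_report <- function(x, ...) {
  cat("thickness_report at",
      if (is.character(x$location)) x$location else
        paste0("(", paste(signif(x$location, 4), collapse = ", "), ") mm"),
      "\n")
  for (nm in c("scalp", "skull", "CSF", "cortex", "scalp_to_cortex"))
    cat(sprintf("  %-16s %6.2f mm\n", nm, x[[nm]]))
  invisible(x)
}
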