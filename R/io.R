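#' Default tissue tag map for Gmsh physical tags
#'
#' @return named integer vector mapping tissue label to physical tag.
#' @export
tissue_tags <- function() {
  stats::setNames(seq_along(all_tissues()), all_tissues())
}

#' Write a labeled tetrahedral mesh as Gmsh ASCII v2.2
#'
#' Tissue labels are carried as physical tags (and `$PhysicalNames`); node
#' sets and the tag-to-tissue map are stored in a JSON sidecar at
#' `<path>.json`. Coordinates are written with 17 significant digits so a
#' write/read round trip reproduces them exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.msh` path.
#' @param tags named integer vector mapping tissue labels to physical
#'   tags (default [tissue_tags()]).
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path, tags = tissue_tags()) {
  used <- unique(mesh$tissue)
  if (!all(used %in% names(tags)))
    stop("labeling error: no tag for tissue(s): ",
         paste(setdiff(used, names(tags)), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", as.character(length(used)))
  for (t in used) wl(sprintf('3 %d "%s"', tags[[t]], t))
  wl("$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)))
  wl(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]))
  wl("$EndNodes")
  wl("$Elements", as.character(nrow(mesh$elements)))
  wl(sprintf("%d 4 2 %d 1 %d %d %d %d", seq_len(nrow(mesh$elements)),
             unname(tags[mesh$tissue]), mesh$elements[, 1L],
             mesh$elements[, 2L], mesh$elements[, 3L],
             mesh$elements[, 4L]))
  wl("$EndElements")
  sidecar <- list(
    format = "tdcsfield-msh-sidecar", version = 1L,
    tissue_tags = as.list(tags[used]),
    edge_length = mesh$edge_length,
    node_sets = mesh$node_sets)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a Gmsh ASCII v2.2 tetrahedral mesh
#'
#' Reads nodes, 4-node tetrahedra and physical tags; tags are mapped to
#' tissue labels through the JSON sidecar written by [write_msh()] (or,
#' failing that, the file's own `$PhysicalNames`). Elements of other types
#' are ignored. Unmapped tags and malformed sections raise errors (the
#' latter with the offending line number).
#'
#' @param path `.msh` path.
#' @param sidecar sidecar path (default `<path>.json`); `NULL` to rely on
#'   `$PhysicalNames` only.
#' @return a [tet_mesh()].
#' @export
read_msh <- function(path, sidecar = paste0(path, ".json")) {
  lines <- readLines(path)
  sect <- function(name) {
    s <- which(lines == paste0("$", name))
    e <- which(lines == paste0("$End", name))
    if (length(s) != 1L || length(e) != 1L || e <= s)
      stop("parse error: section $", name, " missing or malformed",
           if (length(s)) paste0(" (line ", s[1L], ")"))
    (s + 1L):(e - 1L)
  }
  fmt <- lines[sect("MeshFormat")][1L]
  if (!startsWith(fmt, "2.2"))
    stop("parse error: unsupported MeshFormat '", fmt, "' (need 2.2)")
  tag2tissue <- NULL
  if (!is.null(sidecar) && file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tag2tissue <- stats::setNames(names(sc$tissue_tags),
                                  unlist(sc$tissue_tags))
  } else if (any(lines == "$PhysicalNames")) {
    idx <- sect("PhysicalNames")[-1L]
    pn <- regmatches(lines[idx],
                     regexec('^\\s*\\d+\\s+(\\d+)\\s+"(.*)"', lines[idx]))
    tag2tissue <- stats::setNames(vapply(pn, `[`, "", 3L),
                                  vapply(pn, `[`, "", 2L))
  }
  if (is.null(tag2tissue))
    stop("labeling error: no sidecar and no $PhysicalNames to map tags")
  nidx <- sect("Nodes")
  n_decl <- suppressWarnings(as.integer(lines[nidx[1L]]))
  if (is.na(n_decl))
    stop("parse error: bad node count (line ", nidx[1L], ")")
  nrows <- nidx[-1L]
  if (length(nrows) != n_decl)
    stop("parse error: $Nodes declares ", n_decl, " nodes but has ",
         length(nrows), " rows (line ", nidx[1L], ")")
  nm <- matrix(suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[nrows]), "\\s+")))),
    ncol = 4L, byrow = TRUE)
  if (anyNA(nm)) stop("parse error: non-numeric node row near line ",
                      nrows[which(apply(is.na(nm), 1L, any))[1L]])
  nodes <- nm[order(nm[, 1L]), 2:4, drop = FALSE]
  eidx <- sect("Elements")
  e_decl <- suppressWarnings(as.integer(lines[eidx[1L]]))
  erows <- eidx[-1L]
  if (is.na(e_decl) || length(erows) != e_decl)
    stop("parse error: $Elements count mismatch (line ", eidx[1L], ")")
  toks <- strsplit(trimws(lines[erows]), "\\s+")
  keep <- vapply(toks, function(t) t[2L] == "4", logical(1))
  toks <- toks[keep]
  if (!length(toks)) stop("parse error: no tetrahedral elements")
  em <- t(vapply(toks, function(t) {
    ntags <- as.integer(t[3L])
    v <- suppressWarnings(as.integer(t[c(4L, (4L + ntags):(7L + ntags))]))
    v
  }, integer(5L)))
  phys <- em[, 1L]
  unknown <- setdiff(unique(phys), as.integer(names(tag2tissue)))
  if (length(unknown))
    stop("labeling error: unmapped physical tag(s): ",
         paste(unknown, collapse = ", "))
  tissue <- unname(tag2tissue[as.character(phys)])
  node_sets <- list()
  edge <- NA_real_
  if (!is.null(sidecar) && file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$node_sets))
      node_sets <- lapply(sc$node_sets, as.integer)
    if (!is.null(sc$edge_length) && length(sc$edge_length))
      edge <- as.numeric(sc$edge_length)
  }
  tet_mesh(nodes, em[, 2:5, drop = FALSE], tissue, node_sets,
           edge_length = edge)
}

#' Export per-element field magnitudes as CSV
#'
#' One row per element: id, tissue, centroid coordinates (mm) and |E|
#' (V/m).
#'
#' @param mesh the mesh the solution lives on.
#' @param sol a `field_solution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(mesh, sol, path) {
  cen <- tet_centroids(mesh)
  utils::write.csv(data.frame(
    element = seq_len(nrow(mesh$elements)), tissue = mesh$tissue,
    x_mm = cen[, 1L], y_mm = cen[, 2L], z_mm = cen[, 3L],
    E_Vm = sol$magnitude), path, row.names = FALSE)
  invisible(path)
}
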