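#' Tetrahedral finite-element mesh
#'
#' Nodes (mm) plus linear tetrahedra; an optional triangulated surface may be
#' stored, otherwise the boundary faces of the tetrahedra (faces belonging to
#' exactly one tet) act as the surface. Tetrahedra are reoriented to positive
#' signed volume on construction.
#'
#' @param nodes N x 3 numeric matrix (mm).
#' @param tets M x 4 integer matrix of 1-based node indices.
#' @param surface optional K x 3 integer matrix of surface triangles.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, surface = NULL) {
  nodes <- unname(as.matrix(nodes))
  tets <- unname(as.matrix(tets))
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("tet_mesh: nodes must be N x 3")
  if (ncol(tets) != 4L) stop("tet_mesh: tets must be M x 4")
  if (min(tets) < 1L || max(tets) > nrow(nodes))
    stop("tet_mesh: tet indices out of range")
  vol6 <- tet_signed_volumes(nodes, tets)
  flip <- vol6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (!is.null(surface)) {
    surface <- unname(as.matrix(surface))
    storage.mode(surface) <- "integer"
    if (ncol(surface) != 3L) stop("tet_mesh: surface must be K x 3")
    if (min(surface) < 1L || max(surface) > nrow(nodes))
      stop("tet_mesh: surface indices out of range")
  }
  structure(list(nodes = nodes, tets = tets, surface = surface),
            class = "tet_mesh")
}

tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
    b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
    b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets%s\n", nrow(x$nodes), nrow(x$tets),
              if (is.null(x$surface)) "" else
                sprintf(", %d surface triangles", nrow(x$surface))))
  invisible(x)
}

#' Boundary faces of a tetrahedral mesh
#'
#' Faces that belong to exactly one tetrahedron. Used as the mesh surface
#' when no explicit surface triangulation is stored.
#'
#' @param mesh a [tet_mesh()].
#' @return K x 3 integer matrix of triangles (1-based node indices).
#' @export
boundary_faces <- function(mesh) {
  t <- mesh$tets
  faces <- rbind(t[, c(1, 2, 3)], t[, c(1, 2, 4)],
                 t[, c(1, 3, 4)], t[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

mesh_surface <- function(mesh) {
  if (!is.null(mesh$surface)) mesh$surface else boundary_faces(mesh)
}

surface_node_ids <- function(mesh) sort(unique(as.vector(mesh_surface(mesh))))

#' Warp a mesh through a transform
#'
#' Node positions are replaced by `T(node)`; connectivity is untouched
#' (topology preservation — the internal structure of the reference mesh is
#' what the morphing is meant to carry over).
#'
#' @param mesh a [tet_mesh()].
#' @param transform an [ffd_transform()], [affine_transform()] or function.
#' @return the warped [tet_mesh()].
#' @export
warp_mesh <- function(mesh, transform) {
  nodes <- tryCatch(
    transform_points(transform, mesh$nodes),
    error = function(e) stop("warp_mesh: ", conditionMessage(e), call. = FALSE))
  out <- mesh
  out$nodes <- nodes
  out
}

#' Mean point-to-surface distance (accuracy, mm)
#'
#' Mean over the evaluation points of the exact minimum point-to-triangle
#' distance over all surface triangles of the mesh. This is the accuracy
#' measure for the soft-tissue-based prediction: evaluation points sit on the
#' actual organ surface, the mesh is the prediction.
#'
#' @param points K x 3 matrix of evaluation points (mm).
#' @param mesh a [tet_mesh()] with a surface (stored or extracted boundary).
#' @return scalar mean distance (mm), with attribute `distances` (per-point).
#' @export
point_to_surface_accuracy <- function(points, mesh) {
  points <- as_point_matrix(points)
  tri <- mesh_surface(mesh)
  if (is.null(tri) || nrow(tri) == 0L)
    stop("point_to_surface_accuracy: mesh has no surface")
  d <- cpp_point_surface_dist(points,
                              mesh$nodes[tri[, 1], , drop = FALSE],
                              mesh$nodes[tri[, 2], , drop = FALSE],
                              mesh$nodes[tri[, 3], , drop = FALSE])
  out <- mean(d)
  attr(out, "distances") <- as.numeric(d)
  out
}

#' Mean node-to-node surface distance between two same-topology meshes
#'
#' Both meshes must derive from the same reference mesh (identical node count
#' and ordering). The mean is over surface nodes (nodes referenced by surface
#' triangles); the per-node distance field is returned for color-coded
#' visualization.
#'
#' @param a,b [tet_mesh()]es with identical topology.
#' @return scalar mean distance (mm) with attributes `distances` (per surface
#'   node) and `nodes` (their indices).
#' @export
node_to_node_accuracy <- function(a, b) {
  if (nrow(a$nodes) != nrow(b$nodes) ||
      nrow(a$tets) != nrow(b$tets) ||
      !identical(a$tets, b$tets))
    stop("node_to_node_accuracy: meshes do not share topology")
  ids <- surface_node_ids(a)
  d <- sqrt(rowSums((a$nodes[ids, , drop = FALSE] -
                     b$nodes[ids, , drop = FALSE])^2))
  out <- mean(d)
  attr(out, "distances") <- d
  attr(out, "nodes") <- ids
  out
}

#' J10%: mean of the lowest 10% Jacobian determinants inside the organ
#'
#' Evaluates the Jacobian determinant of the transform at every voxel center
#' of the organ mask, sorts ascending, and averages the first
#' `ceiling(0.10 n)` values. A worst-case compression/folding summary of mesh
#' quality; 1 means locally isochoric, values near or below 0 flag severe
#' distortion or folding.
#'
#' @param transform an [ffd_transform()].
#' @param organ_mask a non-empty [mask_volume()] inside the lattice support.
#' @return scalar J10%.
#' @export
j10 <- function(transform, organ_mask) {
  pts <- domain_points(organ_mask)
  if (nrow(pts) == 0L) stop("j10: empty organ mask")
  j <- sort(jacobian_det(transform, pts))
  k <- ceiling(0.10 * length(j))
  mean(j[seq_len(k)])
}

#' Prediction score combining accuracy and mesh quality
#'
#' `score = accuracy * (J10% - 1)^2`. A perfect isochoric transform
#' (J10% = 1) scores 0 for any accuracy; the prediction with the lowest score
#' is selected as best.
#'
#' @param accuracy mean surface accuracy (mm), >= 0.
#' @param j10 the J10% quality measure.
#' @return the scalar score.
#' @export
prediction_score <- function(accuracy, j10) {
  if (any(accuracy < 0)) stop("prediction_score: accuracy must be >= 0")
  accuracy * (j10 - 1)^2
}

#' Select the best prediction from a candidate table
#'
#' Orders candidates by [prediction_score()], breaking ties by larger J10%
#' (prefer the better-conditioned mesh), then by smaller grid spacing
#' `lambda1` if present, then by row order. Returns the winning row index.
#'
#' @param candidates data frame with columns `accuracy`, `j10`, and
#'   optionally `lambda1`.
#' @return integer row index of the best candidate, with the score vector as
#'   attribute `score`.
#' @export
select_best_prediction <- function(candidates) {
  if (!all(c("accuracy", "j10") %in% names(candidates)))
    stop("select_best_prediction: need columns accuracy and j10")
  sc <- prediction_score(candidates$accuracy, candidates$j10)
  l1 <- if ("lambda1" %in% names(candidates)) candidates$lambda1
        else rep(0, nrow(candidates))
  ord <- order(sc, -candidates$j10, l1)
  out <- ord[1]
  attr(out, "score") <- sc
  out
}

# ---------------------------------------------------------------------------
# Structured tetrahedral meshing of an ellipsoid (phantom organ)

#' Structured tetrahedral mesh of an ellipsoid
#'
#' Builds a regular grid of step `h` over the ellipsoid's bounding box and
#' splits every fully inside cube into 6 tetrahedra. The boundary is
#' staircase-like at the scale of `h`; intended for synthetic phantoms, not
#' anatomical meshing.
#'
#' @param center 3-vector (mm).
#' @param radii 3-vector of semi-axes (mm).
#' @param h grid step (mm).
#' @return a [tet_mesh()].
#' @export
tet_mesh_ellipsoid <- function(center, radii, h) {
  lo <- center - radii; hi <- center + radii
  nx <- ceiling((hi - lo) / h) + 1L
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(nx[a]) - 1) * h)
  inside <- function(p) sum(((p - center) / radii)^2) <= 1
  node_id <- array(0L, nx)
  nodes <- list(); tets <- list()
  nid <- function(i, j, k) {
    if (node_id[i, j, k] == 0L) {
      nodes[[length(nodes) + 1L]] <<- c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
      node_id[i, j, k] <<- length(nodes)
    }
    node_id[i, j, k]
  }
  # 6-tet decomposition of the unit cube around the main diagonal
  tet_local <- rbind(c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
                     c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L))
  corner <- function(v) c(bitwAnd(v, 1L), bitwAnd(v, 2L) %/% 2L,
                          bitwAnd(v, 4L) %/% 4L)
  for (k in seq_len(nx[3] - 1L)) for (j in seq_len(nx[2] - 1L))
    for (i in seq_len(nx[1] - 1L)) {
      ok <- TRUE
      for (v in 0:7) {
        o <- corner(v)
        if (!inside(c(ax[[1]][i + o[1]], ax[[2]][j + o[2]], ax[[3]][k + o[3]]))) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      ids <- vapply(0:7, function(v) {
        o <- corner(v)
        nid(i + o[1], j + o[2], k + o[3])
      }, integer(1))
      for (r in seq_len(6)) tets[[length(tets) + 1L]] <- ids[tet_local[r, ] + 1L]
    }
  if (length(tets) == 0L)
    stop("tet_mesh_ellipsoid: grid step too coarse for the ellipsoid")
  tet_mesh(do.call(rbind, nodes), do.call(rbind, tets))
}

# ---------------------------------------------------------------------------
# Mesh I/O: Gmsh MSH 2.2 ASCII, legacy VTK ASCII, ASCII STL for surfaces

#' Read a tetrahedral mesh (Gmsh MSH 2.2 or legacy VTK)
#' @param path file path (`.msh` or `.vtk`).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path) {
  if (grepl("\\.msh$", path)) read_msh(path)
  else if (grepl("\\.vtk$", path)) read_vtk(path)
  else stop("read_mesh: unsupported extension: ", path)
}

#' Write a tetrahedral mesh (Gmsh MSH 2.2 or legacy VTK)
#'
#' For VTK, named per-node scalar fields can be attached as POINT_DATA
#' arrays (e.g. a node-to-node distance field for color-coded display).
#'
#' @param mesh a [tet_mesh()].
#' @param path output path (`.msh` or `.vtk`).
#' @param point_data named list of numeric per-node vectors (VTK only).
#' @export
write_mesh <- function(mesh, path, point_data = NULL) {
  if (grepl("\\.msh$", path)) write_msh(mesh, path)
  else if (grepl("\\.vtk$", path)) write_vtk(mesh, path, point_data)
  else stop("write_mesh: unsupported extension: ", path)
  invisible(path)
}

write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  surf <- mesh$surface
  nelem <- nrow(mesh$tets) + if (is.null(surf)) 0L else nrow(surf)
  writeLines(c("$EndNodes", "$Elements", as.character(nelem)), con)
  eid <- 0L
  if (!is.null(surf)) {
    writeLines(sprintf("%d 2 2 0 1 %d %d %d", seq_len(nrow(surf)),
                       surf[, 1], surf[, 2], surf[, 3]), con)
    eid <- nrow(surf)
  }
  writeLines(sprintf("%d 4 2 0 1 %d %d %d %d", eid + seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("read_msh: missing section ", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  nd <- utils::read.table(text = nl[2:(nn + 1L)])
  nodes <- as.matrix(nd[order(nd[[1]]), 2:4])
  el <- sec("Elements")
  ne <- as.integer(el[1])
  tets <- list(); tris <- list()
  for (ln in el[seq_len(ne) + 1L]) {
    f <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    type <- f[2]; ntags <- f[3]
    conn <- f[(4L + ntags):length(f)]
    if (type == 4L) tets[[length(tets) + 1L]] <- conn
    else if (type == 2L) tris[[length(tris) + 1L]] <- conn
  }
  if (length(tets) == 0L) stop("read_msh: no tetrahedra in ", path)
  tet_mesh(nodes, do.call(rbind, tets),
           surface = if (length(tris)) do.call(rbind, tris) else NULL)
}

write_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "tonguemorph tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      stopifnot(length(point_data[[nm]]) == n)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.17g", point_data[[nm]])), con)
    }
  }
}

read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)[1]
  if (is.na(ip)) stop("read_vtk: no POINTS section")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  coords <- scan(text = paste(lines[(ip + 1L):length(lines)][
    seq_len(ceiling(n))], collapse = " "), quiet = TRUE, n = 3L * n)
  nodes <- matrix(coords, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS ", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- utils::read.table(text = lines[(ic + 1L):(ic + m)])
  if (!all(cells[[1]] == 4L)) stop("read_vtk: only tetrahedral cells supported")
  tet_mesh(nodes, as.matrix(cells[, 2:5]) + 1L)
}

#' Write a triangulated surface as ASCII STL
#' @param nodes N x 3 vertex matrix (mm).
#' @param triangles K x 3 matrix of 1-based vertex indices.
#' @param path output path.
#' @export
write_stl <- function(nodes, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  for (f in seq_len(nrow(triangles))) {
    a <- nodes[triangles[f, 1], ]; b <- nodes[triangles[f, 2], ]
    c_ <- nodes[triangles[f, 3], ]
    u <- b - a; v <- c_ - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
                 sprintf("      vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
                 sprintf("      vertex %.17g %.17g %.17g", c_[1], c_[2], c_[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid surface", con)
  invisible(path)
}

#' Read an ASCII STL surface
#' @param path STL file path.
#' @return list with `nodes` (N x 3) and `triangles` (K x 3, 1-based),
#'   vertices deduplicated exactly.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  coords <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                            `[`, 2:4))), ncol = 3, byrow = TRUE)
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  nodes <- coords[uk, , drop = FALSE]
  id <- match(key, key[uk])
  triangles <- matrix(id, ncol = 3, byrow = TRUE)
  list(nodes = nodes, triangles = triangles)
}
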