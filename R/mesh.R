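# Local node offsets of a hexahedron in VTK ordering.
.HEX_OFFSETS <- cbind(
  dx = c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
  dy = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
  dz = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

# The 12 edges of a hexahedron as pairs of local node indices (VTK order).
.HEX_EDGES <- cbind(
  a = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L),
  b = c(2L, 3L, 4L, 1L, 6L, 7L, 8L, 5L, 5L, 6L, 7L, 8L))

#' Build a voxel-conforming hexahedral mesh
#'
#' Creates one 8-node cubic element per true voxel of the mask, centred at
#' the voxel location, with shared vertices of neighbouring voxels
#' deduplicated so connectivity follows common faces, edges and corners.
#' Each element carries 8 vertices and 12 edges; the number of unique edges
#' over the whole mesh is recorded. Node numbering is deterministic
#' (x fastest, then y, then z on the vertex lattice), so identical input
#' yields identical connectivity.
#'
#' Disconnected voxel components are retained with a warning; components not
#' anchored to the bottom face make the stiffness matrix singular during a
#' solve and surface there as an anchoring error.
#'
#' @param mask logical 3D array; TRUE voxels are meshed.
#' @param spacing voxel spacing in micrometres (node coordinates come out in
#'   mm).
#' @param warnDisconnected check 6-connectivity of the meshed voxels
#'   (disabled for large masks by passing FALSE).
#' @return A \linkS4class{HexMesh}.
#' @examples
#' m <- buildHexMesh(array(TRUE, c(1, 1, 1)), 150)
#' nNodes(m); edgeCount(m)  # 8 and 12
#' @export
buildHexMesh <- function(mask, spacing, warnDisconnected = TRUE) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) .stopf("mesh error: empty mask")
  if (spacing <= 0) .stopf("mesh error: spacing must be > 0")
  d <- dim(mask)
  nd <- d + 1L                       # vertex lattice dims
  vox <- which(mask)                 # linear voxel indices, x fastest
  ijk <- arrayInd(vox, d)            # 1-based voxel indices

  # vertex lattice key (1-based, x fastest) for each element corner
  keyOf <- function(i, j, k) i + (j - 1L) * nd[1] + (k - 1L) * nd[1] * nd[2]
  corner <- matrix(0L, nrow = length(vox), ncol = 8L)
  for (a in seq_len(8L)) {
    corner[, a] <- keyOf(ijk[, 1] + .HEX_OFFSETS[a, 1],
                         ijk[, 2] + .HEX_OFFSETS[a, 2],
                         ijk[, 3] + .HEX_OFFSETS[a, 3])
  }
  keys <- sort(unique(as.vector(corner)))
  renum <- integer(prod(nd))
  renum[keys] <- seq_along(keys)
  elements <- matrix(renum[corner], ncol = 8L)

  nodeIJK <- arrayInd(keys, nd) - 1L            # 0-based lattice indices
  h <- spacing / 1000                            # mm
  nodeCoords <- nodeIJK * h

  # unique edges: encode node pairs (min,max) as doubles
  nNode <- length(keys)
  ea <- elements[, .HEX_EDGES[, 1]]
  eb <- elements[, .HEX_EDGES[, 2]]
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  nEdge <- length(unique(as.numeric(lo) * (nNode + 1) + as.numeric(hi)))

  if (warnDisconnected && length(vox) <= 250000L) {
    comp <- .labelComponents(mask, connectivity = 6L)
    if (max(comp, na.rm = TRUE) > 1L)
      warning("mesh has ", max(comp, na.rm = TRUE),
              " disconnected voxel components; components not anchored to ",
              "the bottom surface will make the stiffness matrix singular")
  }

  new("HexMesh", nodeCoords = nodeCoords, nodeIJK = nodeIJK,
      elements = elements, elementToVoxel = as.integer(vox),
      gridDim = as.integer(d), spacing = as.numeric(spacing),
      edgeCount = as.numeric(nEdge))
}

#' Boundary node sets of a mesh
#'
#' Returns the node sets on the minimal ("bottom") and maximal ("top")
#' lattice layer along the requested axis. Loading always uses the axial
#' (z) faces: shear load cases change the displacement direction applied to
#' the top set, not the loaded faces.
#'
#' @param mesh a \linkS4class{HexMesh}.
#' @param axis "x", "y" or "z" (default).
#' @return list with integer node index vectors \code{top} and \code{bottom}.
#' @export
boundaryNodeSets <- function(mesh, axis = "z") {
  stopifnot(is(mesh, "HexMesh"))
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  v <- mesh@nodeIJK[, ax]
  lo <- min(v); hi <- max(v)
  if (hi - lo < 2L)
    .stopf("boundary error: mesh is a single element layer along %s; a valid load case needs >= 2 layers",
           axis)
  list(top = which(v == hi), bottom = which(v == lo))
}

#' Export a mesh to legacy VTK unstructured-grid format
#'
#' Writes an ASCII legacy \code{.vtk} file with hexahedron cells (type 12),
#' optionally attaching per-element scalar fields for inspection.
#'
#' @param mesh a \linkS4class{HexMesh}.
#' @param file output path.
#' @param cellData optional named list of per-element numeric vectors.
#' @return the file path, invisibly.
#' @export
exportMeshVTK <- function(mesh, file, cellData = list()) {
  stopifnot(is(mesh, "HexMesh"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tbfe voxel mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  n <- nNodes(mesh); ne <- nElements(mesh)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(mesh@nodeCoords, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  writeLines(apply(cbind(8L, mesh@elements - 1L), 1, paste, collapse = " "),
             con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (length(cellData)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cellData)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cellData[[nm]], digits = 10), con)
    }
  }
  invisible(file)
}

# Closed-form counts for a full nx x ny x nz cuboid (used in tests and docs):
# nodes = prod(n+1); elements = prod(n);
# edges = sum over axes of n_i * prod_{j != i} (n_j + 1).
#' @rdname buildHexMesh
#' @param n integer vector of 3 cuboid element counts.
#' @export
cuboidMeshCounts <- function(n) {
  n <- rep(as.numeric(n), length.out = 3L)
  list(nodes = prod(n + 1), elements = prod(n),
       edges = n[1] * (n[2] + 1) * (n[3] + 1) +
               n[2] * (n[1] + 1) * (n[3] + 1) +
               n[3] * (n[1] + 1) * (n[2] + 1))
}
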