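#' Triangle mesh
#'
#' Construct a triangulated surface mesh. The mesh is stored as an `n x 3`
#' matrix of vertex positions (mm) and an `m x 3` integer matrix of vertex
#' index triples with consistent (outward) winding. Per-vertex region labels
#' are optional. Derived quantities (edge table, triangle areas and normals,
#' area-weighted vertex normals) are computed on demand by the accessors
#' below.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices, counter-clockwise when seen from outside.
#' @param labels optional integer vector of per-vertex region labels.
#' @param validate check structural invariants (each triangle references
#'   three distinct existing vertices)?
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  if (ncol(triangles) != 3L) stop("'triangles' must have 3 columns")
  if (validate) {
    if (nrow(triangles) > 0) {
      if (min(triangles) < 1L || max(triangles) > nrow(vertices))
        stop("triangle indices out of range")
      dup <- triangles[, 1] == triangles[, 2] | triangles[, 2] == triangles[, 3] |
        triangles[, 1] == triangles[, 3]
      if (any(dup)) stop("degenerate triangle with repeated vertex")
    }
    if (!is.null(labels) && length(labels) != nrow(vertices))
      stop("'labels' must have one entry per vertex")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 labels = if (!is.null(labels)) as.integer(labels)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  e <- mesh_edges(x)
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, %d edges\n",
              nrow(x$vertices), nrow(x$triangles), nrow(e)))
  cat(sprintf("  Euler characteristic: %d; surface area: %.4g mm^2\n",
              nrow(x$vertices) - nrow(e) + nrow(x$triangles), mesh_area(x)))
  if (!is.null(x$labels))
    cat(sprintf("  region labels: %d regions\n", length(unique(x$labels))))
  invisible(x)
}

#' Undirected edge table of a mesh
#'
#' Each undirected edge appears exactly once, as a row `(i, j)` with `i < j`.
#'
#' @param mesh a [triangle_mesh()].
#' @return two-column integer matrix.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(matrix(integer(), 0, 2))
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  # numeric key is much faster than unique() on a matrix
  key <- (e[, 1] - 1) * (max(e[, 2]) + 1) + e[, 2]
  e[!duplicated(key), , drop = FALSE]
}

# per-edge count of adjacent triangles, aligned with mesh_edges(); 2 on a
# closed manifold, 1 on a boundary edge, >2 where non-manifold
edge_face_count <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  ed <- mesh_edges(mesh)
  as.integer(tab[paste(ed[, 1], ed[, 2])])
}

#' Triangle areas
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of areas (mm^2), one per triangle.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Unit triangle normals
#' @param mesh a [triangle_mesh()].
#' @return numeric matrix, one unit normal per triangle (winding order).
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- sqrt(rowSums(cr^2))
  if (any(n == 0)) stop("zero-area triangle")
  cr / n
}

#' Total surface area
#' @param mesh a [triangle_mesh()].
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Area-weighted vertex normals
#'
#' The normal at a vertex is the normalized area-weighted mean of the unit
#' normals of its adjacent triangles.
#'
#' @param mesh a [triangle_mesh()].
#' @param vertex_index optional subset of vertices; default all.
#' @return matrix of unit normals (rows align with `vertex_index`).
#' @export
vertex_normals <- function(mesh, vertex_index = NULL) {
  tn <- triangle_normals(mesh)
  ar <- triangle_areas(mesh)
  w <- tn * ar
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3)
  tr <- mesh$triangles
  for (c_ in 1:3) {
    acc[, 1] <- acc[, 1] + unname(rowsum_safe(w[, 1], tr[, c_], n))
    acc[, 2] <- acc[, 2] + unname(rowsum_safe(w[, 2], tr[, c_], n))
    acc[, 3] <- acc[, 3] + unname(rowsum_safe(w[, 3], tr[, c_], n))
  }
  len <- sqrt(rowSums(acc^2))
  if (is.null(vertex_index)) vertex_index <- seq_len(n)
  if (any(len[vertex_index] == 0)) {
    deg <- tabulate(tr, n)
    bad <- vertex_index[deg[vertex_index] == 0]
    if (length(bad))
      stop("isolated vertex (degenerate topology): ", paste(bad, collapse = ", "))
    stop("vertex normal of zero length")
  }
  (acc / len)[vertex_index, , drop = FALSE]
}

# sum 'x' by integer group 'g' into a length-n vector (zeros where absent)
rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Euler characteristic V - E + F
#' @param mesh a [triangle_mesh()].
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

#' Vertex areas (one third of adjacent triangle areas)
#'
#' Barycentric lumping of triangle area onto vertices; sums to the total
#' surface area.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector, mm^2 per vertex.
#' @export
vertex_areas <- function(mesh) {
  ar <- triangle_areas(mesh) / 3
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  for (c_ in 1:3) out <- out + rowsum_safe(ar, mesh$triangles[, c_], n)
  out
}
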