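#' Pruning configuration
#'
#' @param min_edge_length collapse edges shorter than this (mm).
#' @param b curvature factor in \[0, 1\]: position of the new vertex between
#'   the edge midpoint (`b = 0`, exact for a plane) and the circle-segment
#'   point reconstructing local curvature (`b = 1`, exact for a sphere).
#' @param l lift factor in \[0, 1) for tetrahedron removal: base vertices are
#'   moved towards the former peak by this fraction.
#' @return a `prune_config` list.
#' @export
prune_config <- function(min_edge_length = 2.5, b = 1, l = 0) {
  if (min_edge_length <= 0) stop("'min_edge_length' must be > 0")
  if (b < 0 || b > 1) stop("'b' must be in [0, 1]")
  if (l < 0 || l >= 1) stop("'l' must be in [0, 1)")
  structure(list(min_edge_length = min_edge_length, b = b, l = l),
            class = "prune_config")
}

# position of the merged vertex for an edge collapse: circle-segment
# construction from endpoint normals; falls back to the midpoint when the
# projected normals are (near-)parallel, which is the exact planar answer
collapse_position <- function(p1, p2, n1, n2, b) {
  p0 <- (p1 + p2) / 2
  if (b == 0) return(p0)
  n0 <- n1 + n2
  nn0 <- sqrt(sum(n0^2))
  if (nn0 < 1e-12) return(p0)          # opposing normals: degenerate fold
  n0 <- n0 / nn0
  u <- p1 - p2
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(p0)
  u <- u / nu
  # orthonormal in-plane basis of the plane through p0 spanned by n0 and u
  e1 <- u
  e2 <- n0 - sum(n0 * e1) * e1
  ne2 <- sqrt(sum(e2^2))
  if (ne2 < 1e-12) return(p0)          # n0 parallel to the edge
  e2 <- e2 / ne2
  proj2 <- function(x) c(sum(x * e1), sum(x * e2))
  # project the endpoint normals into the plane
  m1 <- proj2(n1); m2 <- proj2(n2)
  if (sqrt(sum(m1^2)) < 1e-12 || sqrt(sum(m2^2)) < 1e-12) return(p0)
  q1 <- proj2(p1 - p0); q2 <- proj2(p2 - p0)
  # intersect the 2D lines q1 + t m1 and q2 + s m2
  A <- cbind(m1, -m2)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-10 * sqrt(sum(m1^2)) * sqrt(sum(m2^2))) return(p0)
  ts <- solve(A, q2 - q1)
  cpt <- q1 + ts[1] * m1
  d3 <- (sqrt(sum((cpt - q1)^2)) + sqrt(sum((cpt - q2)^2))) / 2
  # p0 is the in-plane origin; step from c towards p0 by distance d3
  dir <- -cpt
  ndir <- sqrt(sum(dir^2))
  if (ndir < 1e-12) return(p0)
  q3 <- cpt + dir / ndir * d3
  p3 <- p0 + q3[1] * e1 + q3[2] * e2
  p0 + b * (p3 - p0)
}

#' Collapse one edge of a mesh
#'
#' Removes the two triangles sharing the edge and merges its endpoints into a
#' single new vertex placed on a circle segment approximating the local
#' surface (see [prune_config()] for `b`). Vertex count decreases by 1,
#' triangle count by 2.
#'
#' @param mesh a [triangle_mesh()].
#' @param edge integer vector `c(i, j)` of the edge's vertex indices.
#' @param b curvature factor in \[0, 1\].
#' @return the collapsed [triangle_mesh()]; the new vertex takes the index
#'   slot of `min(edge)` (indices above `max(edge)` shift down by one).
#' @export
collapse_edge <- function(mesh, edge, b = 1) {
  i <- min(edge); j <- max(edge)
  tr <- mesh$triangles
  has_i <- tr[, 1] == i | tr[, 2] == i | tr[, 3] == i
  has_j <- tr[, 1] == j | tr[, 2] == j | tr[, 3] == j
  shared <- which(has_i & has_j)
  if (length(shared) == 0) stop("edge does not exist")
  if (length(shared) != 2) stop("non-manifold edge (", length(shared), " adjacent triangles)")
  nrm <- rbind(local_vertex_normal(mesh, which(has_i)),
               local_vertex_normal(mesh, which(has_j)))
  v_new <- collapse_position(mesh$vertices[i, ], mesh$vertices[j, ],
                             nrm[1, ], nrm[2, ], b)
  tr <- tr[-shared, , drop = FALSE]
  tr[tr == j] <- i
  verts <- mesh$vertices
  verts[i, ] <- v_new
  verts <- verts[-j, , drop = FALSE]
  tr[tr > j] <- tr[tr > j] - 1L
  lab <- mesh$labels
  if (!is.null(lab)) lab <- lab[-j]
  out <- triangle_mesh(verts, tr, labels = lab, validate = FALSE)
  hemi <- attr(mesh, "hemisphere")
  if (!is.null(hemi)) attr(out, "hemisphere") <- hemi[-j]
  out
}

# area-weighted normal over the given triangle rows (those adjacent to one
# vertex); avoids recomputing normals for the whole mesh during pruning
local_vertex_normal <- function(mesh, rows) {
  v <- mesh$vertices
  tr <- mesh$triangles[rows, , drop = FALSE]
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  acc <- colSums(cr) / 2      # cross product length = 2 * area, direction = normal
  len <- sqrt(sum(acc^2))
  if (len == 0) stop("degenerate local normal")
  acc / len
}

# adjacency list: neighbours of each vertex
vertex_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  nb <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1]]] <- c(nb[[e[k, 1]]], e[k, 2])
    nb[[e[k, 2]]] <- c(nb[[e[k, 2]]], e[k, 1])
  }
  nb
}

#' Detect "tetrahedron" configurations
#'
#' A tetrahedron is a degree-3 vertex (the peak) whose three neighbours are
#' pairwise connected by mesh edges while the base triple itself is not a face
#' of the mesh (the base triangle is empty). Collapsing an edge of the empty
#' base would fold two triangles onto each other, so these configurations must
#' be removed first.
#'
#' @param mesh a [triangle_mesh()].
#' @return list of entries `list(peak =, base =)`; empty list if none.
#' @export
detect_tetrahedra <- function(mesh) {
  nb <- vertex_neighbors(mesh)
  deg <- lengths(nb)
  tr <- mesh$triangles
  face_key <- apply(tr, 1, function(t) paste(sort(t), collapse = " "))
  edge_env <- new.env(hash = TRUE)
  e <- mesh_edges(mesh)
  for (k in seq_len(nrow(e))) edge_env[[paste(e[k, 1], e[k, 2])]] <- TRUE
  has_edge <- function(a, b) !is.null(edge_env[[paste(min(a, b), max(a, b))]])
  out <- list()
  for (v in which(deg == 3)) {
    base <- sort(nb[[v]])
    if (has_edge(base[1], base[2]) && has_edge(base[2], base[3]) &&
        has_edge(base[1], base[3]) &&
        !(paste(base, collapse = " ") %in% face_key)) {
      out[[length(out) + 1L]] <- list(peak = v, base = base)
    }
  }
  out
}

#' Remove one tetrahedron configuration
#'
#' The peak vertex and its three triangles are removed and the (formerly
#' empty) base triangle becomes a face. For `l > 0` each base vertex is lifted
#' towards the former peak: `(1 - l) * base + l * peak`.
#'
#' @param mesh a [triangle_mesh()].
#' @param peak peak vertex index (degree 3).
#' @param base sorted integer vector of the three base vertex indices.
#' @param l lift factor in \[0, 1).
#' @return the reduced [triangle_mesh()] (V - 1 vertices, F - 2 triangles).
#' @export
remove_tetrahedron <- function(mesh, peak, base, l = 0) {
  tr <- mesh$triangles
  face_key <- apply(tr, 1, function(t) paste(sort(t), collapse = " "))
  if (paste(sort(base), collapse = " ") %in% face_key)
    stop("base is already a face (inconsistent detection)")
  has_peak <- tr[, 1] == peak | tr[, 2] == peak | tr[, 3] == peak
  if (sum(has_peak) != 3) stop("peak is not a degree-3 vertex")
  # orient the new base face like the removed peak faces: take one peak face
  # (a, b, peak) and replace peak by the remaining base vertex
  f1 <- tr[which(has_peak)[1], ]
  rest <- setdiff(base, f1)
  newface <- f1
  newface[newface == peak] <- rest
  tr <- rbind(tr[!has_peak, , drop = FALSE], newface)
  verts <- mesh$vertices
  if (l > 0) {
    for (bv in base)
      verts[bv, ] <- (1 - l) * verts[bv, ] + l * verts[peak, ]
  }
  verts <- verts[-peak, , drop = FALSE]
  tr[tr > peak] <- tr[tr > peak] - 1L
  lab <- mesh$labels
  if (!is.null(lab)) lab <- lab[-peak]
  out <- triangle_mesh(verts, tr, labels = lab, validate = FALSE)
  hemi <- attr(mesh, "hemisphere")
  if (!is.null(hemi)) attr(out, "hemisphere") <- hemi[-peak]
  out
}

# common neighbours of edge endpoints beyond the two triangle apexes make a
# collapse degenerate (duplicate faces); returns them (possibly empty)
extra_common_neighbors <- function(mesh, i, j) {
  tr <- mesh$triangles
  has_i <- tr[, 1] == i | tr[, 2] == i | tr[, 3] == i
  has_j <- tr[, 1] == j | tr[, 2] == j | tr[, 3] == j
  apexes <- setdiff(as.vector(tr[has_i & has_j, ]), c(i, j))
  nb <- function(v) {
    rows <- tr[tr[, 1] == v | tr[, 2] == v | tr[, 3] == v, , drop = FALSE]
    setdiff(unique(as.vector(rows)), v)
  }
  setdiff(intersect(nb(i), nb(j)), apexes)
}

#' Prune a mesh by repeated shortest-edge collapse
#'
#' In each iteration the globally shortest edge below the threshold is
#' collapsed (ties broken deterministically by lowest `(min index, max index)`
#' pair). Tetrahedron configurations whose empty base contains the candidate
#' edge are resolved first; collapses that would flip a triangle normal or
#' create a non-manifold configuration are rejected and the next-shortest edge
#' is taken. Stops when every edge is at least `min_edge_length` long.
#'
#' @param mesh a closed manifold [triangle_mesh()].
#' @param config a [prune_config()].
#' @param min_vertices abort if the mesh would shrink below this size.
#' @param verbose print a summary?
#' @return the pruned [triangle_mesh()], with attributes `prune_report`
#'   (vertex/triangle counts and relative surface-area change).
#' @export
prune_mesh <- function(mesh, config = prune_config(), min_vertices = 8,
                       verbose = FALSE) {
  area0 <- mesh_area(mesh)
  v0 <- nrow(mesh$vertices); f0 <- nrow(mesh$triangles)
  blocked <- character(0)
  repeat {
    if (nrow(mesh$vertices) < min_vertices)
      stop("mesh exhausted below ", min_vertices, " vertices")
    e <- mesh_edges(mesh)
    len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
    ord <- order(len, e[, 1], e[, 2])
    cand <- NULL
    for (k in ord) {
      if (len[k] >= config$min_edge_length) break
      key <- paste(e[k, 1], e[k, 2])
      if (!(key %in% blocked)) { cand <- e[k, ]; break }
    }
    if (is.null(cand)) break
    i <- cand[1]; j <- cand[2]
    extra <- extra_common_neighbors(mesh, i, j)
    if (length(extra)) {
      # resolve a tetrahedron whose empty base contains this edge, if any
      tets <- detect_tetrahedra(mesh)
      hit <- NULL
      for (tt in tets)
        if (all(c(i, j) %in% tt$base)) { hit <- tt; break }
      if (is.null(hit)) {
        blocked <- c(blocked, paste(i, j))   # non-tetrahedron non-manifold case
        next
      }
      mesh <- remove_tetrahedron(mesh, hit$peak, hit$base, config$l)
      blocked <- character(0)
      next
    }
    new_mesh <- tryCatch(collapse_edge(mesh, c(i, j), config$b),
                         error = function(e) e)
    if (inherits(new_mesh, "error")) {
      blocked <- c(blocked, paste(i, j))   # e.g. boundary edge of an open mesh
      next
    }
    if (collapse_flips_normal(mesh, new_mesh, i, j)) {
      blocked <- c(blocked, paste(i, j))
      next
    }
    mesh <- new_mesh
    blocked <- character(0)
  }
  report <- list(vertices = c(before = v0, after = nrow(mesh$vertices)),
                 triangles = c(before = f0, after = nrow(mesh$triangles)),
                 area_change = mesh_area(mesh) / area0 - 1)
  attr(mesh, "prune_report") <- report
  if (verbose)
    message(sprintf("pruned %d -> %d vertices, %d -> %d triangles, area change %+.2f%%",
                    v0, report$vertices["after"], f0, report$triangles["after"],
                    100 * report$area_change))
  mesh
}

# did collapsing edge (i, j) flip any retained triangle's normal?
collapse_flips_normal <- function(old, new, i, j) {
  tr <- old$triangles
  has_i <- tr[, 1] == i | tr[, 2] == i | tr[, 3] == i
  has_j <- tr[, 1] == j | tr[, 2] == j | tr[, 3] == j
  touched <- which((has_i | has_j) & !(has_i & has_j))
  if (!length(touched)) return(FALSE)
  vo <- old$vertices; to <- tr[touched, , drop = FALSE]
  ao <- vo[to[, 2], , drop = FALSE] - vo[to[, 1], , drop = FALSE]
  bo <- vo[to[, 3], , drop = FALSE] - vo[to[, 1], , drop = FALSE]
  old_n <- cbind(ao[, 2] * bo[, 3] - ao[, 3] * bo[, 2],
                 ao[, 3] * bo[, 1] - ao[, 1] * bo[, 3],
                 ao[, 1] * bo[, 2] - ao[, 2] * bo[, 1])
  # map old triangle rows to new rows: shared-face rows removed first
  removed <- which(has_i & has_j)
  new_rows <- touched - vapply(touched, function(t) sum(removed < t), 0L)
  vn <- new$vertices; tn <- new$triangles[new_rows, , drop = FALSE]
  a <- vn[tn[, 2], , drop = FALSE] - vn[tn[, 1], , drop = FALSE]
  b <- vn[tn[, 3], , drop = FALSE] - vn[tn[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  any(rowSums(cr * old_n) < 0)
}
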