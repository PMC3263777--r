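#' Edge graph of a mesh
#'
#' Undirected igraph whose edge weights are Euclidean edge lengths (mm).
#'
#' @param mesh a [triangle_mesh()].
#' @return an igraph object with `weight` edge attribute.
#' @export
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- len
  g
}

#' Geodesic (on-surface) distances up to a cut-off
#'
#' Graph distance over mesh edges (edge weight = Euclidean length) from every
#' vertex to all vertices within `cutoff`. Stored sparsely as a triplet table.
#' Distances between disconnected components are omitted (with a warning).
#'
#' @param mesh a [triangle_mesh()].
#' @param cutoff maximum distance retained (mm).
#' @return a `distance_table`: data.frame with columns `from`, `to`, `distance`
#'   containing each unordered pair once (`from < to`), plus attributes
#'   `n_vertices` and `cutoff`.
#' @export
geodesic_distances <- function(mesh, cutoff) {
  if (cutoff <= 0) stop("'cutoff' must be > 0")
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no > 1)
    warning("mesh has disconnected components; distances reported within components only")
  d <- igraph::distances(g, algorithm = "dijkstra")
  keep <- which(upper.tri(d) & is.finite(d) & d <= cutoff, arr.ind = TRUE)
  out <- data.frame(from = keep[, 1], to = keep[, 2],
                    distance = d[keep])
  attr(out, "n_vertices") <- nrow(mesh$vertices)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("distance_table", class(out))
  out
}

# dense symmetric matrix view of a distance_table (Inf where not stored)
distance_matrix <- function(dt, n = attr(dt, "n_vertices")) {
  m <- matrix(Inf, n, n)
  diag(m) <- 0
  m[cbind(dt$from, dt$to)] <- dt$distance
  m[cbind(dt$to, dt$from)] <- dt$distance
  m
}

#' Spherical-shell volume indicator
#'
#' Membership test for points inside a (possibly hollow) spherical shell;
#' the analytic stand-in for a cortical volume mask.
#'
#' @param center sphere centre (mm).
#' @param outer_radius outer radius (mm).
#' @param inner_radius inner radius (mm); 0 gives a solid ball.
#' @param tolerance boundary tolerance (mm) added outside/subtracted inside.
#' @return a function mapping an `n x 3` matrix of points to a logical vector.
#' @export
shell_indicator <- function(center, outer_radius, inner_radius = 0,
                            tolerance = 1e-6) {
  force(center); force(outer_radius); force(inner_radius); force(tolerance)
  function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    r <- sqrt(rowSums(sweep(points, 2, center)^2))
    r <= outer_radius + tolerance & r >= inner_radius - tolerance
  }
}

#' Union of volume indicators
#' @param ... indicator functions as returned by [shell_indicator()].
#' @return combined indicator function.
#' @export
union_indicator <- function(...) {
  parts <- list(...)
  function(points) {
    res <- Reduce(`|`, lapply(parts, function(f) f(points)))
    res
  }
}

#' Visibility graph of straight through-volume connections
#'
#' Builds the weighted graph whose edges are straight segments between point
#' pairs that lie completely inside the given volume (tested by uniform
#' sampling along the segment), plus the surface-mesh edges, which are always
#' included so that every pair of vertices is connected at least along the
#' surface.
#'
#' @param points `n x 3` matrix of vertex positions (mm), typically of a
#'   coarse route mesh.
#' @param volume membership function (see [shell_indicator()]).
#' @param surface_edges optional 2-column matrix of always-included edges.
#' @param step sampling step along segments (mm).
#' @return list with `edges` (2-column matrix), `weights` (Euclidean lengths)
#'   and `n` (number of points).
#' @export
visibility_graph <- function(points, volume, surface_edges = NULL, step = 0.5) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!all(volume(points))) stop("all points must lie inside the volume")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  seg_len <- sqrt(rowSums((points[pairs[, 1], , drop = FALSE] -
                           points[pairs[, 2], , drop = FALSE])^2))
  m <- pmax(1L, ceiling(seg_len / step))
  keep <- rep(TRUE, nrow(pairs))
  # vectorize the sampling over all pairs that need the same sample count
  for (mm in sort(unique(m))) {
    if (mm == 1L) next
    rows <- which(m == mm & keep)
    if (!length(rows)) next
    A <- points[pairs[rows, 1], , drop = FALSE]
    B <- points[pairs[rows, 2], , drop = FALSE]
    alive <- rep(TRUE, length(rows))
    for (j in seq_len(mm - 1L)) {
      t <- j / mm
      idx <- which(alive)
      if (!length(idx)) break
      P <- (1 - t) * A[idx, , drop = FALSE] + t * B[idx, , drop = FALSE]
      alive[idx] <- volume(P)
    }
    keep[rows] <- alive
  }
  edges <- pairs[keep, , drop = FALSE]
  if (!is.null(surface_edges)) {
    se <- cbind(pmin(surface_edges[, 1], surface_edges[, 2]),
                pmax(surface_edges[, 1], surface_edges[, 2]))
    key <- paste(edges[, 1], edges[, 2])
    add <- !(paste(se[, 1], se[, 2]) %in% key)
    edges <- rbind(edges, se[add, , drop = FALSE])
  }
  w <- sqrt(rowSums((points[edges[, 1], , drop = FALSE] -
                     points[edges[, 2], , drop = FALSE])^2))
  list(edges = unname(edges), weights = w, n = n)
}

# all sampled interior points of the open segment (a, b) inside the volume?
segment_inside <- function(a, b, volume, step) {
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(TRUE)
  m <- max(1L, ceiling(len / step))
  t <- seq_len(m - 1L) / m
  if (!length(t)) return(TRUE)
  pts <- outer(1 - t, a) + outer(t, b)
  all(volume(pts))
}

#' All-pairs shortest paths (Floyd-Warshall)
#'
#' Exact all-pairs shortest path distances on a weighted undirected graph with
#' non-negative weights; vectorized Floyd-Warshall. Disconnected pairs get
#' `Inf`.
#'
#' @param graph a list with `edges`, `weights`, `n` (see [visibility_graph()]),
#'   or a dense symmetric adjacency matrix with `Inf` for missing edges.
#' @param paths also reconstruct shortest routes (successor matrix)?
#' @return distance matrix; with `paths = TRUE` a list `list(distances, next_hop)`
#'   where routes can be read off with [reconstruct_path()].
#' @export
all_pairs_shortest_paths <- function(graph, paths = FALSE) {
  if (is.matrix(graph)) {
    d <- graph
    n <- nrow(d)
  } else {
    n <- graph$n
    d <- matrix(Inf, n, n)
    if (any(graph$weights < 0)) stop("negative edge weight")
    for (k in seq_along(graph$weights)) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      if (graph$weights[k] < d[i, j]) d[i, j] <- d[j, i] <- graph$weights[k]
    }
  }
  diag(d) <- 0
  nxt <- NULL
  if (paths) {
    nxt <- matrix(rep(seq_len(n), each = n), n, n)  # next hop = target if direct
    nxt[!is.finite(d)] <- NA_integer_
    diag(nxt) <- seq_len(n)
  }
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], `+`)
    if (paths) {
      better <- via < d
      if (any(better)) {
        idx <- which(better, arr.ind = TRUE)
        nxt[better] <- nxt[cbind(idx[, 1], k)]
      }
      d <- pmin(d, via)
    } else {
      d <- pmin(d, via)
    }
  }
  if (paths) list(distances = d, next_hop = nxt) else d
}

#' Reconstruct a shortest route from a Floyd-Warshall successor matrix
#' @param apsp result of `all_pairs_shortest_paths(..., paths = TRUE)`.
#' @param from,to vertex indices.
#' @return integer vector of vertex indices along the route.
#' @export
reconstruct_path <- function(apsp, from, to) {
  if (is.na(apsp$next_hop[from, to])) return(integer(0))
  path <- from
  while (from != to) {
    from <- apsp$next_hop[from, to]
    path <- c(path, from)
  }
  path
}

#' Match fine-mesh vertices to their nearest coarse-mesh vertices
#'
#' Euclidean nearest neighbour, ties broken by lowest index. Used to map the
#' NPM surface onto the coarse route mesh for delay lookup.
#'
#' @param fine_mesh,coarse_mesh meshes (or `n x 3` coordinate matrices) in the
#'   same frame.
#' @return integer vector: for each fine vertex the index of the nearest
#'   coarse vertex.
#' @export
match_vertices <- function(fine_mesh, coarse_mesh) {
  fv <- if (inherits(fine_mesh, "triangle_mesh")) fine_mesh$vertices else as.matrix(fine_mesh)
  cv <- if (inherits(coarse_mesh, "triangle_mesh")) coarse_mesh$vertices else as.matrix(coarse_mesh)
  cs <- rowSums(cv^2)
  out <- integer(nrow(fv))
  for (i in seq_len(nrow(fv))) {
    d2 <- cs - 2 * (cv %*% fv[i, ])
    out[i] <- which.min(d2)   # which.min takes the first (lowest index) tie
  }
  out
}

#' Through-volume route distances between mesh vertices
#'
#' Convenience chain for conduction-delay estimation: prune the surface to a
#' coarse route mesh, build the visibility graph of straight segments inside
#' the volume (surface edges always included), run all-pairs shortest paths,
#' and match the fine vertices to the coarse ones.
#'
#' @param mesh the (fine) NPM surface mesh.
#' @param volume membership function for the cortical volume.
#' @param coarse_mesh optional pre-pruned route mesh; default uses `mesh`.
#' @param step segment sampling step (mm).
#' @return list with `distances` (coarse matrix, mm), `match` (fine -> coarse
#'   index), `coarse_mesh`.
#' @export
route_distances <- function(mesh, volume, coarse_mesh = NULL, step = 0.5) {
  if (is.null(coarse_mesh)) coarse_mesh <- mesh
  vg <- visibility_graph(coarse_mesh$vertices, volume,
                         surface_edges = mesh_edges(coarse_mesh), step = step)
  d <- all_pairs_shortest_paths(vg)
  list(distances = d, match = match_vertices(mesh, coarse_mesh),
       coarse_mesh = coarse_mesh)
}
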