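# shared small fixtures and independent mini-oracles

# flat rectangular patch in the z = 0 plane, triangulated grid
flat_patch <- function(nx = 4, ny = 4, spacing = 1) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  verts <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1) * nx + i
  tris <- list()
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  triangle_mesh(verts, do.call(rbind, tris))
}

# replace one face of a closed mesh by a 3-face "tent", creating a
# tetrahedron configuration (apex of degree 3 over an empty base)
add_tetrahedron <- function(mesh, face_idx = 1, height = 0.3) {
  tr <- mesh$triangles
  f <- tr[face_idx, ]
  centroid <- colMeans(mesh$vertices[f, ])
  nrm <- triangle_normals(mesh)[face_idx, ]
  apex <- centroid + height * nrm
  verts <- rbind(mesh$vertices, apex)
  ai <- nrow(verts)
  newf <- rbind(c(f[1], f[2], ai), c(f[2], f[3], ai), c(f[3], f[1], ai))
  triangle_mesh(verts, rbind(tr[-face_idx, , drop = FALSE], newf))
}

# plain O(n^2) Dijkstra over an adjacency matrix (Inf = absent), one source
dijkstra_ref <- function(adj, source) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    relax <- which(is.finite(adj[u, ]))
    dist[relax] <- pmin(dist[relax], dist[u] + adj[u, relax])
  }
  dist
}

# dense adjacency matrix of a mesh's edge graph
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- matrix(Inf, n, n)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  adj[e] <- len
  adj[e[, c(2, 1)]] <- len
  diag(adj) <- 0
  adj
}

# the standard small-cortex fixture: two hemispheres, 3-region parcellation
# on the left hemisphere vertices (regions tiled over both hemispheres)
small_cortex <- function(subdivisions = 2, seed = 11) {
  hemis <- make_hemispheres(subdivisions = subdivisions)
  mesh <- merge_hemispheres(hemis)
  lab <- make_parcellation(mesh, n_regions = 3, seed = seed)
  mesh$labels <- lab
  mesh
}

# cortical volume of the two-hemisphere fixture (with the midline bridge)
hemis_volume <- function() hemispheres_volume()

# group-sum into a length-n vector (zeros where a group is absent)
rowsum_ref <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# session-cached fixtures for the heavier geometry (visibility-graph routes)
.fixture_cache <- new.env(parent = emptyenv())
cached_small_cortex <- function() {
  if (is.null(.fixture_cache$mesh)) .fixture_cache$mesh <- small_cortex(2, seed = 11)
  .fixture_cache$mesh
}
cached_routes <- function() {
  if (is.null(.fixture_cache$routes)) {
    .fixture_cache$routes <- route_distances(cached_small_cortex(),
                                             hemis_volume(), step = 1)
  }
  .fixture_cache$routes
}
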