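test_that("geodesic distances: adjacent vertices get exactly the edge length", {
  ico <- icosphere(2, radius = 10)
  gd <- geodesic_distances(ico, cutoff = 50)
  e <- mesh_edges(ico)
  len <- sqrt(rowSums((ico$vertices[e[, 1], ] - ico$vertices[e[, 2], ])^2))
  key <- paste(gd$from, gd$to)
  got <- gd$distance[match(paste(e[, 1], e[, 2]), key)]
  expect_equal(got, len)
})

test_that("geodesics approximate great-circle arcs on a sphere", {
  ico <- icosphere(3)  # unit sphere
  gd <- geodesic_distances(ico, cutoff = 10)
  v <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  arc <- acos(pmin(1, pmax(-1, rowSums(v[gd$from, ] * v[gd$to, ]))))
  far <- arc > 2.8   # antipodal-ish pairs; overshoot averages out over the path
  expect_gt(sum(far), 10)
  expect_lt(max(abs(gd$distance[far] - arc[far]) / arc[far]), 0.08)
  chord <- sqrt(rowSums((v[gd$from, ] - v[gd$to, ])^2))
  expect_true(all(gd$distance >= chord - 1e-9))  # graph path >= straight line
})

test_that("geodesics match a per-source Dijkstra oracle on random meshes", {
  set.seed(5)
  ico <- icosphere(2)
  ico$vertices <- ico$vertices * (1 + 0.2 * matrix(runif(length(ico$vertices)),
                                                   ncol = 3))
  gd <- geodesic_distances(ico, cutoff = 100)
  dm <- meshnpm:::distance_matrix(gd)
  adj <- mesh_adjacency(ico)
  for (s in c(1, 17, 101)) {
    expect_equal(dm[s, ], dijkstra_ref(adj, s), tolerance = 1e-12)
  }
})

test_that("visibility graph of a convex ball volume is complete", {
  pts <- icosphere(1, radius = 5)$vertices * 0.99
  vol <- shell_indicator(c(0, 0, 0), 5)
  vg <- visibility_graph(pts, vol)
  n <- nrow(pts)
  expect_equal(nrow(vg$edges), n * (n - 1) / 2)
})

test_that("hollow shell blocks chords through the core; sampling-step stable", {
  pts <- icosphere(1, radius = 5)$vertices
  vol <- shell_indicator(c(0, 0, 0), 5.01, inner_radius = 3)
  se <- mesh_edges(icosphere(1))
  vg1 <- visibility_graph(pts, vol, surface_edges = se, step = 0.5)
  key1 <- paste(vg1$edges[, 1], vg1$edges[, 2])
  # antipodal pair: the straight chord passes through the hollow core
  d <- as.matrix(dist(pts))
  anti <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_false(paste(min(anti), max(anti)) %in% key1)
  # surface edges always present
  expect_true(all(paste(pmin(se[, 1], se[, 2]), pmax(se[, 1], se[, 2])) %in% key1))
  vg2 <- visibility_graph(pts, vol, surface_edges = se, step = 0.1)
  key2 <- paste(vg2$edges[, 1], vg2$edges[, 2])
  expect_setequal(key1, key2)
})

test_that("Floyd-Warshall distances are exact, symmetric and zero-diagonal", {
  g <- list(edges = rbind(c(1, 2), c(2, 3)), weights = c(1, 2), n = 3)
  d <- all_pairs_shortest_paths(g)
  expect_equal(d[1, 3], 3)
  set.seed(9)
  n <- 60
  adj <- matrix(Inf, n, n)
  for (k in 1:300) {
    i <- sample(n, 1); j <- sample(n, 1)
    if (i != j) adj[i, j] <- adj[j, i] <- runif(1, 0.1, 2)
  }
  diag(adj) <- 0
  d <- all_pairs_shortest_paths(adj)
  expect_equal(diag(d), rep(0, n))
  expect_equal(d, t(d))
  # independent oracle: igraph Dijkstra
  ig <- igraph::graph_from_adjacency_matrix(
    ifelse(is.finite(adj), adj, 0), mode = "undirected", weighted = TRUE)
  expect_equal(unname(d), unname(igraph::distances(ig, algorithm = "dijkstra")),
               tolerance = 1e-12)
})

test_that("Floyd-Warshall is equivariant under node relabelling", {
  set.seed(2)
  n <- 20
  adj <- matrix(runif(n * n, 0.5, 3), n, n)
  adj[upper.tri(adj)] <- t(adj)[upper.tri(adj)]
  diag(adj) <- 0
  d <- all_pairs_shortest_paths(adj)
  perm <- sample(n)
  d2 <- all_pairs_shortest_paths(adj[perm, perm])
  expect_equal(d2, d[perm, perm])
})

test_that("route reconstruction follows finite shortest paths", {
  g <- list(edges = rbind(c(1, 2), c(2, 3), c(1, 3)), weights = c(1, 1, 5), n = 4)
  r <- all_pairs_shortest_paths(g, paths = TRUE)
  expect_equal(reconstruct_path(r, 1, 3), c(1, 2, 3))
  expect_equal(r$distances[1, 4], Inf)  # disconnected pair
  expect_equal(reconstruct_path(r, 1, 4), integer(0))
})

test_that("vertex matching equals a brute-force nearest-neighbour scan", {
  ico <- icosphere(2)
  expect_equal(match_vertices(ico, ico), seq_len(nrow(ico$vertices)))
  # coarse mesh = fine minus one vertex
  keep <- seq_len(nrow(ico$vertices) - 1)
  coarse <- ico$vertices[keep, ]
  map <- match_vertices(ico, coarse)
  expect_equal(map[keep], keep)
  removed <- nrow(ico$vertices)
  d <- colSums((t(coarse) - ico$vertices[removed, ])^2)
  expect_equal(map[removed], which.min(d))
  set.seed(3)
  fine <- matrix(rnorm(60), ncol = 3)
  brute <- apply(fine, 1, function(p) which.min(colSums((t(coarse) - p)^2)))
  expect_equal(match_vertices(fine, coarse), brute)
})

test_that("through-volume routes never exceed pure surface geodesics", {
  mesh <- icosphere(2, radius = 10)
  vol <- shell_indicator(c(0, 0, 0), 10.01)
  rt <- route_distances(mesh, vol, step = 0.5)
  gd <- geodesic_distances(mesh, cutoff = 100)
  dm <- meshnpm:::distance_matrix(gd)
  sel <- cbind(sample(nrow(dm), 200, replace = TRUE),
               sample(nrow(dm), 200, replace = TRUE))
  expect_true(all(rt$distances[sel] <= dm[sel] + 1e-9))
})
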