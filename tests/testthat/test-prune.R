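test_that("edge collapse reduces counts by (V-1, F-2) and preserves Euler characteristic", {
  ico <- icosphere(2)
  e <- mesh_edges(ico)[1, ]
  out <- collapse_edge(ico, e, b = 1)
  expect_equal(nrow(out$vertices), nrow(ico$vertices) - 1)
  expect_equal(nrow(out$triangles), nrow(ico$triangles) - 2)
  expect_equal(euler_characteristic(out), euler_characteristic(ico))
})

test_that("collapse with b = 0 places the new vertex at the edge midpoint", {
  patch <- flat_patch(4, 4)
  e <- mesh_edges(patch)
  inner <- e[e[, 1] == 6 & e[, 2] == 7, , drop = FALSE][1, ]
  mid <- (patch$vertices[inner[1], ] + patch$vertices[inner[2], ]) / 2
  out <- collapse_edge(patch, inner, b = 0)
  expect_equal(out$vertices[min(inner), ], mid)
  expect_true(all(abs(out$vertices[, 3]) < 1e-12))  # stays in plane
})

test_that("collapse with b = 1 reconstructs the sphere (circle-segment rule)", {
  ico <- icosphere(3)
  for (k in c(1, 50, 200)) {
    e <- mesh_edges(ico)[k, ]
    out <- collapse_edge(ico, e, b = 1)
    expect_lt(abs(sqrt(sum(out$vertices[min(e), ]^2)) - 1), 1e-3)
  }
})

test_that("tetrahedron configurations are detected exactly (brute-force oracle)", {
  expect_length(detect_tetrahedra(icosphere(2)), 0)
  for (face in c(1, 7, 19)) {
    m <- add_tetrahedron(icosphere(1), face_idx = face)
    hits <- detect_tetrahedra(m)
    expect_length(hits, 1)
    expect_equal(hits[[1]]$peak, nrow(m$vertices))
    # independent brute force over all degree-3 vertices
    deg <- tabulate(m$triangles, nrow(m$vertices))
    emat <- mesh_edges(m)
    ekey <- paste(emat[, 1], emat[, 2])
    fkey <- apply(m$triangles, 1, function(t) paste(sort(t), collapse = " "))
    brute <- list()
    for (v in which(deg == 3)) {
      nb <- sort(unique(setdiff(as.vector(
        m$triangles[rowSums(m$triangles == v) > 0, ]), v)))
      if (length(nb) != 3) next
      pairs <- rbind(nb[c(1, 2)], nb[c(2, 3)], nb[c(1, 3)])
      if (all(paste(pairs[, 1], pairs[, 2]) %in% ekey) &&
          !(paste(nb, collapse = " ") %in% fkey))
        brute[[length(brute) + 1]] <- v
    }
    expect_equal(hits[[1]]$peak, brute[[1]])
    expect_length(brute, 1)
  }
})

test_that("tetrahedron removal replaces the peak by the (optionally lifted) base", {
  m <- add_tetrahedron(icosphere(1), face_idx = 3)
  hit <- detect_tetrahedra(m)[[1]]
  base_before <- m$vertices[hit$base, ]
  out0 <- remove_tetrahedron(m, hit$peak, hit$base, l = 0)
  expect_equal(nrow(out0$vertices), nrow(m$vertices) - 1)
  expect_equal(nrow(out0$triangles), nrow(m$triangles) - 2)
  expect_equal(out0$vertices[hit$base, ], base_before)  # unmoved for l = 0
  fkey <- apply(out0$triangles, 1, function(t) paste(sort(t), collapse = " "))
  expect_true(paste(sort(hit$base), collapse = " ") %in% fkey)

  peak_pos <- m$vertices[hit$peak, ]
  out5 <- remove_tetrahedron(m, hit$peak, hit$base, l = 0.5)
  expect_equal(out5$vertices[hit$base, ],
               0.5 * base_before + 0.5 * matrix(peak_pos, 3, 3, byrow = TRUE))
  expect_error(remove_tetrahedron(out0, hit$peak, hit$base), "already a face")
})

test_that("pruning a unit icosphere with b = 1 preserves the radius", {
  ico <- icosphere(4)  # 2562 vertices
  pruned <- prune_mesh(ico, prune_config(min_edge_length = 0.18, b = 1, l = 0))
  expect_lt(nrow(pruned$vertices), nrow(ico$vertices))
  r <- sqrt(rowSums(pruned$vertices^2))
  expect_lte(max(abs(r - 1)), 1e-2)
  elen <- {
    e <- mesh_edges(pruned)
    sqrt(rowSums((pruned$vertices[e[, 1], ] - pruned$vertices[e[, 2], ])^2))
  }
  expect_true(all(elen >= 0.18))
  rep <- attr(pruned, "prune_report")
  expect_lt(abs(rep$area_change), 0.02)
  expect_equal(euler_characteristic(pruned), 2L)
})

test_that("pruning a flat patch with b = 0 keeps vertices coplanar", {
  patch <- flat_patch(6, 6, spacing = 1)
  pruned <- prune_mesh(patch, prune_config(min_edge_length = 1.3, b = 0, l = 0))
  expect_true(all(abs(pruned$vertices[, 3]) < 1e-12))
  expect_lt(nrow(pruned$vertices), nrow(patch$vertices))
})

test_that("pruning is a no-op when all edges already exceed the threshold", {
  ico <- icosphere(2)
  out <- prune_mesh(ico, prune_config(min_edge_length = 0.01))
  expect_equal(out$vertices, ico$vertices)
  expect_equal(out$triangles, ico$triangles)
})

test_that("pruning resolves tetrahedron configurations on the way", {
  m <- add_tetrahedron(icosphere(2), face_idx = 5, height = 0.05)
  cfg <- prune_config(min_edge_length = 0.4, b = 1, l = 0)
  out <- prune_mesh(m, cfg)
  expect_length(detect_tetrahedra(out), 0)
  expect_equal(euler_characteristic(out), 2L)
})

test_that("pruning errors when the mesh would be exhausted", {
  expect_error(prune_mesh(icosphere(0), prune_config(min_edge_length = 10),
                          min_vertices = 8), "exhausted")
})
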