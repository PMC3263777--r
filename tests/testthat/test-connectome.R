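test_that("cut-off distance follows the exponential retention rule", {
  expect_equal(cutoff_distance(25, 0.1), 25 * log(10))
  expect_equal(round(cutoff_distance(25, 0.1) / 10, 2), 5.76)  # cm, printed value
  expect_equal(cutoff_distance(25, 1), 0)
  expect_equal(cutoff_distance(25, exp(-1)), 25)
  expect_error(cutoff_distance(25, 1.2), "retained_fraction")
})

test_that("background weights normalize to one per target to 1e-10", {
  mesh <- icosphere(2, radius = 20)
  kern <- background_kernel(decay_length = 25, cutoff = 30)
  gd <- geodesic_distances(mesh, cutoff = kern$cutoff)
  cn <- background_weights(gd, kern, vertex_areas(mesh))
  sums <- rowsum(cn$connections$weight, cn$connections$dst)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-10)
  expect_true(all(cn$connections$delay_s > 0))
})

test_that("background weight ratios follow the exponential kernel", {
  # three collinear vertices: sources at distances d1 and d2 from the target
  mesh <- flat_patch(8, 3, spacing = 5)
  kern <- background_kernel(decay_length = 25, cutoff = 40)
  gd <- geodesic_distances(mesh, cutoff = 40)
  va <- vertex_areas(mesh)
  cn <- background_weights(gd, kern, va)
  cc <- cn$connections
  tgt <- 12  # interior vertex
  sel <- cc[cc$dst == tgt, ]
  dm <- meshnpm:::distance_matrix(gd)
  for (k in sample(nrow(sel), 5)) {
    for (k2 in sample(nrow(sel), 5)) {
      b1 <- sel$src[k]; b2 <- sel$src[k2]
      expected <- va[b1] / va[b2] * exp(-(dm[b1, tgt] - dm[b2, tgt]) / 25)
      expect_equal(sel$weight[k] / sel$weight[k2], unname(expected),
                   tolerance = 1e-12)
    }
  }
})

test_that("single in-range source gets weight one; equidistant equal-area sources get half", {
  # a path mesh where the cutoff only reaches immediate neighbours
  mesh <- flat_patch(3, 2, spacing = 10)
  kern <- background_kernel(decay_length = 25, cutoff = 10.1)
  gd <- geodesic_distances(mesh, cutoff = 10.1)
  cn <- background_weights(gd, kern, rep(1, nrow(mesh$vertices)))
  cc <- cn$connections
  sums <- rowsum(cc$weight, cc$dst)
  expect_equal(as.numeric(sums), rep(1, nrow(sums)))
  # corner vertex 1 has exactly two sources at 10 mm with equal area weight
  w1 <- cc[cc$dst == 1, ]
  expect_equal(sort(w1$weight), rep(0.5, 2))
})

test_that("specific weights add W_s per afferent region, area-distributed", {
  mesh <- cached_small_cortex()
  rt <- cached_routes()
  va <- vertex_areas(mesh)
  rm3 <- make_region_matrix(3)
  sp <- specific_weights(mesh$labels, rm3, W_s = 0.1, routes = rt,
                         velocity = 3, vertex_areas = va)
  cc <- sp$connections
  # per target: W_s per afferent region with a nonzero grade
  tot <- rowsum_ref(cc$weight, cc$dst, sp$n)
  afferent <- sapply(seq_len(sp$n), function(a) {
    ra <- mesh$labels[a]
    sum(rm3[, ra] > 0) - (rm3[ra, ra] > 0)
  })
  expect_equal(tot, 0.1 * afferent, tolerance = 1e-10)
  # direct summation oracle on one target vertex
  a <- which(mesh$labels == 2)[1]
  sel <- cc[cc$dst == a & mesh$labels[cc$src] == 1, ]
  expect_equal(sum(sel$weight), 0.1, tolerance = 1e-12)
  ratio <- sel$weight / va[sel$src]          # area-proportional distribution
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  expect_equal(nrow(specific_weights(mesh$labels, rm3, 0, rt, 3, va)$connections), 0)
})

test_that("homotopic links map mirror-symmetric vertices exactly and involutively", {
  mesh <- cached_small_cortex()
  hemi <- attr(mesh, "hemisphere")
  mm <- mirror_match(mesh$vertices, hemi)
  refl <- mesh$vertices; refl[, 1] <- -refl[, 1]
  # exact mirror fixture: partner position equals the reflected position
  expect_equal(mesh$vertices[mm, ], unname(refl))
  expect_equal(mm[mm], seq_len(nrow(mesh$vertices)))  # involution
  # brute-force nearest-to-mirror scan
  n <- nrow(mesh$vertices)
  brute <- integer(n)
  for (i in sample(n, 20)) {
    cand <- which(hemi != hemi[i])
    d <- colSums((t(mesh$vertices[cand, ]) - refl[i, ])^2)
    expect_equal(mm[i], cand[which.min(d)])
  }
  rt <- cached_routes()
  hm <- homotopic_connections(mesh, W_s = 0.1, routes = rt, velocity = 3)
  expect_equal(nrow(hm$connections), n)
  expect_true(all(hm$connections$delay_s > 0))
})

test_that("delays discretize to the nearest time step with spline guard", {
  expect_equal(discretize_delays(0.75e-3, 5e-5), 15L)
  expect_equal(discretize_delays(0, 5e-5), 0L)
  expect_equal(discretize_delays(2.6 * 5e-5, 5e-5), 3L)
  expect_error(discretize_delays(0.7e-3, 5e-5, u = 5), "splineable")
  expect_silent(discretize_delays(0.8e-3, 5e-5, u = 5))
})

test_that("the connectome is invariant under rigid motion of the mesh", {
  mesh <- icosphere(2, radius = 15)
  kern <- background_kernel(decay_length = 25, cutoff = 25)
  build <- function(m) {
    gd <- geodesic_distances(m, cutoff = kern$cutoff)
    background_weights(gd, kern, vertex_areas(m))$connections
  }
  cc1 <- build(mesh)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mesh2 <- mesh
  mesh2$vertices <- mesh$vertices %*% Rz + matrix(c(5, -3, 11), nrow(mesh$vertices),
                                                  3, byrow = TRUE)
  cc2 <- build(mesh2)
  expect_equal(cc1$weight, cc2$weight, tolerance = 1e-9)
  expect_equal(cc1$delay_s, cc2$delay_s, tolerance = 1e-9)
})

test_that("specific/background accounting ratio equals W_s x afferent regions", {
  mesh <- cached_small_cortex()
  rt <- cached_routes()
  kern <- background_kernel(decay_length = 25, cutoff = 40)
  cn <- suppressWarnings(
    build_connectome(mesh, kern, mesh$labels, make_region_matrix(3),
                     W_s = 0.3, routes = rt, homotopic = TRUE))
  ratio <- specific_background_ratio(cn)
  afferent <- sapply(seq_len(cn$n), function(a) {
    ra <- mesh$labels[a]
    sum(make_region_matrix(3)[, ra] > 0)
  }) + 1  # homotopic mirror link counts as one afferent
  expect_equal(ratio, 0.3 * afferent, tolerance = 1e-10)
})
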