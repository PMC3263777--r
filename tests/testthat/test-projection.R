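test_that("projection weights peak at zero displacement and respect the kernel", {
  mesh <- icosphere(2, radius = 20)
  grid <- make_voxel_grid(mesh, spacing = 2)
  cfg <- projection_config()
  W <- projection_weights(mesh, grid, cfg)
  expect_equal(dim(W), c(nrow(mesh$vertices), prod(grid$dim)))
  # a voxel centred exactly on a vertex has pre-normalization weight 1
  vc <- voxel_centers(grid)
  mesh2 <- mesh
  mesh2$vertices[1, ] <- vc[100, ] * c(1, 1, 1)
  W2 <- projection_weights(mesh2, grid, cfg)
  expect_equal(W2[1, 100], 1)
  expect_true(all(W@x <= 1 + 1e-15))
})

test_that("normal/tangential decomposition is exactly orthogonal", {
  set.seed(4)
  for (k in 1:100) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    d <- rnorm(3, sd = 3)
    n_comp <- sum(d * nrm) * nrm
    t_comp <- d - n_comp
    expect_equal(sum(n_comp * t_comp), 0, tolerance = 1e-12)
    expect_equal(sum(n_comp^2) + sum(t_comp^2), sum(d^2), tolerance = 1e-12)
  }
})

test_that("isotropic widths reduce to an isotropic Gaussian of |d|", {
  mesh <- icosphere(2, radius = 15)
  grid <- make_voxel_grid(mesh, spacing = 3)
  cfg <- projection_config(sigma_n = 2, sigma_t = 2)
  W <- projection_weights(mesh, grid, cfg)
  vc <- voxel_centers(grid)
  Wd <- as.matrix(W)
  sel <- which(Wd > 1e-6, arr.ind = TRUE)
  sel <- sel[sample(nrow(sel), 200), ]
  d2 <- rowSums((mesh$vertices[sel[, 1], ] - vc[sel[, 2], ])^2)
  expect_equal(Wd[sel], exp(-d2 / (2 * 4)), tolerance = 1e-12)
})

test_that("uniform fields project to the uniform value in both directions", {
  mesh <- icosphere(2, radius = 15)
  grid <- make_voxel_grid(mesh, spacing = 2)
  W <- projection_weights(mesh, grid)
  img <- vertex_to_voxel(rep(3.7, nrow(mesh$vertices)), W)
  expect_equal(unique(img[!is.na(img)]), 3.7)
  back <- voxel_to_vertex(img, W)
  expect_equal(back, rep(3.7, nrow(mesh$vertices)))
})

test_that("a single active vertex produces a decaying tangential blob with the right FWHM", {
  # flat patch: normals along z, tangential plane x-y
  mesh <- flat_patch(41, 5, spacing = 0.5)
  grid <- make_voxel_grid(mesh, spacing = 0.25, pad = 2)
  cfg <- projection_config(sigma_n = 2, sigma_t = 1.66)
  W <- projection_weights(mesh, grid, cfg)
  v <- numeric(nrow(mesh$vertices))
  center_vertex <- which(mesh$vertices[, 1] == 10 & mesh$vertices[, 2] == 1)
  v[center_vertex] <- 1
  img <- vertex_to_voxel(v, W, rescale = FALSE)
  vc <- voxel_centers(grid)
  # profile along x through the vertex, at the vertex's y/z plane
  row_sel <- which(abs(vc[, 2] - 1) < 1e-9 & abs(vc[, 3]) < 0.126)
  prof <- img[row_sel]
  xs <- vc[row_sel, 1]
  ok <- !is.na(prof)
  prof <- prof[ok]; xs <- xs[ok]
  pk <- which.max(prof)
  expect_equal(xs[pk], 10, tolerance = 0.26)       # maximum at the vertex
  expect_true(all(diff(prof[xs >= 10 & xs <= 13]) <= 1e-12))  # monotone decay
  # FWHM of the weight profile ~ 2 sqrt(2 ln 2) * 1.66 = 3.9 mm; measure it
  # from the unnormalized weight row of the center vertex
  wrow <- as.numeric(W[center_vertex, row_sel][ok])
  half <- max(wrow) / 2
  above <- xs[wrow >= half]
  expect_equal(max(above) - min(above), gaussian_fwhm(1.66), tolerance = 0.3)
})

test_that("smooth fields survive a voxel round trip (r > 0.95)", {
  mesh <- icosphere(3, radius = 15)
  grid <- make_voxel_grid(mesh, spacing = 2)
  W <- projection_weights(mesh, grid)
  field <- sin(mesh$vertices[, 1] / 6) + 0.5 * cos(mesh$vertices[, 2] / 8)
  img <- vertex_to_voxel(field, W)
  back <- voxel_to_vertex(img, W)
  ok <- !is.na(back)
  expect_gt(stats::cor(field[ok], back[ok]), 0.95)
  # range restoration: projected image spans the input range exactly
  expect_equal(range(img, na.rm = TRUE), range(field))
})

test_that("a single-voxel impulse back-projects maximally onto the nearest vertex", {
  mesh <- icosphere(2, radius = 12)
  grid <- make_voxel_grid(mesh, spacing = 2)
  W <- projection_weights(mesh, grid)
  vc <- voxel_centers(grid)
  # choose a voxel close to the surface
  d2v <- colSums((t(vc) - mesh$vertices[7, ])^2)
  vox <- which.min(d2v)
  img <- rep(NA_real_, nrow(vc)); img[vox] <- 1
  vals <- voxel_to_vertex(img, W, rescale = FALSE)
  near <- which.min(colSums((t(mesh$vertices) - vc[vox, ])^2))
  expect_equal(which.max(ifelse(is.na(vals), -Inf, vals)), near)
})

test_that("NIfTI export round-trips values and affine geometry", {
  mesh <- icosphere(1, radius = 8)
  grid <- make_voxel_grid(mesh, spacing = 2)
  W <- projection_weights(mesh, grid)
  img <- vertex_to_voxel(mesh$vertices[, 3], W)
  path <- tempfile(fileext = ".nii")
  write_voxel_image(img, grid, path)
  back <- read_voxel_image(path)
  expect_equal(back$dim, grid$dim)
  expect_equal(back$values, ifelse(is.na(img), 0, img), tolerance = 1e-6)
  hdr <- RNifti::niftiHeader(RNifti::readNifti(path))
  expect_equal(hdr$srow_x[4], grid$origin[1], tolerance = 1e-5)
  # world <-> index mappings are exact inverses
  ijk <- rbind(c(0, 0, 0), c(3, 4, 5))
  expect_equal(world_to_index(grid, index_to_world(grid, ijk)), ijk)
})
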