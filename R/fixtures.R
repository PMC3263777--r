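#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; the standard quasi-uniform
#' sphere triangulation. Subdivision level `s` gives `10 * 4^s + 2` vertices.
#'
#' @param subdivisions integer >= 0.
#' @param radius sphere radius (mm).
#' @param center length-3 numeric center (mm).
#' @return a [triangle_mesh()] with outward winding.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    extra <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      extra[[length(extra) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(c_, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f)
}

#' Synthetic two-hemisphere cortex fixture
#'
#' Two mirror-symmetric (across x = 0) icospheres standing in for the left and
#' right cortical hemispheres, optionally with a sinusoidal radial "folding"
#' perturbation mimicking gyri. Vertices of the right hemisphere are the exact
#' mirror images of the left ones.
#'
#' @param subdivisions icosphere subdivision level (>= 2).
#' @param radius hemisphere radius (mm).
#' @param separation distance between hemisphere centers (mm).
#' @param fold_amplitude relative radial modulation amplitude (0 = smooth sphere).
#' @param fold_frequency angular frequency of the folding pattern.
#' @return list with `left`, `right` ([triangle_mesh()]) and `hemisphere`
#'   labels ("L"/"R") aligned with `merge_hemispheres()` order.
#' @export
make_hemispheres <- function(subdivisions = 2, radius = 28, separation = 70,
                             fold_amplitude = 0, fold_frequency = 4) {
  if (subdivisions < 2) stop("'subdivisions' must be >= 2")
  left <- icosphere(subdivisions, radius, center = c(0, 0, 0))
  if (fold_amplitude > 0) {
    u <- sweep(left$vertices, 2, c(0, 0, 0))
    r <- sqrt(rowSums(u^2))
    dir <- u / r
    mod <- 1 + fold_amplitude * sin(fold_frequency * atan2(dir[, 2], dir[, 1])) *
      sin(fold_frequency * acos(pmin(1, pmax(-1, dir[, 3]))))
    left$vertices <- dir * (r * mod)
  }
  left$vertices[, 1] <- left$vertices[, 1] - separation / 2
  right <- left
  right$vertices[, 1] <- -right$vertices[, 1]
  # mirroring flips orientation; swap two columns to restore outward winding
  right$triangles <- right$triangles[, c(1, 3, 2)]
  list(left = left, right = right,
       hemisphere = rep(c("L", "R"), each = nrow(left$vertices)))
}

#' Merge two hemisphere meshes into one mesh
#'
#' Vertices of `right` are appended after those of `left`; the two components
#' remain topologically disconnected.
#'
#' @param hemis result of [make_hemispheres()], or a list with `left`/`right`.
#' @return a [triangle_mesh()] with a `hemisphere` attribute ("L"/"R" per vertex).
#' @export
merge_hemispheres <- function(hemis) {
  nl <- nrow(hemis$left$vertices)
  mesh <- triangle_mesh(
    rbind(hemis$left$vertices, hemis$right$vertices),
    rbind(hemis$left$triangles, hemis$right$triangles + nl),
    labels = c(hemis$left$labels, hemis$right$labels))
  attr(mesh, "hemisphere") <- rep(c("L", "R"),
                                  c(nl, nrow(hemis$right$vertices)))
  mesh
}

#' Contiguous random parcellation of a mesh
#'
#' Seeds `n_regions` vertices (farthest-point sampling after a random start)
#' and grows regions by nearest-seed geodesic distance, yielding contiguous
#' spherical patches that partition the vertex set.
#'
#' @param mesh a [triangle_mesh()].
#' @param n_regions number of regions (>= 3).
#' @param seed RNG seed (mandatory; fixtures are pure functions of spec + seed).
#' @return integer vector of region ids 1..n_regions, one per vertex.
#' @export
make_parcellation <- function(mesh, n_regions = 3, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_regions < 3) stop("'n_regions' must be >= 3")
  n <- nrow(mesh$vertices)
  g <- mesh_graph(mesh)
  set.seed(seed)
  seeds <- sample.int(n, 1)
  d_to_seeds <- igraph::distances(g, v = seeds)
  while (length(seeds) < n_regions) {
    cand <- which.max(apply(d_to_seeds, 2, min))
    seeds <- c(seeds, cand)
    d_to_seeds <- rbind(d_to_seeds, igraph::distances(g, v = cand))
  }
  lab <- apply(d_to_seeds, 2, which.min)
  if (min(tabulate(lab, n_regions)) < 5)
    stop("region smaller than 5 vertices; use fewer regions or a finer mesh")
  as.integer(lab)
}

#' Graded region-to-region connectivity matrix fixture
#'
#' The default pattern is a fully connected 3-region triangle of grade-2
#' ("moderate") connections in both directions, mimicking a small visual
#' network (two visual areas plus a frontal eye field), with zero diagonal.
#' For `n_regions > 3` additional random connections are drawn.
#'
#' @param n_regions number of regions.
#' @param pattern "triangle" (default) or "random".
#' @param density fraction of off-diagonal entries present for "random".
#' @param seed RNG seed.
#' @return integer matrix of grades 0-3 with region names `R1..Rn`.
#' @export
make_region_matrix <- function(n_regions = 3, pattern = c("triangle", "random"),
                               density = 0.3, seed = 1) {
  pattern <- match.arg(pattern)
  m <- matrix(0L, n_regions, n_regions)
  if (pattern == "triangle") {
    m[1:3, 1:3] <- 2L
    diag(m) <- 0L
    if (n_regions > 3) {
      set.seed(seed)
      off <- which(row(m) != col(m) & (row(m) > 3 | col(m) > 3))
      pick <- off[stats::runif(length(off)) < density]
      m[pick] <- sample(1:3, length(pick), replace = TRUE)
    }
  } else {
    set.seed(seed)
    off <- which(row(m) != col(m))
    pick <- off[stats::runif(length(off)) < density]
    m[pick] <- sample(1:3, length(pick), replace = TRUE)
  }
  dimnames(m) <- list(paste0("R", 1:n_regions), paste0("R", 1:n_regions))
  m
}

#' Volume indicator for the two-hemisphere fixture
#'
#' Union of the two hemisphere balls plus a midline bridge ball standing in
#' for the callosal cross-over, so that contralateral through-volume routes
#' exist. Matches the [make_hemispheres()] geometry.
#'
#' @param radius hemisphere radius (mm).
#' @param separation distance between hemisphere centers (mm).
#' @param bridge_radius radius of the midline bridge ball (mm); must exceed
#'   half the inter-surface gap to overlap both hemispheres.
#' @param tolerance boundary tolerance (mm).
#' @return a membership function (see [shell_indicator()]).
#' @export
hemispheres_volume <- function(radius = 28, separation = 70,
                               bridge_radius = 12, tolerance = 0.5) {
  gap <- separation / 2 - radius
  if (bridge_radius <= gap) stop("bridge does not reach the hemispheres")
  union_indicator(
    shell_indicator(c(-separation / 2, 0, 0), radius, tolerance = tolerance),
    shell_indicator(c(separation / 2, 0, 0), radius, tolerance = tolerance),
    shell_indicator(c(0, 0, 0), bridge_radius, tolerance = tolerance))
}

#' Three-shell synthetic head model
#'
#' Concentric icosphere surfaces for the inner skull, outer skull and scalp,
#' with standard conductivities: 0.2 S/m inside the skull, 0.03 S/m for the
#' skull, 0.2 S/m for the scalp.
#'
#' @param radii strictly increasing shell radii (mm), inner skull to scalp.
#' @param conductivities conductivities (S/m) of the three compartments
#'   enclosed by the respective surfaces.
#' @param subdivisions icosphere subdivision level per shell.
#' @return a `head_model` list: `surfaces` (list of 3 meshes, innermost
#'   first), `conductivities`, `radii`.
#' @export
make_head_shells <- function(radii = c(80, 85, 92),
                             conductivities = c(0.2, 0.03, 0.2),
                             subdivisions = 3) {
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  surfaces <- lapply(radii, function(r) icosphere(subdivisions, r))
  structure(list(surfaces = surfaces, conductivities = conductivities,
                 radii = radii), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model: 3 nested shells, radii %s mm, conductivities %s S/m\n",
              paste(x$radii, collapse = "/"),
              paste(x$conductivities, collapse = "/")))
  invisible(x)
}

#' Quasi-uniform electrode cap on the scalp shell
#'
#' Electrodes placed on a Fibonacci lattice over the upper part of the scalp
#' sphere.
#'
#' @param n_electrodes number of electrodes.
#' @param scalp_radius scalp sphere radius (mm).
#' @param coverage fraction of the full sphere covered from the vertex down
#'   (0.5 = upper hemisphere only).
#' @return data.frame with columns label, x, y, z (mm).
#' @export
make_electrodes <- function(n_electrodes = 32, scalp_radius = 92, coverage = 0.6) {
  i <- seq_len(n_electrodes) - 0.5
  z <- 1 - (i / n_electrodes) * 2 * coverage     # from pole downwards
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- scalp_radius * cbind(rho * cos(phi), rho * sin(phi), z)
  data.frame(label = sprintf("E%02d", seq_len(n_electrodes)),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Isotropic voxel grid covering a mesh
#'
#' Axis-aligned grid of cubic voxels (centres at `origin + (index-1)*spacing`)
#' padded around the mesh bounding box, with a NIfTI-style affine mapping
#' 0-based indices to world mm coordinates.
#'
#' @param mesh a [triangle_mesh()] (or matrix of points) to cover.
#' @param spacing voxel edge length (mm).
#' @param pad padding (mm) added around the bounding box.
#' @return a `voxel_grid` list: `dim`, `spacing`, `origin` (world mm of the
#'   centre of voxel (1,1,1)), `affine` (4x4).
#' @export
make_voxel_grid <- function(mesh, spacing = 2, pad = 6) {
  pts <- if (inherits(mesh, "triangle_mesh")) mesh$vertices else as.matrix(mesh)
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dim <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- lo
  structure(list(dim = dim, spacing = rep(spacing, 3), origin = lo,
                 affine = affine), class = "voxel_grid")
}

#' Voxel centre world coordinates
#' @param grid a [make_voxel_grid()] result.
#' @return matrix `prod(dim) x 3` of voxel centre positions (mm), in
#'   column-major (x fastest) order.
#' @export
voxel_centers <- function(grid) {
  idx <- as.matrix(expand.grid(x = seq_len(grid$dim[1]) - 1L,
                               y = seq_len(grid$dim[2]) - 1L,
                               z = seq_len(grid$dim[3]) - 1L))
  sweep(idx %*% diag(grid$spacing), 2, grid$origin, "+")
}

#' World to 0-based voxel index coordinates
#' @param grid a [make_voxel_grid()] result.
#' @param xyz matrix of world coordinates (mm).
#' @return matrix of continuous 0-based index coordinates.
#' @export
world_to_index <- function(grid, xyz) {
  sweep(as.matrix(xyz), 2, grid$origin, "-") %*% diag(1 / grid$spacing)
}

#' @rdname world_to_index
#' @param ijk matrix of 0-based index coordinates.
#' @export
index_to_world <- function(grid, ijk) {
  sweep(as.matrix(ijk) %*% diag(grid$spacing), 2, grid$origin, "+")
}
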