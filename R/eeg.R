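#' Head model from explicit surfaces
#'
#' @param surfaces list of three closed [triangle_mesh()] surfaces, innermost
#'   (inner skull) first, outward winding.
#' @param conductivities compartment conductivities (S/m), innermost first;
#'   the exterior is insulating.
#' @return a `head_model`.
#' @export
head_model <- function(surfaces, conductivities = c(0.2, 0.03, 0.2)) {
  if (length(surfaces) != 3) stop("three nested surfaces required")
  if (any(conductivities <= 0)) stop("conductivities must be > 0")
  structure(list(surfaces = surfaces, conductivities = conductivities,
                 radii = NULL), class = "head_model")
}

#' Dipole sources from excitatory membrane potentials
#'
#' Each mesh vertex carries a current dipole along its outward surface normal
#' with moment proportional to the deviation of `h_e` from rest, weighted by
#' the vertex area: `moment(t) = c_d * (h_e(t) - rest_h_e) * vertex_area`.
#'
#' @param h_e_series `n x nt` matrix of per-vertex h_e (mV).
#' @param mesh the cortex [triangle_mesh()].
#' @param rest_h_e resting potential to subtract (mV).
#' @param c_d proportionality constant (arbitrary units; absolute scalp-volt
#'   calibration is not attempted).
#' @param inner_skull optional inner-skull [triangle_mesh()]; if given, all
#'   vertices are checked to lie strictly inside it.
#' @return a `dipole_set`: `positions`, unit `orientations`, `moments`
#'   (`n x nt`).
#' @export
dipole_sources <- function(h_e_series, mesh, rest_h_e, c_d = 1,
                           inner_skull = NULL) {
  h_e_series <- rbind(h_e_series)
  n <- nrow(mesh$vertices)
  if (nrow(h_e_series) != n) stop("h_e series rows must match mesh vertices")
  if (!is.null(inner_skull)) {
    ok <- points_inside_surface(mesh$vertices, inner_skull)
    if (!all(ok))
      stop("vertices outside the inner skull: ",
           paste(utils::head(which(!ok)), collapse = ", "))
  }
  structure(list(positions = mesh$vertices,
                 orientations = vertex_normals(mesh),
                 moments = c_d * (h_e_series - rest_h_e) * vertex_areas(mesh)),
            class = "dipole_set")
}

# ray-free inside test via the total solid angle (4 pi inside, 0 outside)
points_inside_surface <- function(points, surface) {
  tr <- surface$triangles; vv <- surface$vertices
  om <- .solid_angles(as.matrix(points), vv[tr[, 1], , drop = FALSE],
                      vv[tr[, 2], , drop = FALSE], vv[tr[, 3], , drop = FALSE])
  abs(rowSums(om)) > 2 * pi
}

#' EEG transfer matrix by the boundary element method
#'
#' Linear collocation on triangle centroids for the piecewise-homogeneous
#' three-compartment conductor, with the isolated-skull approach for the
#' low-conductivity skull layer, autosolid-angle diagonal correction and
#' deflation of the singular system. The returned matrix maps dipole moments
#' (fixed positions and orientations) to average-referenced electrode
#' potentials; it is computed once and reused across time steps.
#'
#' @param head a `head_model` (see [head_model()] / [make_head_shells()]).
#' @param source_positions `ns x 3` dipole positions (mm), inside the inner
#'   surface.
#' @param orientations `ns x 3` unit dipole orientations.
#' @param electrodes `ne x 3` electrode positions (mm), snapped to the nearest
#'   scalp collocation point.
#' @param isa use the isolated-skull approach? (recommended for realistic
#'   skull conductivity contrasts).
#' @return `ne x ns` transfer matrix (average reference).
#' @export
bem_transfer_matrix <- function(head, source_positions, orientations,
                                electrodes, isa = TRUE) {
  geom <- bem_geometry(head)
  sys <- bem_system(geom, head$conductivities, isa = isa)
  src_inf <- infinite_medium_potential(geom$centroids, source_positions,
                                       orientations)   # M x ns, sigma-free
  v <- bem_solve(sys, src_inf)
  el_idx <- match_vertices(electrodes, geom$centroids[geom$surface == 3, ,
                                                      drop = FALSE])
  scalp <- v[geom$surface == 3, , drop = FALSE]
  out <- scalp[el_idx, , drop = FALSE]
  sweep(out, 2, colMeans(out))           # average reference
}

# centroids, triangle vertex blocks and surface ids of the three shells
bem_geometry <- function(head) {
  cents <- list(); v1 <- list(); v2 <- list(); v3 <- list(); surf <- list()
  for (s in 1:3) {
    m <- head$surfaces[[s]]
    tr <- m$triangles; vv <- m$vertices
    v1[[s]] <- vv[tr[, 1], , drop = FALSE]
    v2[[s]] <- vv[tr[, 2], , drop = FALSE]
    v3[[s]] <- vv[tr[, 3], , drop = FALSE]
    cents[[s]] <- (v1[[s]] + v2[[s]] + v3[[s]]) / 3
    surf[[s]] <- rep(s, nrow(tr))
  }
  list(centroids = do.call(rbind, cents),
       v1 = do.call(rbind, v1), v2 = do.call(rbind, v2),
       v3 = do.call(rbind, v3), surface = unlist(surf))
}

# assemble and factorize the deflated BEM system(s)
bem_system <- function(geom, cond, isa = TRUE) {
  M <- nrow(geom$centroids)
  surf <- geom$surface
  om <- .solid_angles(geom$centroids, geom$v1, geom$v2, geom$v3)
  # autosolid-angle: force row sums per source surface to the analytic values
  # (2 pi on the own surface, 4 pi for enclosing surfaces, 0 otherwise)
  for (k in 1:3) for (l in 1:3) {
    rows <- which(surf == k); cols <- which(surf == l)
    target <- if (l == k) 2 * pi else if (l > k) 4 * pi else 0
    if (l == k) {
      # put the correction on the self-triangle (diagonal) entry
      rs <- rowSums(om[rows, cols, drop = FALSE])
      dg <- cbind(rows, cols[seq_along(rows)])
      om[dg] <- om[dg] + (target - rs)
    }
  }
  sig_in <- cond                     # conductivity inside surface k
  sig_out <- c(cond[2], cond[3], 0)  # conductivity outside surface k
  sig_bar <- (sig_in + sig_out) / 2
  cdiff <- sig_in - sig_out
  B <- om * rep(cdiff[surf] / (4 * pi), each = M) / sig_bar[surf]
  A <- diag(M) - B + 1 / M           # deflation of the constant nullspace
  sys <- list(M = M, surf = surf, om = om, sig_bar = sig_bar, cdiff = cdiff,
              A = A, isa = isa, cond = cond)
  if (isa) {
    rows1 <- which(surf == 1)
    M1 <- length(rows1)
    B1 <- om[rows1, rows1, drop = FALSE] * (cond[1] / (4 * pi)) / (cond[1] / 2)
    sys$A_iso <- diag(M1) - B1 + 1 / M1
    sys$rows1 <- rows1
  }
  sys
}

# solve for surface potentials; src_inf is the sigma-free infinite-medium
# potential, which already equals sigma_s * v_inf(centroids)
bem_solve <- function(sys, src_inf) {
  g <- src_inf
  b <- g / sys$sig_bar[sys$surf]
  if (!sys$isa) return(solve(sys$A, b))
  # isolated problem on the inner surface (insulating exterior)
  rows1 <- sys$rows1
  b_iso <- g[rows1, , drop = FALSE] / (sys$cond[1] / 2)
  v_iso <- solve(sys$A_iso, b_iso)
  beta <- sys$cond[1] / (sys$cond[1] - sys$cond[2])
  vt <- matrix(0, sys$M, ncol(src_inf))
  vt[rows1, ] <- v_iso
  # modified source term cancels the large isolated part analytically
  c1 <- sys$cdiff[1]
  corr <- (c1 / (4 * pi)) * (sys$om[, rows1, drop = FALSE] %*% v_iso)
  b2 <- (g - beta * sys$sig_bar[sys$surf] * vt + beta * corr) /
    sys$sig_bar[sys$surf]
  w <- solve(sys$A, b2)
  w + beta * vt
}

# sigma-free infinite-medium dipole potential: rows observation points,
# columns sources; multiply by 1/sigma for the physical potential
infinite_medium_potential <- function(obs, src_pos, src_ori) {
  obs <- as.matrix(obs); src_pos <- rbind(src_pos); src_ori <- rbind(src_ori)
  M <- nrow(obs); ns <- nrow(src_pos)
  out <- matrix(0, M, ns)
  for (s in seq_len(ns)) {
    d <- sweep(obs, 2, src_pos[s, ])
    r3 <- (rowSums(d^2))^1.5
    out[, s] <- (d %*% src_ori[s, ]) / (4 * pi * r3)
  }
  out
}

#' Electrode time series from a transfer matrix and dipole moments
#'
#' @param transfer `ne x ns` matrix from [bem_transfer_matrix()].
#' @param dipoles a `dipole_set` (see [dipole_sources()]) or an `ns x nt`
#'   moment matrix.
#' @param decimate keep every `decimate`-th time point.
#' @return `ne x nt` EEG matrix (average-referenced like the transfer matrix).
#' @export
electrode_timeseries <- function(transfer, dipoles, decimate = 1L) {
  m <- if (inherits(dipoles, "dipole_set")) dipoles$moments else dipoles
  m <- rbind(m)
  if (ncol(transfer) != nrow(m)) stop("transfer/sources shape mismatch")
  keep <- seq(1, ncol(m), by = decimate)
  transfer %*% m[, keep, drop = FALSE]
}
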