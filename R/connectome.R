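#' Background connectivity kernel
#'
#' Homogeneous, isotropic, exponentially decaying cortico-cortical coupling.
#' Weights from source vertex b to target vertex a are proportional to
#' `area(b) * exp(-distance / decay_length)` for distances up to the cut-off,
#' and are normalized to sum to one per target. Long-range connections are
#' excitatory only; firing arrives with delay `distance / velocity`.
#'
#' @param decay_length characteristic decay length (mm); default 25 mm.
#' @param cutoff cut-off distance (mm); default [cutoff_distance()] at 10%
#'   retention, about 57.6 mm.
#' @param n_synapses number of long-range synapses formed at each target
#'   vertex, per receiving population (names "ee", "ei").
#' @param velocity conduction velocity (m/s); default 3.
#' @return a `background_kernel` list.
#' @export
background_kernel <- function(decay_length = 25,
                              cutoff = cutoff_distance(decay_length, 0.1),
                              n_synapses = c(ee = 4000, ei = 2000),
                              velocity = 3) {
  if (decay_length <= 0) stop("'decay_length' must be > 0")
  if (cutoff <= 0) stop("'cutoff' must be > 0")
  structure(list(decay_length = decay_length, cutoff = cutoff,
                 n_synapses = n_synapses, velocity = velocity),
            class = "background_kernel")
}

#' Cut-off distance of the exponential background kernel
#'
#' Distance at which `exp(-d / decay_length)` falls to `retained_fraction`:
#' `decay_length * log(1 / retained_fraction)`. A decay length of 25 mm with
#' 10% retention gives 57.6 mm.
#'
#' @param decay_length decay length (mm).
#' @param retained_fraction fraction of the zero-distance weight retained at
#'   the cut-off, in (0, 1\].
#' @return cut-off distance, same unit as `decay_length`.
#' @export
cutoff_distance <- function(decay_length, retained_fraction) {
  if (retained_fraction > 1 || retained_fraction <= 0)
    stop("'retained_fraction' must be in (0, 1]")
  decay_length * log(1 / retained_fraction)
}

#' Background connection weights
#'
#' @param geodesics a [geodesic_distances()] table (cutoff >= kernel cutoff).
#' @param kernel a [background_kernel()].
#' @param vertex_areas per-vertex areas (mm^2), see [vertex_areas()].
#' @return a `connectome` with the background part: data.frame columns `src`,
#'   `dst`, `weight`, `delay_s`, `kind`.
#' @export
background_weights <- function(geodesics, kernel, vertex_areas) {
  if (attr(geodesics, "cutoff") < kernel$cutoff)
    stop("geodesic table cutoff is smaller than the kernel cutoff")
  keep <- geodesics$distance <= kernel$cutoff
  src <- c(geodesics$from[keep], geodesics$to[keep])
  dst <- c(geodesics$to[keep], geodesics$from[keep])
  dd <- c(geodesics$distance[keep], geodesics$distance[keep])
  w <- vertex_areas[src] * exp(-dd / kernel$decay_length)
  n <- length(vertex_areas)
  tot <- rowsum_safe(w, dst, n)
  if (any(tot == 0))
    stop("vertex without in-range background sources (mesh too coarse for the cutoff): ",
         paste(utils::head(which(tot == 0)), collapse = ", "))
  w <- w / tot[dst]
  out <- data.frame(src = src, dst = dst, weight = w,
                    delay_s = dd / (kernel$velocity * 1000),  # mm / (mm/s)
                    kind = "background")
  make_connectome(out, n, kernel$n_synapses)
}

make_connectome <- function(df, n, n_synapses) {
  structure(list(connections = df, n = n, n_synapses = n_synapses),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  k <- table(x$connections$kind)
  cat(sprintf("connectome: %d vertices, %d connections (%s)\n", x$n,
              nrow(x$connections),
              paste(names(k), k, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Combine connectome parts
#' @param ... `connectome` objects over the same vertex set.
#' @return merged `connectome`.
#' @export
combine_connectomes <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  n <- parts[[1]]$n
  stopifnot(all(vapply(parts, function(p) p$n, 0) == n))
  make_connectome(do.call(rbind, lapply(parts, `[[`, "connections")), n,
                  parts[[1]]$n_synapses)
}

#' Specific (region-to-region) connection weights
#'
#' For each ordered region pair with a nonzero grade in the connectivity
#' matrix, every vertex of the receiving region gains incoming weights from
#' all vertices of the source region. The per-target total equals `W_s`
#' (strength relative to the total background, which sums to one), distributed
#' over source vertices proportionally to their area. Delays are routed
#' through-volume distances divided by the conduction velocity.
#'
#' Grades only gate presence by default (one universal strength for all
#' present connections); `grade_strengths` allows mapping grades 1-3 to
#' multipliers instead.
#'
#' @param parcellation integer region label per vertex.
#' @param region_matrix square integer grade matrix (rows = source regions).
#' @param W_s universal specific strength (fraction of total background).
#' @param routes result of [route_distances()] (coarse distances + match).
#' @param velocity conduction velocity (m/s).
#' @param vertex_areas per-vertex areas (mm^2).
#' @param grade_strengths optional numeric length-3 multiplier per grade;
#'   default `c(1, 1, 1)` (presence only).
#' @return a `connectome` with the specific part (possibly 0 rows for
#'   `W_s = 0`).
#' @export
specific_weights <- function(parcellation, region_matrix, W_s, routes, velocity,
                             vertex_areas, grade_strengths = c(1, 1, 1)) {
  if (W_s < 0) stop("'W_s' must be >= 0")
  n <- length(parcellation)
  empty <- make_connectome(
    data.frame(src = integer(), dst = integer(), weight = numeric(),
               delay_s = numeric(), kind = character()), n, NULL)
  if (W_s == 0) return(empty)
  parts <- list()
  nr <- nrow(region_matrix)
  for (rb in seq_len(nr)) for (ra in seq_len(nr)) {
    g <- region_matrix[rb, ra]
    if (rb == ra || g == 0) next
    src_v <- which(parcellation == rb)
    dst_v <- which(parcellation == ra)
    if (!length(src_v) || !length(dst_v))
      stop("empty region in parcellation: ", if (!length(src_v)) rb else ra)
    aw <- vertex_areas[src_v] / sum(vertex_areas[src_v])
    pair <- expand.grid(si = seq_along(src_v), di = seq_along(dst_v))
    src <- src_v[pair$si]; dst <- dst_v[pair$di]
    dist <- routes$distances[cbind(routes$match[src], routes$match[dst])]
    parts[[length(parts) + 1L]] <- data.frame(
      src = src, dst = dst,
      weight = W_s * grade_strengths[g] * aw[pair$si],
      delay_s = dist / (velocity * 1000),
      kind = "specific")
  }
  if (!length(parts)) return(empty)
  make_connectome(do.call(rbind, parts), n, NULL)
}

#' Homotopic contralateral connections
#'
#' Links every vertex to the vertex nearest to its mirror position across the
#' midsagittal plane (x = 0 by default), with weight `W_s` and delay from the
#' routed distance.
#'
#' @param mesh merged two-hemisphere [triangle_mesh()] with a `hemisphere`
#'   attribute ("L"/"R" per vertex).
#' @param W_s connection weight (fraction of total background).
#' @param routes result of [route_distances()].
#' @param velocity conduction velocity (m/s).
#' @param mirror_coord coordinate axis of the midsagittal plane (1 = x).
#' @return a `connectome` with kind "homotopic" (directed both ways).
#' @export
homotopic_connections <- function(mesh, W_s, routes, velocity, mirror_coord = 1) {
  hemi <- attr(mesh, "hemisphere")
  if (is.null(hemi)) stop("mesh lacks a 'hemisphere' attribute")
  n <- nrow(mesh$vertices)
  if (W_s == 0)
    return(make_connectome(
      data.frame(src = integer(), dst = integer(), weight = numeric(),
                 delay_s = numeric(), kind = character()), n, NULL))
  mirror <- mirror_match(mesh$vertices, hemi, mirror_coord)
  dist <- routes$distances[cbind(routes$match[mirror], routes$match[seq_len(n)])]
  make_connectome(data.frame(src = mirror, dst = seq_len(n), weight = W_s,
                             delay_s = dist / (velocity * 1000),
                             kind = "homotopic"), n, NULL)
}

#' Nearest vertex to each vertex's mirror position
#' @param vertices `n x 3` positions.
#' @param hemisphere "L"/"R" label per vertex.
#' @param mirror_coord axis to reflect (1 = x).
#' @return integer vector: contralateral partner of each vertex.
#' @export
mirror_match <- function(vertices, hemisphere, mirror_coord = 1) {
  refl <- vertices
  refl[, mirror_coord] <- -refl[, mirror_coord]
  out <- integer(nrow(vertices))
  for (h in unique(hemisphere)) {
    own <- hemisphere == h
    other <- which(!own)
    out[own] <- other[match_vertices(refl[own, , drop = FALSE],
                                     vertices[other, , drop = FALSE])]
  }
  out
}

#' Discretize conduction delays to time steps
#'
#' Rounds each delay to the nearest integer multiple of the simulation time
#' step. If `u` is given, specific (splined) delays at or below the minimum
#' splineable delay `3 * u * dt` raise an error.
#'
#' @param delays_s delays in seconds.
#' @param dt time step (s).
#' @param u optional spline up-sampling factor of the transmission channel.
#' @return integer vector of delay steps.
#' @export
discretize_delays <- function(delays_s, dt, u = NULL) {
  if (dt <= 0) stop("'dt' must be > 0")
  steps <- as.integer(round(delays_s / dt))
  if (!is.null(u) && any(delays_s <= 3 * u * dt)) {
    stop("specific delay <= minimum splineable delay 3*u*dt = ", 3 * u * dt,
         " s; lower the up-sampling factor u or merge the connection into a ",
         "background (per-step) path")
  }
  steps
}

#' Build a full connectome (background + specific + homotopic)
#'
#' @param mesh merged cortex [triangle_mesh()] (with `hemisphere` attribute if
#'   homotopic links are wanted).
#' @param kernel a [background_kernel()].
#' @param parcellation region label per vertex (NULL disables specific part).
#' @param region_matrix graded region matrix.
#' @param W_s universal specific strength.
#' @param routes result of [route_distances()].
#' @param geodesics optional precomputed [geodesic_distances()] table.
#' @param homotopic include contralateral mirror links?
#' @return merged `connectome`.
#' @export
build_connectome <- function(mesh, kernel, parcellation = NULL,
                             region_matrix = NULL, W_s = 0, routes = NULL,
                             geodesics = NULL, homotopic = TRUE) {
  if (is.null(geodesics))
    geodesics <- geodesic_distances(mesh, cutoff = kernel$cutoff)
  va <- vertex_areas(mesh)
  bg <- background_weights(geodesics, kernel, va)
  sp <- hm <- NULL
  if (!is.null(parcellation) && !is.null(region_matrix) && W_s > 0) {
    if (is.null(routes)) stop("routed distances required for specific connections")
    sp <- specific_weights(parcellation, region_matrix, W_s, routes,
                           kernel$velocity, va)
  }
  if (homotopic && W_s > 0 && !is.null(attr(mesh, "hemisphere"))) {
    if (is.null(routes)) stop("routed distances required for homotopic connections")
    hm <- homotopic_connections(mesh, W_s, routes, kernel$velocity)
  }
  combine_connectomes(bg, sp, hm)
}

#' Per-vertex specific-to-background input ratio
#'
#' Accounting check used by the sweep protocol: per target vertex, the total
#' specific (plus homotopic) weight divided by the total background weight
#' (which is 1 by construction). Equals `W_s` times the number of afferent
#' regions (counting the homotopic mirror link as one).
#'
#' @param connectome a `connectome`.
#' @return numeric vector, one ratio per vertex.
#' @export
specific_background_ratio <- function(connectome) {
  cc <- connectome$connections
  bg <- rowsum_safe(cc$weight[cc$kind == "background"],
                    cc$dst[cc$kind == "background"], connectome$n)
  sp <- rowsum_safe(cc$weight[cc$kind != "background"],
                    cc$dst[cc$kind != "background"], connectome$n)
  sp / bg
}
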