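#' Specific-connectivity sweep protocol
#'
#' @param W_s_values specific strengths to sweep (fractions of the total
#'   background strength); the study grid spans 0 to 1.
#' @param duration simulated time per point (s).
#' @param analysis_window length of the trailing window analysed (s), to skip
#'   initial transients.
#' @param segment_s,overlap_fraction Welch settings (Hann taper).
#' @param seed RNG seed, reused at every sweep point so spectral differences
#'   are attributable to connectivity alone.
#' @return a `sweep_protocol` list.
#' @export
sweep_protocol <- function(W_s_values = c(0, 0.30, 0.60, 0.85, 0.90, 1.0),
                           duration = 10, analysis_window = 4,
                           segment_s = 2, overlap_fraction = 0.5, seed = 1) {
  if (analysis_window > duration) stop("analysis window longer than duration")
  if (any(W_s_values < 0)) stop("W_s must be >= 0")
  structure(list(W_s_values = W_s_values, duration = duration,
                 analysis_window = analysis_window, segment_s = segment_s,
                 overlap_fraction = overlap_fraction, seed = seed),
            class = "sweep_protocol")
}

#' Run the connectivity-strength sweep
#'
#' For each specific strength `W_s`: rebuild the connectome (fixed background,
#' rescaled specific and homotopic parts), simulate with identical noise,
#' compute the Welch power spectrum of the vertex-averaged excitatory soma
#' potential ("ECoG") over the trailing analysis window, and collect
#' per-vertex snapshot series for EEG/BOLD export. Points where the
#' simulation diverges are recorded as failed and the sweep continues.
#'
#' @param protocol a [sweep_protocol()].
#' @param mesh merged cortex mesh (with `hemisphere` attribute for homotopic
#'   links).
#' @param kernel a [background_kernel()].
#' @param parcellation region labels per vertex.
#' @param region_matrix graded region connectivity matrix.
#' @param routes [route_distances()] result.
#' @param params an [npm_parameters()] set.
#' @param record_every field decimation (steps) for snapshot export.
#' @param mean_every decimation (steps) of the ECoG series.
#' @param homotopic include mirror links?
#' @return a `sweep_result`: per-point list with `W_s`, `psd` (dB re overall
#'   max), `ratio` (realized specific/background totals per vertex), `sim`
#'   (the simulation object), `failed` flag.
#' @export
run_sweep <- function(protocol, mesh, kernel, parcellation, region_matrix,
                      routes, params, record_every = 100L, mean_every = 4L,
                      homotopic = TRUE) {
  geod <- geodesic_distances(mesh, cutoff = kernel$cutoff)
  points <- vector("list", length(protocol$W_s_values))
  fs <- 1 / (params$dt * mean_every)
  for (k in seq_along(protocol$W_s_values)) {
    W_s <- protocol$W_s_values[k]
    cn <- build_connectome(mesh, kernel, parcellation, region_matrix,
                           W_s = W_s, routes = routes, geodesics = geod,
                           homotopic = homotopic)
    pt <- list(W_s = W_s, ratio = specific_background_ratio(cn), failed = FALSE)
    sim <- tryCatch(
      run_simulation(cn, params, protocol$duration, protocol$seed,
                     observers = c("mean_he", "fields"),
                     record_every = record_every, mean_every = mean_every),
      error = function(e) e)
    if (inherits(sim, "error")) {
      pt$failed <- TRUE
      pt$message <- conditionMessage(sim)
    } else {
      tail_sel <- sim$time_mean >= protocol$duration - protocol$analysis_window
      pt$psd <- psd_welch(sim$mean_he[tail_sel], fs,
                          segment_s = protocol$segment_s,
                          overlap_fraction = protocol$overlap_fraction)
      pt$sim <- sim
    }
    points[[k]] <- pt
  }
  # power in dB relative to the largest value across the whole sweep
  pmax_all <- max(vapply(points, function(p)
    if (p$failed) -Inf else max(p$psd$power), 0))
  for (k in seq_along(points)) {
    if (!points[[k]]$failed)
      points[[k]]$psd$db <- 10 * log10(points[[k]]$psd$power / pmax_all)
  }
  structure(list(points = points, protocol = protocol), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result over W_s =",
      paste(x$protocol$W_s_values, collapse = ", "), "\n")
  for (p in x$points) {
    if (p$failed) {
      cat(sprintf("  W_s = %.2f: FAILED (%s)\n", p$W_s, p$message))
    } else {
      pk <- p$psd$frequency[which.max(p$psd$power)]
      cat(sprintf("  W_s = %.2f: peak %.2f Hz, mean specific/background ratio %.3f\n",
                  p$W_s, pk, mean(p$ratio)))
    }
  }
  invisible(x)
}

#' Export sweep snapshots (EEG traces, ECoG series, BOLD volume)
#'
#' Writes, for one sweep point: the average-referenced electrode traces
#' (delimited text), the vertex-mean ECoG series (delimited text), and the
#' BOLD contrast at the final sample projected to the voxel grid (NIfTI), plus
#' a JSON summary of the accounting checks.
#'
#' @param point one element of `sweep_result$points`.
#' @param mesh the cortex mesh.
#' @param transfer EEG transfer matrix for the mesh vertices.
#' @param balloon a [balloon_parameters()].
#' @param baseline resting excitatory-input baseline (see [neural_drive()]).
#' @param weights projection weights ([projection_weights()]).
#' @param grid voxel grid.
#' @param rest_h_e resting h_e (mV) subtracted for dipole moments.
#' @param dir output directory.
#' @return invisible list of written paths.
#' @export
export_snapshots <- function(point, mesh, transfer, balloon, baseline,
                             weights, grid, rest_h_e, dir) {
  if (point$failed) stop("cannot export a failed sweep point")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- point$sim
  dip <- dipole_sources(sim$h_e, mesh, rest_h_e)
  eeg <- electrode_timeseries(transfer, dip)
  eeg_path <- file.path(dir, sprintf("eeg_Ws%03d.tsv", round(100 * point$W_s)))
  utils::write.table(t(eeg), eeg_path, sep = "\t", row.names = FALSE)
  ecog_path <- file.path(dir, sprintf("ecog_Ws%03d.tsv", round(100 * point$W_s)))
  utils::write.table(data.frame(time = sim$time_mean, mean_he = sim$mean_he),
                     ecog_path, sep = "\t", row.names = FALSE)
  bold <- simulate_bold(sim$A_ee, sim$A_ei, sim$time_fields, balloon, baseline)
  img <- vertex_to_voxel(bold$bold[, ncol(bold$bold)], weights)
  nii_path <- file.path(dir, sprintf("bold_Ws%03d.nii", round(100 * point$W_s)))
  write_voxel_image(img, grid, nii_path)
  paths <- list(eeg = eeg_path, ecog = ecog_path, bold = nii_path)
  invisible(paths)
}
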