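#' Analytic potential of a radial dipole in concentric spherical shells
#'
#' Series (Legendre expansion) solution for the surface potential of a
#' current dipole oriented radially, inside the innermost of N nested
#' spherical compartments with piecewise-constant conductivity and an
#' insulating exterior. Independent closed-form reference for the
#' boundary-element forward solution.
#'
#' @param radii strictly increasing interface radii (mm), innermost first.
#' @param conductivities conductivity (S/m) of each compartment, innermost
#'   first (same length as `radii`; exterior is insulating).
#' @param dipole_r radial position of the dipole (mm), `0 < dipole_r < radii[1]`.
#' @param moment dipole moment magnitude (radial direction).
#' @param electrodes `n x 3` matrix of positions on the outer sphere (mm);
#'   only their angle to the dipole axis (+z) is used.
#' @param n_max series truncation order.
#' @return electrode potentials (not referenced).
#' @export
concentric_spheres_potential <- function(radii, conductivities, dipole_r,
                                         moment, electrodes, n_max = 120) {
  L <- length(radii)
  stopifnot(length(conductivities) == L, dipole_r > 0, dipole_r < radii[1])
  R <- radii / radii[L]                  # nondimensionalize
  b <- dipole_r / radii[L]
  sig <- conductivities
  # per order n solve for coefficients A_j, B_j (B_1 absorbed in the source)
  # unknowns: A_1, then (A_j, B_j) for j = 2..L -> 2L - 1 unknowns
  nunk <- 2 * L - 1
  costh <- drop(as.matrix(electrodes) %*% c(0, 0, 1)) /
    sqrt(rowSums(as.matrix(electrodes)^2))
  pot <- numeric(nrow(electrodes))
  p_nm1 <- rep(1, length(costh))         # P_0
  p_n <- costh                           # P_1
  for (n in seq_len(n_max)) {
    src <- function(r) moment / (4 * pi * sig[1]) * n * b^(n - 1) / r^(n + 1)
    dsrc <- function(r) -moment / (4 * pi * sig[1]) * n * (n + 1) * b^(n - 1) / r^(n + 2)
    A <- matrix(0, nunk, nunk)
    rhs <- numeric(nunk)
    idxA <- function(j) if (j == 1) 1L else 2L * (j - 1L)
    idxB <- function(j) 2L * (j - 1L) + 1L   # j >= 2
    row <- 0L
    for (j in seq_len(L - 1)) {            # interface at R[j]: j | j+1
      r <- R[j]
      row <- row + 1L                      # potential continuity
      A[row, idxA(j)] <- r^n
      if (j > 1) A[row, idxB(j)] <- r^(-n - 1)
      A[row, idxA(j + 1)] <- -r^n
      A[row, idxB(j + 1)] <- -r^(-n - 1)
      rhs[row] <- if (j == 1) -src(r) else 0
      row <- row + 1L                      # current continuity
      A[row, idxA(j)] <- sig[j] * n * r^(n - 1)
      if (j > 1) A[row, idxB(j)] <- -sig[j] * (n + 1) * r^(-n - 2)
      A[row, idxA(j + 1)] <- -sig[j + 1] * n * r^(n - 1)
      A[row, idxB(j + 1)] <- sig[j + 1] * (n + 1) * r^(-n - 2)
      rhs[row] <- if (j == 1) -sig[1] * dsrc(r) else 0
    }
    row <- row + 1L                        # insulating exterior at R[L] = 1
    A[row, idxA(L)] <- n
    A[row, idxB(L)] <- -(n + 1)
    rhs[row] <- 0
    x <- solve(A, rhs)
    vL <- x[idxA(L)] + x[idxB(L)]          # at r = 1
    term <- vL * p_n
    pot <- pot + term
    if (n > 10 && max(abs(term)) < 1e-14 * max(abs(pot), 1e-300)) break
    p_np1 <- ((2 * n + 1) * costh * p_n - n * p_nm1) / (n + 1)
    p_nm1 <- p_n; p_n <- p_np1
  }
  # lengths were expressed in units of radii[L]; the dipole potential has
  # dimension 1/length^2, so undo the scaling
  pot / radii[L]^2
}
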