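## Steering forces from a solved potential: F_i = -q_i grad(phi)(r_i), the
## gradient obtained by central differences of the trilinear interpolant,
## plus the force-window rescaling that keeps steering forces readable by
## an MD engine without distorting their directions.

#' Per-atom electrostatic forces from a potential grid
#'
#' Each ligand atom feels F = -q * grad(phi) at its position; the gradient
#' is computed numerically as a central difference of the trilinearly
#' interpolated potential (default step = half a grid spacing, which
#' smooths node-level discretization noise).
#'
#' @param grid a [PotentialGrid-class] solved for the receptor (with the
#'   ligand as an uncharged cavity).
#' @param ligand a [Structure-class]; its partial charges are applied here.
#' @param step finite-difference step, A (default `spacing / 2`).
#' @return a [ForceSet-class] in kcal/mol/A, `appliedFactor = 1`.
#' @export
forcesFromPotential <- function(grid, ligand, step = NULL) {
  stopifnot(is(grid, "PotentialGrid"), is(ligand, "Structure"))
  h <- grid@spacing
  if (is.null(step)) step <- h / 2
  xyz <- coords(ligand)
  lo <- grid@origin + 2 * h
  hi <- grid@origin + (grid@dims - 1L) * h - 2 * h
  bad <- which(xyz[, 1] < lo[1] | xyz[, 2] < lo[2] | xyz[, 3] < lo[3] |
               xyz[, 1] > hi[1] | xyz[, 2] > hi[2] | xyz[, 3] > hi[3])
  if (length(bad))
    stop(sprintf("atom %s too near the grid boundary (< 2 spacings)",
                 paste(atoms(ligand)$serial[bad], collapse = ", ")),
         call. = FALSE)
  q <- atoms(ligand)$charge
  F <- matrix(0, nrow(xyz), 3L)
  for (ax in 1:3) {
    dp <- xyz; dp[, ax] <- dp[, ax] + step
    dm <- xyz; dm[, ax] <- dm[, ax] - step
    F[, ax] <- -q * (potentialAt(grid, dp) - potentialAt(grid, dm)) / (2 * step)
  }
  mag <- sqrt(rowSums(F^2))
  new("ForceSet", atomSerials = atoms(ligand)$serial, forces = F,
      fMax = max(mag), appliedFactor = 1)
}

#' Rescale a force set into the steering window
#'
#' If the maximum per-atom force magnitude is below `fLower`, all vectors
#' are multiplied by `fLower / Fmax` (so the maximum becomes exactly
#' `fLower`); if it exceeds `fUpper`, all are multiplied by
#' `fUpper / Fmax`. Directions are preserved exactly and the applied factor
#' is recorded. A zero force field cannot be normalized and is returned
#' unchanged with a warning.
#'
#' @param fs a [ForceSet-class].
#' @param window a [ForceWindow-class].
#' @return the rescaled [ForceSet-class].
#' @export
rescaleToWindow <- function(fs, window = forceWindow()) {
  stopifnot(is(fs, "ForceSet"), is(window, "ForceWindow"))
  mag <- sqrt(rowSums(fs@forces^2))
  fmax <- max(mag)
  if (fmax == 0) {
    warning("all forces are exactly zero; window rescaling skipped")
    fs@fMax <- 0
    fs@appliedFactor <- 1
    return(fs)
  }
  factor <- if (fmax < window@fLower) window@fLower / fmax
            else if (fmax > window@fUpper) window@fUpper / fmax
            else 1
  fs@forces <- fs@forces * factor
  fs@fMax <- fmax * factor
  fs@appliedFactor <- factor
  fs
}

#' Build a ForceSet from raw vectors
#'
#' @param forces n x 3 matrix, kcal/mol/A.
#' @param atomSerials integer serials (default 1..n).
#' @return a [ForceSet-class] with `appliedFactor = 1`.
#' @export
forceSet <- function(forces, atomSerials = seq_len(nrow(forces))) {
  forces <- as.matrix(forces)
  new("ForceSet", atomSerials = as.integer(atomSerials), forces = forces,
      fMax = max(sqrt(rowSums(forces^2))), appliedFactor = 1)
}
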