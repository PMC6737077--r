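## R-side interface to the Langevin engine: local (non-steering) forces and
## BAOAB dynamics over a cycle with the steering force held constant.

.ligandTopology <- function(ligand) {
  meta <- structureMeta(ligand)
  n <- nAtoms(ligand)
  bonds <- meta$bonds
  angles <- meta$angles
  mass <- meta$mass
  if (is.null(bonds)) bonds <- matrix(numeric(0), 0, 4,
    dimnames = list(NULL, c("i", "j", "r0", "k")))
  if (is.null(angles)) angles <- matrix(numeric(0), 0, 5,
    dimnames = list(NULL, c("i", "j", "k", "theta0", "kang")))
  if (is.null(mass)) mass <- rep(20, n)
  list(bonds = bonds, angles = angles, mass = rep_len(mass, n))
}

.emptyReceptorArgs <- function() {
  list(rx = matrix(numeric(0), 0, 3), rq = numeric(0), rrad = numeric(0))
}

.receptorArgs <- function(receptor) {
  if (is.null(receptor)) return(.emptyReceptorArgs())
  list(rx = coords(receptor), rq = atoms(receptor)$charge,
       rrad = atoms(receptor)$radius)
}

#' Local (non-steering) forces on a ligand
#'
#' The short-range force field that stands in for a full MD force field at
#' bead resolution: harmonic bonds and angles from the ligand topology, a
#' purely repulsive truncated-shifted Lennard-Jones (WCA) interaction
#' between every ligand and receptor bead, and, optionally, screened
#' Coulomb electrostatics within `steeringCutoff`.
#'
#' @param ligand a [Structure-class] with topology in `meta`.
#' @param receptor optional rigid [Structure-class].
#' @param config an [EngineConfig-class].
#' @param solverCfg a [SolverConfig-class] (solvent dielectric of the
#'   local electrostatics).
#' @param gbCfg a [GBConfig-class] for the Born radii of the local
#'   electrostatics.
#' @param tetherK,tetherCenter optional external harmonic tether (used by
#'   thermostat calibration experiments).
#' @return n x 3 force matrix, kcal/mol/A.
#' @export
localForces <- function(ligand, receptor = NULL, config = engineConfig(),
                        solverCfg = solverConfig(), gbCfg = gbConfig(),
                        tetherK = 0, tetherCenter = c(0, 0, 0)) {
  topo <- .ligandTopology(ligand)
  ra <- .receptorArgs(receptor)
  born <- .engineBornRadii(ligand, receptor, config, gbCfg)
  F <- .localForces(coords(ligand),
                    matrix(as.integer(topo$bonds[, 1:2]), ncol = 2),
                    as.numeric(topo$bonds[, "r0"]),
                    as.numeric(topo$bonds[, "k"]),
                    matrix(as.integer(topo$angles[, 1:3]), ncol = 3),
                    as.numeric(topo$angles[, "theta0"]),
                    as.numeric(topo$angles[, "kang"]),
                    ra$rx, ra$rq, ra$rrad,
                    atoms(ligand)$charge, atoms(ligand)$radius,
                    born$receptor, born$ligand,
                    config@wcaEpsilon, isTRUE(config@localElec),
                    config@steeringCutoff, solverCfg@epsSolvent,
                    tetherK, tetherCenter)
  fmax <- max(sqrt(rowSums(F^2)))
  if (!is.finite(fmax) || fmax > 1e4)
    stop(sprintf("local force blow-up (|F|max = %.3g kcal/mol/A)", fmax),
         call. = FALSE)
  F
}

#' Run BAOAB Langevin dynamics for a block of steps
#'
#' Underdamped Langevin dynamics with the BAOAB splitting. The steering
#' force (if any) is held constant across the block, matching the
#' constant-pulling-force convention of steered MD between force updates.
#' The RNG stream is fully determined by (`seed`, `stream`).
#'
#' @param ligand a [Structure-class] (topology in `meta`).
#' @param receptor optional rigid [Structure-class].
#' @param nSteps number of timesteps.
#' @param config an [EngineConfig-class].
#' @param solverCfg a [SolverConfig-class] for the local electrostatics.
#' @param gbCfg a [GBConfig-class] for the local-electrostatics Born radii.
#' @param velocities n x 3 initial velocities, A/fs (default zero).
#' @param steering optional [ForceSet-class] or n x 3 matrix, kcal/mol/A.
#' @param tetherK,tetherCenter optional external harmonic tether.
#' @param seed,stream RNG seed pair.
#' @param recordEvery record positions every this many steps (0 = none).
#' @return list with `x`, `v`, `blewUp`, `blowStep`, `keMean` (mean kinetic
#'   energy, kcal/mol) and `records` (recorded flattened positions).
#' @export
langevinStep <- function(ligand, receptor = NULL, nSteps,
                         config = engineConfig(), solverCfg = solverConfig(),
                         gbCfg = gbConfig(), velocities = NULL,
                         steering = NULL,
                         tetherK = 0, tetherCenter = c(0, 0, 0),
                         seed = config@seed, stream = 0L, recordEvery = 0L) {
  topo <- .ligandTopology(ligand)
  ra <- .receptorArgs(receptor)
  n <- nAtoms(ligand)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  steerMat <- if (is.null(steering)) matrix(0, n, 3)
              else if (is(steering, "ForceSet")) forces(steering)
              else as.matrix(steering)
  born <- .engineBornRadii(ligand, receptor, config, gbCfg)
  res <- .langevinCycle(coords(ligand), velocities, topo$mass,
                        matrix(as.integer(topo$bonds[, 1:2]), ncol = 2),
                        as.numeric(topo$bonds[, "r0"]),
                        as.numeric(topo$bonds[, "k"]),
                        matrix(as.integer(topo$angles[, 1:3]), ncol = 3),
                        as.numeric(topo$angles[, "theta0"]),
                        as.numeric(topo$angles[, "kang"]),
                        ra$rx, ra$rq, ra$rrad,
                        atoms(ligand)$charge, atoms(ligand)$radius,
                        born$receptor, born$ligand,
                        steerMat, config@timestep, config@langevinGamma,
                        config@temperature, as.integer(nSteps),
                        config@wcaEpsilon, isTRUE(config@localElec),
                        config@steeringCutoff, solverCfg@epsSolvent,
                        tetherK, tetherCenter,
                        as.numeric(seed %% 2^31), as.numeric(stream %% 2^31),
                        as.integer(recordEvery), 1e4)
  res
}

#' Maxwell-Boltzmann initial velocities
#'
#' @param ligand a [Structure-class].
#' @param temperature K.
#' @param seed integer seed.
#' @return n x 3 velocity matrix, A/fs.
#' @export
initialVelocities <- function(ligand, temperature = 300, seed = 1) {
  topo <- .ligandTopology(ligand)
  n <- nAtoms(ligand)
  sig <- sqrt(.accConv * .kBoltz * temperature / topo$mass)
  .withSeed(seed, matrix(rnorm(3 * n), n, 3) * sig)
}


## Born radii of ligand and receptor atoms for the engine's local GB
## electrostatics, recomputed once per cycle and held fixed inside it.
## Transient overlaps during dynamics are tolerated by clamping rather
## than erroring, and the effective radius is bounded above.
.engineBornRadii <- function(ligand, receptor, config, gbCfg) {
  n <- nAtoms(ligand)
  m <- if (is.null(receptor)) 0L else nAtoms(receptor)
  if (!isTRUE(config@localElec) || m == 0L)
    return(list(ligand = rep(1, n), receptor = rep(1, max(m, 0L))))
  a <- rbind(atoms(ligand), atoms(receptor))
  xyz <- unname(as.matrix(a[, c("x", "y", "z")]))
  nm <- n + m
  rho <- pmax(a$radius - gbCfg@radiusOffset, 0.5)
  D <- pmax(as.matrix(dist(xyz)), 0.5)
  sSc <- gbCfg@radiusScale * rho
  ## fully vectorized over the pair matrix; out-of-cutoff and diagonal
  ## entries are zeroed, so the row sums equal the neighbour-loop sums
  mask <- D < gbCfg@cutoff
  diag(mask) <- FALSE
  H <- .hctH(D, matrix(sSc, nm, nm, byrow = TRUE), rho)
  S <- .switchFun(D, gbCfg@switchingStart, gbCfg@cutoff)$s
  inv <- 1 / rho - unname(rowSums(H * S * mask))
  R <- 1 / pmax(inv, 0.05)
  list(ligand = R[seq_len(n)], receptor = R[n + seq_len(m)])
}
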