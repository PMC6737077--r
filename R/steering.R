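## The steering loop: every cycle the linearized PB equation is re-solved
## for the receptor with the ligand as an uncharged cavity at its current
## pose, per-atom forces are taken from the potential gradient, gated by
## the steering mode, window-rescaled, and held constant over a block of
## BAOAB Langevin steps.

#' Steering gate
#'
#' Decides whether steering forces are applied this cycle. Mode
#' "accelerated" always steers; "cutoff" steers only while every ligand
#' atom is farther than `steeringCutoff` from every receptor atom (once any
#' atom comes inside the cutoff the local force field is presumed to carry
#' the interaction); "scaled" always steers (its GB correction handles
#' proximity); "off" never steers.
#'
#' @param minPairDist minimum ligand-receptor atom-atom distance, A.
#' @param mode engine mode string.
#' @param steeringCutoff gate distance, A.
#' @return logical.
#' @export
steeringGate <- function(minPairDist, mode, steeringCutoff = 18) {
  switch(mode,
         accelerated = TRUE,
         cutoff = minPairDist > steeringCutoff,
         scaled = TRUE,
         off = FALSE,
         stop("unknown mode: ", mode, call. = FALSE))
}

## Analytic screened-Coulomb forces of the receptor charges on the ligand
## atoms; the long-range fallback when an atom leaves the solved grid
## (outside the box the potential is the boundary-condition sum anyway).
.dhForces <- function(bcAtoms, ligand, epsSolvent, kappa) {
  xyz <- coords(ligand)
  q <- atoms(ligand)$charge
  F <- matrix(0, nrow(xyz), 3L)
  for (a in seq_len(nrow(bcAtoms))) {
    d <- sweep(xyz, 2, bcAtoms[a, 1:3])
    r <- sqrt(rowSums(d^2))
    fr <- .kCoulomb * q * bcAtoms[a, 4] * exp(-kappa * r) *
          (1 / r + kappa) / (epsSolvent * r^2)
    F <- F + d * fr
  }
  F
}

.minPairDist <- function(receptor, ligand) {
  rx <- coords(receptor); lx <- coords(ligand)
  min(vapply(seq_len(nrow(lx)), function(i)
    min(sqrt(rowSums(sweep(rx, 2, lx[i, ])^2))), numeric(1)))
}

#' Run a steered Langevin simulation with cyclic PB force updates
#'
#' Loops until `totalSteps`: (1) solve the PB equation for the receptor
#' with the ligand cavity at its current pose; (2) convert the potential
#' gradient into per-atom forces on the ligand; (3) apply the mode gate
#' ("accelerated" always steers, "cutoff" steers only beyond the cutoff,
#' "scaled" subtracts the GB forces); (4) rescale into the force window;
#' (5) run `cycleSteps` BAOAB steps with the steering force constant.
#' Steering forces are recalculated every `cycleSteps` steps (default 500).
#' One trajectory frame is saved per cycle.
#'
#' @param receptor rigid charged [Structure-class].
#' @param ligand placed [Structure-class] with topology in `meta`.
#' @param engineCfg an [EngineConfig-class].
#' @param solverCfg a [SolverConfig-class].
#' @param gbCfg a [GBConfig-class] (mode "scaled" only).
#' @param verbose print per-cycle progress.
#' @return a [SteeringRun-class].
#' @export
runSteeredDynamics <- function(receptor, ligand, engineCfg = engineConfig(),
                    solverCfg = solverConfig(), gbCfg = gbConfig(),
                    verbose = FALSE) {
  stopifnot(is(receptor, "Structure"), is(ligand, "Structure"))
  mode <- engineCfg@mode
  d0 <- .minPairDist(receptor, ligand)
  if (d0 < engineCfg@steeringCutoff && mode != "off")
    warning(sprintf("initial min ligand-receptor distance %.1f A is inside the steering cutoff (%.1f A)",
                    d0, engineCfg@steeringCutoff))
  kappa <- sqrt(.debyeKappaSq(solverCfg@saltMolar, solverCfg@epsSolvent,
                              solverCfg@temperature))
  steeringNeeded <- mode != "off" && any(atoms(receptor)$charge != 0)
  geometry <- NULL
  phiPrev <- NULL
  bcCache <- NULL
  if (steeringNeeded && engineCfg@freezeGrid) {
    ## receptor is rigid: build its maps and boundary condition once; only
    ## the small ligand cavity is re-carved each cycle
    geometry <- buildMaps(receptor, NULL,
                          sizeGrid(list(receptor, ligand), solverCfg),
                          solverCfg)
    bcCache <- boundaryValues(geometry, solverCfg)
  }
  cavityLigand <- ligand  # pose used for the cavity when freezeCavity

  velocities <- initialVelocities(ligand, engineCfg@temperature,
                                  engineCfg@seed)
  nCycles <- ceiling(engineCfg@totalSteps / engineCfg@cycleSteps)
  frames <- vector("list", nCycles)
  times <- numeric(nCycles)
  ev <- vector("list", nCycles)
  completed <- TRUE
  stepsDone <- 0L

  for (cyc in seq_len(nCycles)) {
    nSteps <- min(engineCfg@cycleSteps, engineCfg@totalSteps - stepsDone)
    minD <- .minPairDist(receptor, ligand)
    gate <- steeringGate(minD, mode, engineCfg@steeringCutoff)
    rawFMax <- 0; factor <- 1; pbSolved <- FALSE; sweeps <- 0L
    residual <- 0; src <- "none"
    steer <- NULL
    if (gate && steeringNeeded) {
      fs <- NULL
      geomCyc <- if (engineCfg@freezeGrid) geometry
                 else sizeGrid(list(receptor, ligand), solverCfg)
      cavity <- if (engineCfg@freezeCavity) cavityLigand else ligand
      insideGrid <- {
        top <- geomCyc@origin + (geomCyc@dims - 1L) * geomCyc@spacing
        margin <- 2 * geomCyc@spacing
        lx <- coords(cavity)
        all(sweep(lx, 2, geomCyc@origin + margin) > 0) &&
          all(sweep(lx, 2, top - margin) < 0)
      }
      if (insideGrid) {
        gm <- if (engineCfg@freezeGrid) carveCavity(geomCyc, cavity, solverCfg)
              else buildMaps(receptor, cavity, geomCyc, solverCfg)
        phi <- suppressWarnings(solvePB(gm, solverCfg, init = phiPrev,
                                        bcValues = bcCache))
        if (!isConverged(phi)) {
          warning(sprintf("cycle %d: PB solve not converged (residual %.2e); cycle skipped",
                          cyc, phi@residual))
        } else {
          if (engineCfg@freezeGrid) phiPrev <- phi
          fs <- forcesFromPotential(phi, ligand)
          pbSolved <- TRUE
          sweeps <- phi@iterations
          residual <- phi@residual
          src <- "grid"
        }
      } else {
        ## ligand has drifted (partly) out of the solved box: out there the
        ## potential equals the analytic boundary-condition sum, so use its
        ## gradient directly
        F <- .dhForces(cbind(coords(receptor), atoms(receptor)$charge),
                       ligand, solverCfg@epsSolvent, kappa)
        fs <- forceSet(F, atoms(ligand)$serial)
        src <- "analytic"
      }
      if (!is.null(fs)) {
        if (mode == "scaled") {
          gb <- gbForces(receptor, ligand, gbCfg)
          fs <- forceSet(forces(fs) - forces(gb), atoms(ligand)$serial)
        }
        rawFMax <- fMax(fs)
        if (rawFMax > 0) {
          fs <- rescaleToWindow(fs, engineCfg@window)
          factor <- appliedFactor(fs)
          steer <- fs
        }
      }
    }
    res <- langevinStep(ligand, receptor, nSteps, engineCfg, solverCfg,
                        gbCfg = gbCfg, velocities = velocities,
                        steering = steer, seed = engineCfg@seed, stream = cyc)
    coords(ligand) <- res$x
    velocities <- res$v
    stepsDone <- stepsDone + nSteps
    frames[[cyc]] <- res$x
    times[cyc] <- stepsDone * engineCfg@timestep / 1000
    ev[[cyc]] <- data.frame(cycle = cyc, time = times[cyc],
                            rawFMax = rawFMax, factor = factor,
                            gate = gate, steered = !is.null(steer),
                            minPairDist = minD, pbSolved = pbSolved,
                            sweeps = sweeps, residual = residual,
                            source = src, keMean = res$keMean)
    if (verbose)
      message(sprintf("cycle %3d t=%8.1f ps  minD=%6.2f  Fmax=%.3g x%.3g [%s]",
                      cyc, times[cyc], minD, rawFMax, factor, src))
    if (res$blewUp) {
      warning(sprintf("dynamics blow-up at cycle %d, step %d; run terminated",
                      cyc, res$blowStep))
      completed <- FALSE
      frames <- frames[seq_len(cyc)]
      times <- times[seq_len(cyc)]
      ev <- ev[seq_len(cyc)]
      break
    }
  }
  new("SteeringRun", receptor = receptor, ligand = ligand,
      velocities = velocities, trajectory = frames, times = times,
      events = do.call(rbind, ev), config = engineCfg,
      solverConfig = solverCfg, completed = completed)
}

#' Distance from the ligand centre to the receptor pocket centre
#'
#' @param run a [SteeringRun-class] (or a ligand [Structure-class]).
#' @param pocketCenter 3-vector; defaults to the receptor's
#'   `meta$pocketCenter`.
#' @return distance in A (final frame for a run).
#' @export
pocketDistance <- function(run, pocketCenter = NULL) {
  if (is(run, "SteeringRun")) {
    if (is.null(pocketCenter))
      pocketCenter <- structureMeta(run@receptor)$pocketCenter
    lig <- run@ligand
  } else lig <- run
  stopifnot(!is.null(pocketCenter))
  sqrt(sum((colMeans(coords(lig)) - pocketCenter)^2))
}

#' Replicated funnel-capture experiment
#'
#' Runs `nSeeds` independent steered (or unsteered control) simulations of
#' the default funnel receptor (-10 e) with a spermidine-like (+3 e) ligand
#' placed 60 A from the receptor centre along the pocket axis, and reports
#' the final ligand-centre to pocket-centre distance of each run. A run is
#' counted as captured when that distance is below `captureRadius`
#' (default 5 A, the customary binding-success criterion).
#'
#' Desk-scale protocol: a coarse 0.5 grids/A PB lattice, 5 fs timesteps,
#' 0.5/ps Langevin damping (light damping accelerates the diffusive
#' approach, as small damping coefficients are understood to do), a
#' steering window of (0.01, 1) kcal/mol/A -- the upper bound tightened
#' below the conventional 10 so a captured bead chain is not slammed into
#' the repulsive wall between force updates -- and 320,000 steps (1.6 ns)
#' per run, long enough for the diffusive approach leg to complete its
#' first passage.
#'
#' @param nSeeds number of replicate runs.
#' @param baseSeed integer; run i uses seed `baseSeed + i - 1`.
#' @param steered logical: steering on (mode "accelerated") or off.
#' @param totalSteps,timestep,langevinGamma,cycleSteps engine parameters.
#' @param fLower,fUpper steering window bounds, kcal/mol/A.
#' @param scale PB grid resolution, grids/A.
#' @param distance initial centre-to-centre distance, A.
#' @param captureRadius success threshold, A.
#' @param receptor optional receptor override.
#' @param verbose print per-run progress.
#' @return data.frame with seed, finalDist, minDist and captured.
#' @export
funnelCaptureExperiment <- function(nSeeds = 10, baseSeed = 1, steered = TRUE,
                                    totalSteps = 320000, timestep = 5,
                                    langevinGamma = 0.5, cycleSteps = 500,
                                    fLower = 0.01, fUpper = 1,
                                    scale = 0.5, distance = 60,
                                    captureRadius = 5, receptor = NULL,
                                    verbose = FALSE) {
  if (is.null(receptor)) receptor <- makeFunnelReceptor()
  pocket <- structureMeta(receptor)$pocketCenter
  solverCfg <- solverConfig(scale = scale, tolerance = 1e-3,
                            maxIterations = 5000L)
  out <- lapply(seq_len(nSeeds), function(i) {
    seed <- baseSeed + i - 1L
    lig <- placeLigand(receptor, makePolyamineLigand("spermidine"),
                       direction = structureMeta(receptor)$mouthDirection,
                       distance = distance, seed = seed)
    ## the unsteered control removes the electrostatic guidance entirely
    ## (long-range steering and its short-range tail): free diffusion with
    ## excluded volume only
    cfg <- engineConfig(mode = if (steered) "accelerated" else "off",
                        localElec = steered,
                        totalSteps = totalSteps, timestep = timestep,
                        langevinGamma = langevinGamma,
                        cycleSteps = cycleSteps, seed = seed,
                        window = forceWindow(fLower, fUpper))
    run <- suppressWarnings(runSteeredDynamics(receptor, lig, cfg, solverCfg))
    dists <- vapply(trajectory(run), function(xy)
      sqrt(sum((colMeans(xy) - pocket)^2)), numeric(1))
    if (verbose)
      message(sprintf("seed %d: final %.2f A, min %.2f A", seed,
                      pocketDistance(run), min(dists)))
    data.frame(seed = seed, finalDist = pocketDistance(run),
               minDist = min(dists),
               captured = pocketDistance(run) < captureRadius)
  })
  do.call(rbind, out)
}
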