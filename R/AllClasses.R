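#' @import methods
#' @importFrom stats density dist median optim quantile rnorm runif sd setNames
#' @importFrom utils read.table write.csv packageVersion
#' @useDynLib pbsteer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Columns every Structure atom table must carry, in canonical order.
.atomCols <- c("serial", "atomName", "resName", "chain", "resNo",
               "x", "y", "z", "charge", "radius", "isH")

#' Molecular structure with per-atom charges and radii
#'
#' The central container of the package: an ordered table of atoms, each with
#' a position (Angstrom), a partial charge (elementary charges) and a radius
#' (Angstrom), as carried by the PQR format. The `meta` list holds optional
#' annotations produced by the fixture generators: the pocket-center
#' coordinate of a funnel receptor, bonded topology (bonds, angles) and
#' per-bead masses of a flexible ligand.
#'
#' @slot atoms data.frame with columns serial, atomName, resName, chain,
#'   resNo, x, y, z, charge, radius, isH.
#' @slot label single character label for the molecule.
#' @slot meta list of optional annotations.
#' @export
setClass("Structure",
  representation(atoms = "data.frame", label = "character", meta = "list"),
  prototype(atoms = data.frame(), label = "", meta = list()))

setValidity("Structure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return("Structure must contain at least one atom")
  miss <- setdiff(.atomCols, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("atom positions must be finite")
  if (any(!is.finite(a$charge))) return("charges must be finite")
  if (any(a$radius < 0)) return("radii must be non-negative")
  TRUE
})

#' Electrostatic potential on a cubic grid
#'
#' Node-centred scalar field of electrostatic potential in kcal/(mol e) on a
#' uniform cubic lattice. Grid dimensions are odd so the box centre falls on
#' a node. `converged` and `residual` report the state of the finite
#' difference relaxation that produced the field.
#'
#' @slot origin position of node (1,1,1), Angstrom.
#' @slot spacing uniform grid spacing, Angstrom.
#' @slot dims three odd positive integers.
#' @slot values numeric array of shape `dims`, kcal/(mol e).
#' @slot converged logical convergence flag.
#' @slot residual final max per-sweep potential change, kcal/(mol e).
#' @slot iterations number of relaxation sweeps performed.
#' @export
setClass("PotentialGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 values = "array", converged = "logical", residual = "numeric",
                 iterations = "integer"),
  prototype(converged = TRUE, residual = 0, iterations = 0L))

setValidity("PotentialGrid", function(object) {
  if (length(object@origin) != 3L) return("origin must be a 3-vector")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  if (any(object@dims %% 2L == 0L)) return("dims must be odd")
  if (!identical(dim(object@values), as.integer(object@dims)))
    return("values array shape must equal dims")
  if (!all(is.finite(object@values))) return("potential values must be finite")
  TRUE
})

#' Discretized Poisson-Boltzmann problem geometry
#'
#' Internal representation of the finite-difference problem: edge-centred
#' dielectric maps (one per axis), a node-centred Debye screening map
#' (kappa^2, zeroed inside the solute and its Stern layer) and the
#' node-centred source charge field obtained by trilinear spreading of the
#' receptor charges.
#'
#' @slot origin,spacing,dims grid geometry as in [PotentialGrid-class].
#' @slot epsX,epsY,epsZ edge-midpoint dielectric arrays.
#' @slot kappaSq node-centred kappa^2 map, 1/A^2.
#' @slot source node-centred charge field, e per node.
#' @slot bcAtoms matrix (x, y, z, charge) of the source atoms, used for the
#'   analytic screened-Coulomb boundary condition.
#' @slot complete TRUE once maps have been built (not just sized).
#' @export
setClass("GridGeometry",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 epsX = "array", epsY = "array", epsZ = "array",
                 kappaSq = "array", source = "array", bcAtoms = "matrix",
                 complete = "logical"),
  prototype(complete = FALSE, bcAtoms = matrix(numeric(0), 0, 4)))

#' Steering-force window
#'
#' Lower and upper bounds of the steering-force window. When the maximum
#' per-atom force magnitude falls below `fLower` all forces are inflated so
#' the maximum equals `fLower`; when it exceeds `fUpper` all forces are
#' deflated so the maximum equals `fUpper`. Directions are never changed.
#'
#' @slot fLower minimal steering force, kcal/mol/A (default 0.01, ~0.7 pN).
#' @slot fUpper maximal steering force, kcal/mol/A (default 10).
#' @export
setClass("ForceWindow",
  representation(fLower = "numeric", fUpper = "numeric"),
  prototype(fLower = 0.01, fUpper = 10))

setValidity("ForceWindow", function(object) {
  if (!(object@fLower > 0)) return("fLower must be positive")
  if (!(object@fUpper > object@fLower)) return("fUpper must exceed fLower")
  TRUE
})

#' @param fLower,fUpper window bounds in kcal/mol/A.
#' @rdname ForceWindow-class
#' @export
forceWindow <- function(fLower = 0.01, fUpper = 10) {
  new("ForceWindow", fLower = fLower, fUpper = fUpper)
}

#' Per-atom force vectors on a ligand
#'
#' @slot atomSerials integer serials the rows of `forces` refer to.
#' @slot forces n x 3 matrix of force vectors, kcal/mol/A.
#' @slot fMax maximum per-atom force magnitude (after any rescale).
#' @slot appliedFactor rescale multiplier applied (1 if none).
#' @export
setClass("ForceSet",
  representation(atomSerials = "integer", forces = "matrix",
                 fMax = "numeric", appliedFactor = "numeric"),
  prototype(appliedFactor = 1))

setValidity("ForceSet", function(object) {
  if (nrow(object@forces) != length(object@atomSerials))
    return("forces rows must match atomSerials")
  if (ncol(object@forces) != 3L) return("forces must have 3 columns")
  if (!all(is.finite(object@forces))) return("forces must be finite")
  if (!(object@appliedFactor > 0)) return("appliedFactor must be positive")
  TRUE
})

#' Poisson-Boltzmann solver configuration
#'
#' Defaults follow standard continuum-electrostatics practice for
#' protein-ligand systems: solute dielectric 2, solvent dielectric 80,
#' 0.15 M monovalent salt, box filled to 70 percent by the solute
#' (perfil), 2 grid points per Angstrom, 300 K.
#'
#' @slot epsSolute,epsSolvent interior and solvent dielectric constants.
#' @slot saltMolar 1:1 salt ionic strength, mol/L.
#' @slot scale grid points per Angstrom.
#' @slot perfil percentage of the box edge filled by the solute extent.
#' @slot temperature Kelvin.
#' @slot maxIterations relaxation sweep cap.
#' @slot tolerance convergence threshold on max per-sweep change, kcal/(mol e).
#' @slot sternLayer ion-exclusion layer thickness around the solute, A.
#' @slot omega SOR over-relaxation factor.
#' @slot maxDims hard cap on grid dimension (error above it).
#' @export
setClass("SolverConfig",
  representation(epsSolute = "numeric", epsSolvent = "numeric",
                 saltMolar = "numeric", scale = "numeric", perfil = "numeric",
                 temperature = "numeric", maxIterations = "integer",
                 tolerance = "numeric", sternLayer = "numeric",
                 omega = "numeric", maxDims = "integer"),
  prototype(epsSolute = 2, epsSolvent = 80, saltMolar = 0.15, scale = 2,
            perfil = 70, temperature = 300, maxIterations = 2000L,
            tolerance = 1e-4, sternLayer = 2.0, omega = 1.8, maxDims = 401L))

setValidity("SolverConfig", function(object) {
  if (!(object@epsSolvent > object@epsSolute && object@epsSolute >= 1))
    return("need epsSolvent > epsSolute >= 1")
  if (!(object@perfil > 0 && object@perfil <= 100))
    return("perfil must be in (0, 100]")
  if (!(object@scale > 0)) return("scale must be positive")
  if (!(object@tolerance > 0)) return("tolerance must be positive")
  if (object@saltMolar < 0) return("saltMolar must be non-negative")
  if (!(object@omega > 0 && object@omega < 2)) return("omega must be in (0, 2)")
  TRUE
})

#' @param ... named SolverConfig slot overrides.
#' @rdname SolverConfig-class
#' @export
solverConfig <- function(...) {
  args <- list(...)
  for (nm in c("maxIterations", "maxDims"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SolverConfig"), args))
}

#' Generalized-Born model configuration
#'
#' Pairwise GB with HCT-style descreened Born radii and Still's interaction
#' function. Pair interactions and the descreening sum are smoothly switched
#' to zero between `switchingStart` and `cutoff` (defaults 16 and 18 A, the
#' customary implicit-solvent MD truncation).
#'
#' @slot epsSolvent solvent dielectric (80).
#' @slot cutoff pair and descreening cutoff, A.
#' @slot switchingStart switching-function onset, A.
#' @slot radiusOffset intrinsic radius = atomic radius - offset, A.
#' @slot radiusScale HCT descreening scale factor on neighbour radii.
#' @export
setClass("GBConfig",
  representation(epsSolvent = "numeric", cutoff = "numeric",
                 switchingStart = "numeric", radiusOffset = "numeric",
                 radiusScale = "numeric"),
  prototype(epsSolvent = 80, cutoff = 18, switchingStart = 16,
            radiusOffset = 0.09, radiusScale = 0.8))

setValidity("GBConfig", function(object) {
  if (!(object@switchingStart < object@cutoff))
    return("switchingStart must be below cutoff")
  if (!(object@cutoff > 0)) return("cutoff must be positive")
  TRUE
})

#' @param ... named GBConfig slot overrides.
#' @rdname GBConfig-class
#' @export
gbConfig <- function(...) do.call(new, c(list("GBConfig"), list(...)))

#' Steered-dynamics engine configuration
#'
#' @slot mode one of "accelerated" (steer every cycle), "cutoff" (steer only
#'   while every ligand atom is beyond `steeringCutoff` from every receptor
#'   atom), "scaled" (steering = PB force - GB force) or "off" (no steering;
#'   control runs).
#' @slot cycleSteps dynamics steps per steering update (default 500).
#' @slot timestep fs (default 2).
#' @slot temperature thermostat temperature, K (default 300).
#' @slot langevinGamma Langevin damping, 1/ps (default 5).
#' @slot steeringCutoff distance gate for mode "cutoff" and range of the
#'   local short-range electrostatics, A (default 18).
#' @slot window [ForceWindow-class] applied to the steering forces.
#' @slot seed integer RNG seed; the whole run is reproducible from it.
#' @slot totalSteps total dynamics steps.
#' @slot wcaEpsilon repulsive (WCA) energy scale, kcal/mol.
#' @slot localElec logical: include the engine's native short-range
#'   screened-Coulomb electrostatics between ligand and receptor within
#'   `steeringCutoff` (default TRUE for every mode -- an MD engine's own
#'   truncated electrostatics is always present; the steering force is
#'   added on top, and the "scaled" mode exists precisely to remove the
#'   resulting double count).
#' @slot freezeGrid logical: size the PB grid once from the initial pose and
#'   reuse it (with the previous potential as initial guess) every cycle.
#' @slot freezeCavity logical: if TRUE the ligand cavity is not re-carved as
#'   the ligand moves.
#' @export
setClass("EngineConfig",
  representation(mode = "character", cycleSteps = "integer",
                 timestep = "numeric", temperature = "numeric",
                 langevinGamma = "numeric", steeringCutoff = "numeric",
                 window = "ForceWindow", seed = "integer",
                 totalSteps = "integer", wcaEpsilon = "numeric",
                 localElec = "logical", freezeGrid = "logical",
                 freezeCavity = "logical"),
  prototype(mode = "accelerated", cycleSteps = 500L, timestep = 2,
            temperature = 300, langevinGamma = 5, steeringCutoff = 18,
            window = new("ForceWindow"), seed = 1L, totalSteps = 5000L,
            wcaEpsilon = 0.2, localElec = NA, freezeGrid = TRUE,
            freezeCavity = FALSE))

setValidity("EngineConfig", function(object) {
  if (!object@mode %in% c("accelerated", "cutoff", "scaled", "off"))
    return("mode must be accelerated, cutoff, scaled or off")
  if (object@cycleSteps < 1L) return("cycleSteps must be >= 1")
  if (!(object@timestep > 0)) return("timestep must be positive")
  if (object@langevinGamma < 0) return("langevinGamma must be >= 0")
  TRUE
})

#' @param ... named EngineConfig slot overrides.
#' @rdname EngineConfig-class
#' @export
engineConfig <- function(...) {
  args <- list(...)
  for (nm in c("cycleSteps", "seed", "totalSteps"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  obj <- do.call(new, c(list("EngineConfig"), args))
  if (is.na(obj@localElec)) obj@localElec <- TRUE
  obj
}

#' Completed steered-dynamics run
#'
#' @slot receptor rigid receptor [Structure-class] (identical in all frames).
#' @slot ligand ligand [Structure-class] carrying the final coordinates.
#' @slot velocities final ligand velocities, A/fs.
#' @slot trajectory list of n x 3 ligand coordinate matrices (saved frames).
#' @slot times frame times, ps.
#' @slot events per-cycle data.frame: cycle, time, rawFMax, factor, gate,
#'   steered, minPairDist, pbSolved, sweeps, residual, source.
#' @slot config the [EngineConfig-class] used.
#' @slot solverConfig the [SolverConfig-class] used.
#' @slot completed logical; FALSE if the run aborted (blow-up).
#' @export
setClass("SteeringRun",
  representation(receptor = "Structure", ligand = "Structure",
                 velocities = "matrix", trajectory = "list",
                 times = "numeric", events = "data.frame",
                 config = "EngineConfig", solverConfig = "SolverConfig",
                 completed = "logical"),
  prototype(completed = TRUE))

#' Fluorescence titration series
#'
#' @slot lt total ligand concentrations, molar (strictly increasing).
#' @slot fc corrected fluorescence readings, arbitrary units.
#' @slot pt total protein concentration, molar.
#' @slot replicate integer replicate id per point.
#' @export
setClass("TitrationSeries",
  representation(lt = "numeric", fc = "numeric", pt = "numeric",
                 replicate = "integer"))

setValidity("TitrationSeries", function(object) {
  if (length(object@lt) != length(object@fc))
    return("lt and fc must have equal length")
  if (any(object@lt < 0)) return("ligand concentrations must be non-negative")
  if (!(object@pt > 0)) return("pt must be positive")
  sp <- split(object@lt, object@replicate)
  if (!all(vapply(sp, function(v) all(diff(v) > 0), logical(1))))
    return("lt must be strictly increasing within each replicate")
  TRUE
})

#' Fitted single-site binding isotherm
#'
#' @slot kd dissociation constant, molar.
#' @slot fp,fpb free and bound fluorescence coefficients (one per replicate).
#' @slot residualNorm residual sum of squares of the fit.
#' @slot converged optimizer convergence flag.
#' @slot se named standard errors (log10Kd and coefficients).
#' @export
setClass("BindingFit",
  representation(kd = "numeric", fp = "numeric", fpb = "numeric",
                 residualNorm = "numeric", converged = "logical",
                 se = "numeric"))
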