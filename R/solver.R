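## Finite-difference linearized Poisson-Boltzmann solver.
##
## Discretization: div(eps grad phi) - eps_s kappa^2 phi = -4 pi C rho on a
## uniform cubic grid, two-dielectric model (solute interior = van der Waals
## union of atom spheres), mobile-ion term zeroed inside the solute plus a
## Stern layer, boundary nodes fixed to the per-atom screened-Coulomb sum.
## Potential is in kcal/(mol e) so that q * grad(phi) is directly a force in
## kcal/mol/A.

#' Size a cubic PB grid around a system
#'
#' The cubic box edge is the maximal system extent (including atomic radii)
#' divided by perfil/100; the grid dimension is the smallest odd integer of
#' at least box * scale + 1 grid points (odd so the centre is a node), the
#' same in all three directions, and the grid is centred on the system.
#'
#' @param system a [Structure-class] (or list of Structures taken together).
#' @param config a [SolverConfig-class].
#' @return a sized (incomplete) [GridGeometry-class].
#' @export
sizeGrid <- function(system, config = solverConfig()) {
  if (is(system, "Structure")) system <- list(system)
  stopifnot(length(system) > 0L)
  xyz <- do.call(rbind, lapply(system, coords))
  rad <- unlist(lapply(system, function(s) atoms(s)$radius))
  lo <- apply(xyz - rad, 2, min)
  hi <- apply(xyz + rad, 2, max)
  extent <- max(hi - lo)
  box <- extent / (config@perfil / 100)
  n <- ceiling(box * config@scale + 1)
  if (n %% 2L == 0L) n <- n + 1L
  n <- max(n, 5L)
  if (n > config@maxDims)
    stop(sprintf(paste("grid dimension %d exceeds the cap of %d;",
                       "use a coarser scale (fewer grids/A) or smaller perfil"),
                 n, config@maxDims), call. = FALSE)
  h <- 1 / config@scale
  centre <- (lo + hi) / 2
  origin <- centre - (n - 1) / 2 * h
  new("GridGeometry", origin = origin, spacing = h,
      dims = rep(as.integer(n), 3L), complete = FALSE)
}

#' Build an explicit PB grid geometry from box parameters
#'
#' Convenience constructor (mainly for controlled numerical experiments)
#' bypassing the perfil-based sizing.
#'
#' @param center box centre, A.
#' @param spacing grid spacing, A.
#' @param dims odd integer dimension (scalar or 3-vector).
#' @return a sized (incomplete) [GridGeometry-class].
#' @export
gridGeometry <- function(center = c(0, 0, 0), spacing = 1, dims = 65) {
  dims <- as.integer(rep_len(dims, 3L))
  stopifnot(all(dims %% 2L == 1L), spacing > 0)
  origin <- center - (dims - 1) / 2 * spacing
  new("GridGeometry", origin = origin, spacing = spacing, dims = dims,
      complete = FALSE)
}

## Mark array entries whose sample point lies within `radius` of `center`.
## offset: sample-point offset (in grid units) of the array relative to the
## node lattice, e.g. c(0.5, 0, 0) for x-edge midpoints.
.markInside <- function(arr, origin, h, offset, center, radius, value) {
  d <- dim(arr)
  idx <- vector("list", 3L)
  for (ax in 1:3) {
    gc <- (center[ax] - origin[ax]) / h - offset[ax]   # 0-based array coord
    lo <- max(0L, ceiling(gc - radius / h))
    hi <- min(d[ax] - 1L, floor(gc + radius / h))
    if (lo > hi) return(arr)
    idx[[ax]] <- lo:hi
  }
  dsq <- lapply(1:3, function(ax)
    (origin[ax] + (idx[[ax]] + offset[ax]) * h - center[ax])^2)
  D2 <- outer(outer(dsq[[1]], dsq[[2]], "+"), dsq[[3]], "+")
  sel <- D2 <= radius^2
  if (!any(sel)) return(arr)
  block <- arr[idx[[1]] + 1L, idx[[2]] + 1L, idx[[3]] + 1L, drop = FALSE]
  block[sel] <- value
  arr[idx[[1]] + 1L, idx[[2]] + 1L, idx[[3]] + 1L] <- block
  arr
}

## Trilinear spread of point charges onto the 8 surrounding nodes.
.spreadCharges <- function(source, origin, h, xyz, q, dims) {
  for (a in seq_along(q)) {
    if (q[a] == 0) next
    g <- (xyz[a, ] - origin) / h
    i0 <- floor(g)
    if (any(i0 < 0) || any(i0 > dims - 2L))
      stop(sprintf("charged atom %d lies outside the grid", a), call. = FALSE)
    f <- g - i0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) f[1] else 1 - f[1]) *
           (if (cy) f[2] else 1 - f[2]) *
           (if (cz) f[3] else 1 - f[3])
      ii <- i0 + c(cx, cy, cz) + 1L
      source[ii[1], ii[2], ii[3]] <- source[ii[1], ii[2], ii[3]] + q[a] * w
    }
  }
  source
}

#' Build the dielectric, screening and source maps of a PB problem
#'
#' The solute interior (dielectric `epsSolute`) is the union of the atom
#' spheres of the receptor and, when given, the ligand: the ligand
#' contributes shape only -- its charges are never spread, so the solved
#' field is the receptor's field in the presence of the uncharged ligand
#' cavity. The mobile-ion term is zeroed wherever a node falls inside any
#' atom radius plus the Stern layer. Receptor charges are spread to the 8
#' surrounding nodes with trilinear weights.
#'
#' @param receptor charged [Structure-class] (the field source).
#' @param ligand optional [Structure-class]; shape (cavity) only.
#' @param geometry a sized [GridGeometry-class] enclosing both molecules.
#' @param config a [SolverConfig-class].
#' @return the completed [GridGeometry-class].
#' @export
buildMaps <- function(receptor, ligand = NULL, geometry, config = solverConfig()) {
  stopifnot(is(receptor, "Structure"), is(geometry, "GridGeometry"))
  d <- geometry@dims; h <- geometry@spacing; o <- geometry@origin
  epsS <- config@epsSolvent
  epsX <- array(epsS, dim = c(d[1] - 1L, d[2], d[3]))
  epsY <- array(epsS, dim = c(d[1], d[2] - 1L, d[3]))
  epsZ <- array(epsS, dim = c(d[1], d[2], d[3] - 1L))
  kap2 <- .debyeKappaSq(config@saltMolar, epsS, config@temperature)
  kappaSq <- array(kap2, dim = d)
  source <- array(0, dim = d)

  shapeAtoms <- atoms(receptor)
  if (!is.null(ligand)) shapeAtoms <- rbind(shapeAtoms, atoms(ligand))
  top <- o + (d - 1L) * h
  for (a in seq_len(nrow(shapeAtoms))) {
    ctr <- as.numeric(shapeAtoms[a, c("x", "y", "z")])
    if (any(ctr < o) || any(ctr > top))
      stop(sprintf("atom %d lies outside the grid", a), call. = FALSE)
    r <- shapeAtoms$radius[a]
    if (r <= 0) next
    epsX <- .markInside(epsX, o, h, c(0.5, 0, 0), ctr, r, config@epsSolute)
    epsY <- .markInside(epsY, o, h, c(0, 0.5, 0), ctr, r, config@epsSolute)
    epsZ <- .markInside(epsZ, o, h, c(0, 0, 0.5), ctr, r, config@epsSolute)
    if (kap2 > 0)
      kappaSq <- .markInside(kappaSq, o, h, c(0, 0, 0), ctr,
                             r + config@sternLayer, 0)
  }
  recAtoms <- atoms(receptor)
  source <- .spreadCharges(source, o, h,
                           as.matrix(recAtoms[, c("x", "y", "z")]),
                           recAtoms$charge, d)
  geometry@epsX <- epsX; geometry@epsY <- epsY; geometry@epsZ <- epsZ
  geometry@kappaSq <- kappaSq; geometry@source <- source
  geometry@bcAtoms <- cbind(as.matrix(recAtoms[, c("x", "y", "z")]),
                            recAtoms$charge)
  geometry@complete <- TRUE
  geometry
}

## Boundary-node coordinates of a dims-shaped grid, plus their linear index.
.boundaryIndex <- function(d) {
  ix <- array(FALSE, dim = d)
  ix[c(1, d[1]), , ] <- TRUE
  ix[, c(1, d[2]), ] <- TRUE
  ix[, , c(1, d[3])] <- TRUE
  which(ix)
}

.nodeCoords <- function(linIdx, origin, h, d) {
  i0 <- (linIdx - 1L) %% d[1]
  j0 <- ((linIdx - 1L) %/% d[1]) %% d[2]
  k0 <- (linIdx - 1L) %/% (d[1] * d[2])
  cbind(origin[1] + i0 * h, origin[2] + j0 * h, origin[3] + k0 * h)
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Red-black SOR relaxation of the 7-point discretization, with boundary
#' nodes fixed to the sum of per-source-atom screened-Coulomb
#' (Debye-Hueckel) potentials. Iteration stops when the maximum per-sweep
#' potential change falls below `tolerance`; otherwise the returned grid is
#' flagged non-converged and carries the final residual.
#'
#' @param geometry a completed [GridGeometry-class].
#' @param config a [SolverConfig-class].
#' @param init optional [PotentialGrid-class] (or numeric array) used as
#'   the initial guess, e.g. the previous solution of a slowly changing
#'   system; defaults to zero in the interior.
#' @param bcValues optional precomputed boundary-node values (from
#'   [boundaryValues()]); since the boundary condition depends only on the
#'   source charges it can be cached across repeated solves on a fixed
#'   grid.
#' @return a [PotentialGrid-class].
#' @export
solvePB <- function(geometry, config = solverConfig(), init = NULL,
                    bcValues = NULL) {
  stopifnot(is(geometry, "GridGeometry"))
  if (!geometry@complete)
    stop("geometry is only sized; run buildMaps() first", call. = FALSE)
  d <- geometry@dims; h <- geometry@spacing; o <- geometry@origin
  phi <- array(0, dim = d)
  if (!is.null(init)) {
    vals <- if (is(init, "PotentialGrid")) init@values else init
    if (identical(dim(vals), as.integer(d))) phi <- vals
  }
  bIdx <- .boundaryIndex(d)
  if (is.null(bcValues)) bcValues <- boundaryValues(geometry, config)
  phi[bIdx] <- bcValues
  kappaTerm <- config@epsSolvent * geometry@kappaSq * h^2
  srcTerm <- 4 * pi * .kCoulomb * geometry@source / h
  ## arrays are REALSXPs; Rcpp wraps them without copying
  res <- .sorRelax(phi, d, geometry@epsX, geometry@epsY, geometry@epsZ,
                   kappaTerm, srcTerm, config@omega, config@tolerance,
                   config@maxIterations)
  if (!res$converged)
    warning(sprintf("PB solve not converged after %d sweeps (residual %.3e)",
                    res$iterations, res$residual))
  new("PotentialGrid", origin = o, spacing = h, dims = d,
      values = array(res$phi, dim = d), converged = res$converged,
      residual = res$residual, iterations = as.integer(res$iterations))
}

#' Boundary-condition values of a PB problem
#'
#' Screened-Coulomb (Debye-Hueckel) potential of the source charges at the
#' grid boundary nodes. Depends only on the source atoms and the grid, so
#' repeated solves on a fixed grid can cache it.
#'
#' @param geometry a completed [GridGeometry-class].
#' @param config a [SolverConfig-class].
#' @return numeric vector over the boundary nodes (in `.boundaryIndex`
#'   order).
#' @export
boundaryValues <- function(geometry, config = solverConfig()) {
  d <- geometry@dims
  bIdx <- .boundaryIndex(d)
  if (nrow(geometry@bcAtoms) == 0 || all(geometry@bcAtoms[, 4] == 0))
    return(numeric(length(bIdx)))
  kappa <- sqrt(.debyeKappaSq(config@saltMolar, config@epsSolvent,
                              config@temperature))
  .dhPotential(.nodeCoords(bIdx, geometry@origin, geometry@spacing, d),
               geometry@bcAtoms, .kCoulomb, config@epsSolvent, kappa)
}

#' Carve an uncharged ligand cavity into prebuilt maps
#'
#' Returns a copy of `geometry` whose dielectric maps are additionally set
#' to `epsSolute` inside the ligand atoms and whose screening map is zeroed
#' within the ligand plus the Stern layer. With a rigid receptor this lets
#' the expensive receptor maps be built once and the (small) ligand cavity
#' re-carved every steering cycle.
#'
#' @param geometry a completed [GridGeometry-class] (receptor maps).
#' @param ligand a [Structure-class]; shape only, charges ignored.
#' @param config a [SolverConfig-class].
#' @return the modified [GridGeometry-class].
#' @export
carveCavity <- function(geometry, ligand, config = solverConfig()) {
  stopifnot(geometry@complete, is(ligand, "Structure"))
  h <- geometry@spacing; o <- geometry@origin
  la <- atoms(ligand)
  top <- o + (geometry@dims - 1L) * h
  kap2 <- .debyeKappaSq(config@saltMolar, config@epsSolvent,
                        config@temperature)
  for (a in seq_len(nrow(la))) {
    ctr <- as.numeric(la[a, c("x", "y", "z")])
    if (any(ctr < o) || any(ctr > top))
      stop(sprintf("ligand atom %d lies outside the grid", a), call. = FALSE)
    r <- la$radius[a]
    if (r <= 0) next
    geometry@epsX <- .markInside(geometry@epsX, o, h, c(0.5, 0, 0), ctr, r,
                                 config@epsSolute)
    geometry@epsY <- .markInside(geometry@epsY, o, h, c(0, 0.5, 0), ctr, r,
                                 config@epsSolute)
    geometry@epsZ <- .markInside(geometry@epsZ, o, h, c(0, 0, 0.5), ctr, r,
                                 config@epsSolute)
    if (kap2 > 0)
      geometry@kappaSq <- .markInside(geometry@kappaSq, o, h, c(0, 0, 0),
                                      ctr, r + config@sternLayer, 0)
  }
  geometry
}

#' Trilinear interpolation of a potential grid
#'
#' @param grid a [PotentialGrid-class].
#' @param points n x 3 matrix of positions, A.
#' @return numeric vector of interpolated potentials, kcal/(mol e).
#' @export
potentialAt <- function(grid, points) {
  stopifnot(is(grid, "PotentialGrid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  d <- grid@dims; h <- grid@spacing; o <- grid@origin
  g <- sweep(points, 2, o) / h
  if (any(g < 0) || any(sweep(g, 2, d - 1L) > 0))
    stop("interpolation point outside the grid", call. = FALSE)
  i0 <- pmin(floor(g), matrix(rep(d - 2L, each = nrow(g)), ncol = 3L))
  f <- g - i0
  v <- grid@values
  out <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    out <- out + w * v[cbind(i0[, 1] + cx + 1L, i0[, 2] + cy + 1L,
                             i0[, 3] + cz + 1L)]
  }
  out
}
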