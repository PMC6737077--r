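## Shared builders for tiny test systems.

## A bare point charge (no cavity: radius 0) for uniform-dielectric tests.
pointCharge <- function(q = 1, pos = c(0, 0, 0), radius = 0, serial = 1L) {
  newStructure(serial = serial, atomName = "X", x = pos[1], y = pos[2],
               z = pos[3], charge = q, radius = radius)
}

## A random small charged structure (fields held at PQR printed precision
## so file round-trips are exact).
randomStructure <- function(n, seed, box = 6, qmax = 1, radius = 1.6,
                            center = c(0, 0, 0)) {
  set.seed(seed)
  newStructure(serial = seq_len(n), atomName = "C",
               x = round(runif(n, -box, box) + center[1], 3),
               y = round(runif(n, -box, box) + center[2], 3),
               z = round(runif(n, -box, box) + center[3], 3),
               charge = round(runif(n, -qmax, qmax), 4), radius = radius)
}

## Uniform-dielectric solve of a set of point charges (no cavity).
solveUniform <- function(structure, dims = 65, spacing = 0.5,
                         salt = 0, eps = 80, center = c(0, 0, 0), ...) {
  cfg <- solverConfig(saltMolar = salt, epsSolvent = eps, sternLayer = 0, ...)
  gm <- buildMaps(structure, NULL, gridGeometry(center, spacing, dims), cfg)
  list(phi = solvePB(gm, cfg), cfg = cfg, gm = gm)
}

kCoulombTest <- 332.0636
kBoltzTest <- 0.0019872041
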