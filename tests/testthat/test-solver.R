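test_that("grid sizing follows the perfil/scale formula", {
  mk <- function(extent) newStructure(serial = 1:2, atomName = "C",
    x = c(0, extent), y = 0, z = 0, charge = 0, radius = 0)
  ## 105 A extent, perfil 70, 2 grids/A: the standard ~300^3 mesh
  g <- sizeGrid(mk(105), solverConfig(perfil = 70, scale = 2))
  expect_identical(gridDims(g), rep(301L, 3))
  ## 31.5 A extent, perfil 70, 1 grid/A: box 45 A, 47 nodes
  g2 <- sizeGrid(mk(31.5), solverConfig(perfil = 70, scale = 1))
  expect_identical(gridDims(g2), rep(47L, 3))
  ## perfil 100: no inflation
  g3 <- sizeGrid(mk(10), solverConfig(perfil = 100, scale = 1))
  expect_identical(gridDims(g3), rep(11L, 3))
  ## the hard cap advises a coarser scale
  expect_error(sizeGrid(mk(500), solverConfig(scale = 2)), "coarser scale")
  ## radii inflate the extent and the grid is centred
  s <- newStructure(serial = 1L, atomName = "C", x = 5, y = 5, z = 5,
                    charge = 0, radius = 2)
  g4 <- sizeGrid(s, solverConfig(perfil = 50, scale = 1))
  ctr <- gridOrigin(g4) + (gridDims(g4) - 1) / 2 * gridSpacing(g4)
  expect_equal(ctr, c(5, 5, 5), tolerance = 1e-9)
})

test_that("charge spreading uses exact trilinear weights", {
  cfg <- solverConfig(saltMolar = 0)
  ## charge exactly on a node
  gm <- buildMaps(pointCharge(1, c(0, 0, 0)), NULL,
                  gridGeometry(c(0, 0, 0), 1, 9), cfg)
  expect_equal(gm@source[5, 5, 5], 1)
  expect_equal(sum(gm@source), 1, tolerance = 1e-12)
  expect_equal(sum(gm@source != 0), 1L)
  ## charge at a cell centre: eight nodes, 0.125 each
  gm2 <- buildMaps(pointCharge(1, c(0.5, 0.5, 0.5)), NULL,
                   gridGeometry(c(0, 0, 0), 1, 9), cfg)
  expect_equal(sum(gm2@source != 0), 8L)
  expect_equal(unique(round(gm2@source[gm2@source != 0], 12)), 0.125)
  ## total source equals the receptor net charge
  s <- randomStructure(12, seed = 2, box = 3)
  gm3 <- buildMaps(s, NULL, gridGeometry(c(0, 0, 0), 1, 17), cfg)
  expect_equal(sum(gm3@source), netCharge(s), tolerance = 1e-6)
  ## atom outside the grid is an error
  expect_error(buildMaps(pointCharge(1, c(30, 0, 0)), NULL,
                         gridGeometry(c(0, 0, 0), 1, 9), cfg), "outside")
})

test_that("dielectric maps carve the vdW union of receptor and ligand", {
  cfg <- solverConfig(saltMolar = 0.15, sternLayer = 2)
  atom <- pointCharge(0, c(0, 0, 0), radius = 2)
  gm <- buildMaps(atom, NULL, gridGeometry(c(0, 0, 0), 0.5, 21), cfg)
  ## x-edge midpoints within 2 A are solute; far edges solvent
  expect_equal(gm@epsX[11, 11, 11], cfg@epsSolute)  # 0.25 A from centre
  expect_equal(gm@epsX[1, 1, 1], cfg@epsSolvent)
  ## interior edge-midpoint count approximates the 2 A sphere volume
  inside <- sum(gm@epsX == cfg@epsSolute)
  expectVol <- 4 / 3 * pi * 2^3 / 0.5^3
  expect_lt(abs(inside - expectVol) / expectVol, 0.25)
  ## kappa is zeroed out to radius + Stern layer
  expect_equal(gm@kappaSq[11, 11, 11], 0)
  expect_equal(gm@kappaSq[11 + 7, 11, 11], 0)        # 3.5 A < 2 + 2
  expect_gt(gm@kappaSq[11 + 9, 11, 11], 0)           # 4.5 A > 4
  ## the ligand contributes shape but never charge
  lig <- pointCharge(5, c(2.5, 0, 0), radius = 1)
  gm2 <- buildMaps(atom, lig, gridGeometry(c(0, 0, 0), 0.5, 21), cfg)
  expect_equal(sum(gm2@source), 0, tolerance = 1e-12)
  expect_equal(gm2@epsX[16, 11, 11], cfg@epsSolute)  # inside the ligand
})

test_that("zero charge gives the identically zero potential", {
  gm <- buildMaps(pointCharge(0, radius = 1.5), NULL,
                  gridGeometry(c(0, 0, 0), 1, 17), solverConfig())
  phi <- solvePB(gm, solverConfig())
  expect_true(all(gridValues(phi) == 0))
  expect_true(isConverged(phi))
})

test_that("solver reproduces the Coulomb potential in uniform dielectric", {
  res <- solveUniform(pointCharge(1), dims = 65, spacing = 0.5)
  for (r in c(4, 5, 8, 10)) {
    exact <- kCoulombTest / (80 * r)
    for (p in list(c(r, 0, 0), c(0, -r, 0), rep(r / sqrt(3), 3)))
      expect_lt(abs(potentialAt(res$phi, p) / exact - 1), 0.05)
  }
})

test_that("solver reproduces Debye-Hueckel screening at 0.15 M", {
  res <- solveUniform(pointCharge(1), dims = 65, spacing = 0.5, salt = 0.15)
  kappa <- sqrt(8 * pi * kCoulombTest * 0.15 * 6.02214076e-4 /
                (80 * kBoltzTest * 300))
  for (r in c(5, 6, 8, 10)) {
    exact <- kCoulombTest / (80 * r) * exp(-kappa * r)
    expect_lt(abs(potentialAt(res$phi, c(r, 0, 0)) / exact - 1), 0.07)
    expect_lt(abs(potentialAt(res$phi, c(0, 0, -r)) / exact - 1), 0.07)
  }
})

test_that("mirror symmetry of the discretized operator is exact", {
  s <- newStructure(serial = 1:2, atomName = "C", x = c(-3.5, 2), y = c(1, -2),
                    z = c(0.5, 1.5), charge = c(1, -0.6), radius = 1.5)
  cfg <- solverConfig(saltMolar = 0.15)
  gm <- buildMaps(s, NULL, gridGeometry(c(0, 0, 0), 1, 33), cfg)
  phi <- solvePB(gm, cfg)
  refl <- s
  coords(refl) <- -coords(s)
  gmR <- buildMaps(refl, NULL, gridGeometry(c(0, 0, 0), 1, 33), cfg)
  phiR <- solvePB(gmR, cfg)
  v <- gridValues(phi)
  vR <- gridValues(phiR)[33:1, 33:1, 33:1]
  expect_lt(max(abs(v - vR)), 1e-10 * max(abs(v)))
})

test_that("superposition holds for the linear PBE", {
  cfg <- solverConfig(saltMolar = 0.15)
  q1 <- pointCharge(1, c(-4, 0, 0))
  q2 <- pointCharge(-0.5, c(3, 2, 0), serial = 2L)
  both <- combineStructures(q1, q2)
  g <- function(struct) solvePB(buildMaps(struct, NULL,
    gridGeometry(c(0, 0, 0), 1, 33), cfg), cfg)
  vSum <- gridValues(g(q1)) + gridValues(g(q2))
  vBoth <- gridValues(g(both))
  expect_lt(max(abs(vBoth - vSum)), 10 * cfg@tolerance)
})

test_that("salt strictly screens the potential of a positive charge", {
  phi0 <- solveUniform(pointCharge(1), dims = 33, spacing = 1)$phi
  phiSalt <- solveUniform(pointCharge(1), dims = 33, spacing = 1,
                          salt = 0.15)$phi
  pts <- rbind(c(5, 0, 0), c(0, 8, 0), c(0, 0, -10), c(6, 6, 6), c(-9, 3, 2))
  expect_true(all(potentialAt(phiSalt, pts) < potentialAt(phi0, pts)))
  expect_true(all(potentialAt(phiSalt, pts) > 0))
})

test_that("grid refinement changes the Coulomb solution by under 3 percent", {
  coarse <- solveUniform(pointCharge(1), dims = 33, spacing = 1)$phi
  fine <- solveUniform(pointCharge(1), dims = 65, spacing = 0.5)$phi
  for (r in c(5, 8, 10)) {
    pc <- potentialAt(coarse, c(r, 0, 0))
    pf <- potentialAt(fine, c(r, 0, 0))
    expect_lt(abs(pf / pc - 1), 0.03)
  }
})

test_that("non-convergence is flagged with the residual", {
  cfg <- solverConfig(maxIterations = 3L, tolerance = 1e-10)
  gm <- buildMaps(pointCharge(1), NULL, gridGeometry(c(0, 0, 0), 1, 33), cfg)
  expect_warning(phi <- solvePB(gm, cfg), "not converged")
  expect_false(isConverged(phi))
  expect_gt(phi@residual, 0)
})

test_that("carved ligand cavity matches the maps built from scratch", {
  rec <- makeFunnelReceptor()
  lig <- placeLigand(rec, makePolyamineLigand("spermidine"), "+X", 20,
                     seed = 3)
  cfg <- solverConfig(scale = 1)
  geom <- sizeGrid(list(rec, lig), cfg)
  full <- buildMaps(rec, lig, geom, cfg)
  carved <- carveCavity(buildMaps(rec, NULL, geom, cfg), lig, cfg)
  expect_identical(carved@epsX, full@epsX)
  expect_identical(carved@epsY, full@epsY)
  expect_identical(carved@epsZ, full@epsZ)
  expect_identical(carved@kappaSq, full@kappaSq)
})
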