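test_that("neutral atoms feel no grid force", {
  res <- solveUniform(pointCharge(1), dims = 33, spacing = 1)
  probe <- pointCharge(0, c(7, 3, -2))
  fs <- forcesFromPotential(res$phi, probe)
  expect_equal(forces(fs), matrix(0, 1, 3))
  expect_equal(appliedFactor(fs), 1)
})

test_that("grid force matches the analytic Coulomb force", {
  res <- solveUniform(pointCharge(1), dims = 65, spacing = 0.5)
  probe <- pointCharge(1, c(10, 0, 0))
  fs <- forcesFromPotential(res$phi, probe)
  exact <- kCoulombTest / (80 * 10^2)
  expect_lt(abs(forces(fs)[1, 1] / exact - 1), 0.05)   # repulsive, along x
  expect_gt(forces(fs)[1, 1], 0)
  expect_lt(max(abs(forces(fs)[1, 2:3])), 0.02 * exact)
  ## sign flips with the probe charge (linearity)
  fsNeg <- forcesFromPotential(res$phi, pointCharge(-1, c(10, 0, 0)))
  expect_equal(forces(fsNeg), -forces(fs), tolerance = 1e-12)
})

test_that("summed force projection matches the energy derivative", {
  ## receptor with structure (not a pure monopole), multi-atom ligand
  rec <- newStructure(serial = 1:3, atomName = "C",
                      x = c(-2, 0, 1.5), y = c(0, 2, -1), z = c(1, 0, -0.5),
                      charge = c(-2, 1, -1.5), radius = 0)
  cfg <- solverConfig(saltMolar = 0.15, sternLayer = 0)
  gm <- buildMaps(rec, NULL, gridGeometry(c(0, 0, 0), 0.5, 81), cfg)
  phi <- solvePB(gm, cfg)
  lig <- newStructure(serial = 1:3, atomName = "C",
                      x = c(9, 10.5, 12), y = c(0.5, 0, -0.5), z = 0,
                      charge = c(1, 1, 1), radius = 0)
  fs <- forcesFromPotential(phi, lig)
  fProj <- sum(forces(fs)[, 1])          # projection on the +x approach axis
  energyAt <- function(dx) {
    s <- lig
    cc <- coords(lig); cc[, 1] <- cc[, 1] + dx
    coords(s) <- cc
    sum(atoms(s)$charge * potentialAt(phi, coords(s)))
  }
  dUdd <- (energyAt(0.5) - energyAt(-0.5)) / 1
  expect_lt(abs(fProj - (-dUdd)) / abs(fProj), 0.05)
})

test_that("atoms too near the grid boundary are rejected by name", {
  res <- solveUniform(pointCharge(1), dims = 17, spacing = 1)
  probe <- pointCharge(1, c(7.5, 0, 0), serial = 42L)
  expect_error(forcesFromPotential(res$phi, probe), "atom 42")
})

test_that("window rescaling matches the lower/upper bound rules", {
  mags <- c(0.001, 0.002)
  dirs <- rbind(c(1, 0, 0), c(0, 0.6, 0.8))
  fs <- forceSet(dirs * mags)
  out <- rescaleToWindow(fs, forceWindow(0.01, 10))
  expect_equal(appliedFactor(out), 5)
  expect_equal(fMax(out), 0.01)
  expect_equal(max(sqrt(rowSums(forces(out)^2))), 0.01)
  ## inside the window: untouched
  fs2 <- forceSet(dirs * c(0.05, 2.0))
  out2 <- rescaleToWindow(fs2, forceWindow(0.01, 10))
  expect_equal(appliedFactor(out2), 1)
  expect_identical(forces(out2), forces(fs2))
  ## above the window: reduced onto the upper bound
  fs3 <- forceSet(dirs * c(4, 20))
  out3 <- rescaleToWindow(fs3, forceWindow(0.01, 10))
  expect_equal(appliedFactor(out3), 0.5)
  expect_equal(fMax(out3), 10)
})

test_that("rescaling preserves directions and is idempotent", {
  set.seed(8)
  F <- matrix(rnorm(30), 10, 3) * 10^runif(10, -4, 2)
  fs <- forceSet(F)
  for (w in list(forceWindow(0.01, 10), forceWindow(0.5, 2))) {
    out <- rescaleToWindow(fs, w)
    cosines <- rowSums(forces(out) * F) /
      (sqrt(rowSums(forces(out)^2)) * sqrt(rowSums(F^2)))
    expect_equal(cosines, rep(1, 10), tolerance = 1e-12)
    twice <- rescaleToWindow(out, w)
    expect_equal(forces(twice), forces(out), tolerance = 1e-12)
  }
  ## a zero field cannot be normalized
  z <- forceSet(matrix(0, 2, 3))
  expect_warning(outz <- rescaleToWindow(z, forceWindow(0.01, 10)), "zero")
  expect_equal(appliedFactor(outz), 1)
})

test_that("kcal/mol/A converts to pN with Avogadro arithmetic", {
  expect_equal(round(kcalPerMolAToPN(0.01), 1), 0.7)
  expect_equal(kcalPerMolAToPN(0), 0)
  expect_equal(kcalPerMolAToPN(1), 69.48, tolerance = 1e-3)
  expect_equal(kcalPerMolAToPN(1),
               4184 / (6.02214076e23 * 1e-10) * 1e12, tolerance = 1e-12)
})

test_that("grid forces match pairwise Coulomb sums on random systems", {
  set.seed(21)
  for (rep in 1:2) {
    rec <- randomStructure(4, seed = 30 + rep, box = 3, radius = 0)
    lig <- randomStructure(3, seed = 60 + rep, box = 2, radius = 0,
                           center = c(9, 0, 0))
    la <- atoms(lig)
    la$charge <- abs(la$charge) + 0.2
    lig <- new("Structure", atoms = la, label = "probe")
    cfg <- solverConfig(saltMolar = 0, sternLayer = 0)
    gm <- buildMaps(rec, NULL, gridGeometry(c(2, 0, 0), 0.5, 81), cfg)
    phi <- solvePB(gm, cfg)
    fs <- forcesFromPotential(phi, lig)
    ## pairwise Coulomb oracle in uniform eps = 80
    exact <- matrix(0, nAtoms(lig), 3)
    ra <- atoms(rec)
    for (i in seq_len(nAtoms(lig))) for (j in seq_len(nAtoms(rec))) {
      d <- coords(lig)[i, ] - coords(rec)[j, ]
      r <- sqrt(sum(d^2))
      exact[i, ] <- exact[i, ] +
        kCoulombTest * la$charge[i] * ra$charge[j] / (80 * r^2) * d / r
    }
    expect_lt(max(abs(forces(fs) - exact)) / max(abs(exact)), 0.05)
  }
})
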