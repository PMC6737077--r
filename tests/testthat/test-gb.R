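## Numeric-quadrature oracle for the HCT descreening integral:
## (1/4pi) int over the scaled neighbour sphere of |x - r_i|^-4, truncated
## below the intrinsic radius rho, by radial-shell quadrature.
hctOracle <- function(r, s, rho) {
  L <- max(rho, abs(r - s)); U <- r + s
  extra <- if (s - r > rho) 1 / rho - 1 / (s - r) else 0
  if (U <= L) return(extra)
  shell <- function(x) {
    cosT <- (x^2 + r^2 - s^2) / (2 * x * r)
    (1 - pmin(1, pmax(-1, cosT))) / 2 / x^2
  }
  stats::integrate(shell, L, U, rel.tol = 1e-10)$value + extra
}

test_that("Born radii: isolation, cutoff semantics and descreening", {
  cfg <- gbConfig()
  iso <- pointCharge(1, radius = 1.59)
  expect_equal(bornRadii(iso, cfg), 1.5)   # intrinsic = radius - 0.09
  ## a neighbour beyond the cutoff leaves the radius at the isolated value
  far <- newStructure(serial = 1:2, atomName = "C", x = c(0, 25), y = 0,
                      z = 0, charge = c(1, 0), radius = 1.59)
  expect_equal(bornRadii(far, cfg), c(1.5, 1.5))
  ## effective radii strictly grow as a neighbour approaches
  rads <- vapply(c(12, 9, 7, 5, 4), function(d) {
    s <- newStructure(serial = 1:2, atomName = "C", x = c(0, d), y = 0,
                      z = 0, charge = c(1, 0), radius = 1.59)
    bornRadii(s, cfg)[1]
  }, numeric(1))
  expect_true(all(diff(rads) > 0))
  expect_true(all(rads > 1.5))
  expect_error(bornRadii(newStructure(serial = 1:2, atomName = "C",
    x = c(0, 0), y = 0, z = 0, charge = 1, radius = 1.5), cfg),
    "overlapping")
})

test_that("HCT descreening integral matches radial quadrature", {
  for (r in c(4, 6, 9)) for (s in c(1.2, 1.8)) for (rho in c(1.5, 3.2)) {
    expect_equal(pbsteer:::.hctH(r, s, rho), hctOracle(r, s, rho),
                 tolerance = 1e-6)
  }
  ## overlapping (enclosing-neighbour) branch
  expect_equal(pbsteer:::.hctH(1.0, 1.4, 0.3), hctOracle(1.0, 1.4, 0.3),
               tolerance = 1e-6)
})

test_that("GB analytic forces match numerical energy derivatives", {
  cfg <- gbConfig()
  for (seed in 1:3) {
    rec <- randomStructure(4, seed = seed, box = 3, radius = 1.8)
    lig <- randomStructure(3, seed = seed + 50, box = 2, radius = 1.6,
                           center = c(7, 0, 0))
    fs <- gbForces(rec, lig, cfg)
    h <- 1e-5
    for (i in seq_len(nAtoms(lig))) for (ax in 1:3) {
      cp <- coords(lig); cp[i, ax] <- cp[i, ax] + h
      cm <- coords(lig); cm[i, ax] <- cm[i, ax] - h
      lp <- lig; coords(lp) <- cp
      lm <- lig; coords(lm) <- cm
      num <- -(gbEnergy(rec, lp, cfg) - gbEnergy(rec, lm, cfg)) / (2 * h)
      expect_equal(forces(fs)[i, ax], num, tolerance = 1e-4)
    }
  }
})

test_that("energy and force are continuous across the switching region", {
  cfg <- gbConfig(cutoff = 18, switchingStart = 16)
  probeAt <- function(d) {
    a <- pointCharge(1, radius = 1.59)
    b <- pointCharge(1, c(d, 0, 0), radius = 1.59)
    list(E = gbEnergy(a, b, cfg), F = forces(gbForces(a, b, cfg))[1, 1])
  }
  for (edge in c(16, 18)) {
    lo <- probeAt(edge - 1e-9)
    hi <- probeAt(edge + 1e-9)
    expect_lt(abs(lo$E - hi$E), 1e-8)
    expect_lt(abs(lo$F - hi$F), 1e-8)
  }
  ## identically zero beyond the cutoff
  expect_equal(probeAt(18.5)$F, 0)
  far <- probeAt(30)
  expect_equal(far$F, 0)
})

test_that("all pairs beyond cutoff give zero GB forces", {
  a <- pointCharge(1, c(0, 0, 0), radius = 2)
  b <- pointCharge(1, c(40, 0, 0), radius = 2)
  expect_equal(forces(gbForces(a, b)), matrix(0, 1, 3))
})

test_that("a neutral body outside all cutoffs leaves GB forces unchanged", {
  cfg <- gbConfig()
  ## interacting ion pair, neutral body beyond the cutoff of both
  src <- pointCharge(1, c(-6, 0, 0), radius = 2)
  rcv <- pointCharge(1, c(6, 0, 0), radius = 2)
  bodyAt <- function(y) {
    g <- expand.grid(x = (-1:1) * 3, y = (-1:1) * 3 + y, z = (-1:1) * 3)
    newStructure(serial = seq_len(nrow(g)), atomName = "C", x = g$x,
                 y = g$y, z = g$z, charge = 0, radius = 2)
  }
  f1 <- forces(gbForces(combineStructures(src, bodyAt(30)), rcv, cfg))
  f2 <- forces(gbForces(combineStructures(src, bodyAt(60)), rcv, cfg))
  expect_gt(abs(f1[1, 1]), 0)
  expect_lt(max(abs(f1 - f2)), 0.01 * max(abs(f1)))
})

test_that("two-ion contrast: GB is cutoff-blind where PB responds", {
  ## the supplementary-style toy comparison, desk scale: one source ion,
  ## one receiving ion, a neutral low-dielectric body either midway
  ## between them or displaced far off-axis
  gbArm <- function(intervening) {
    sys <- makeTwoIonSystem(separation = 60, intervening = intervening)
    forces(gbForces(combineStructures(sys$source, sys$body), sys$receiver))
  }
  pbArm <- function(intervening) {
    sys <- makeTwoIonSystem(separation = 60, intervening = intervening)
    rec <- combineStructures(sys$source, sys$body)
    cfg <- solverConfig(scale = 1, saltMolar = 0.15)
    gm <- buildMaps(rec, sys$receiver, sizeGrid(list(rec, sys$receiver), cfg),
                    cfg)
    forces(forcesFromPotential(solvePB(gm, cfg), sys$receiver))
  }
  gbIn <- gbArm(TRUE); gbOut <- gbArm(FALSE)
  pbIn <- pbArm(TRUE); pbOut <- pbArm(FALSE)
  mPbIn <- sqrt(sum(pbIn^2)); mPbOut <- sqrt(sum(pbOut^2))
  ## PB feels the intervening dielectric body
  expect_gt(abs(mPbIn - mPbOut) / max(mPbIn, mPbOut), 0.20)
  ## GB with its cutoffs cannot: both placements give (identically) nothing
  expect_lt(max(abs(gbIn - gbOut)), 0.01 * max(mPbIn, mPbOut))
})
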