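test_that("steering gate implements the all-atoms-beyond-cutoff rule", {
  expect_true(steeringGate(25, "cutoff", 18))
  expect_false(steeringGate(17.9, "cutoff", 18))
  expect_true(steeringGate(0.1, "accelerated", 18))
  expect_true(steeringGate(100, "accelerated", 18))
  expect_true(steeringGate(1, "scaled", 18))
  expect_false(steeringGate(100, "off", 18))
})

test_that("a 5000-step run with the default cycle logs exactly 10 PB solves", {
  rec <- makeFunnelReceptor()
  lig <- placeLigand(rec, makePolyamineLigand("spermidine"), "+X", 30,
                     seed = 2)
  cfg <- engineConfig(mode = "accelerated", totalSteps = 5000,
                      cycleSteps = 500, timestep = 2, seed = 2)
  scfg <- solverConfig(scale = 0.5, tolerance = 1e-3)
  run <- suppressWarnings(runSteeredDynamics(rec, lig, cfg, scfg))
  ev <- events(run)
  expect_equal(nrow(ev), 10L)
  expect_equal(sum(ev$pbSolved), 10L)
  expect_true(all(ev$steered))
  ## receptor coordinates never move and the trajectory has one frame/cycle
  expect_identical(coords(run@receptor), coords(rec))
  expect_length(trajectory(run), 10L)
  expect_equal(run@times, (1:10) * 500 * 2 / 1000)
})

test_that("an uncharged receptor produces no steering and no drift", {
  rec <- makeFunnelReceptor()
  a <- atoms(rec); a$charge <- 0
  recNeutral <- new("Structure", atoms = a, label = "neutral",
                    meta = structureMeta(rec))
  lig0 <- makePolyamineLigand("spermidine")
  drifts <- vapply(1:6, function(seed) {
    lig <- placeLigand(recNeutral, lig0, "+X", 40, seed = seed)
    cfg <- engineConfig(mode = "accelerated", totalSteps = 3000,
                        cycleSteps = 500, timestep = 5, seed = seed)
    run <- suppressWarnings(runSteeredDynamics(rec = recNeutral, lig, cfg,
                                    solverConfig(scale = 0.5)))
    ev <- events(run)
    expect_equal(max(ev$rawFMax), 0)
    expect_true(all(ev$factor == 1))
    ## displacement along the receptor direction (negative = toward it)
    d0 <- geometricCenter(lig) - geometricCenter(recNeutral)
    dIn <- sum((colMeans(trajectory(run)[[length(trajectory(run))]]) -
                geometricCenter(lig)) * d0 / sqrt(sum(d0^2)))
    dIn
  }, numeric(1))
  ## no systematic drift toward the receptor across seeds
  expect_gt(mean(drifts) + 2 * sd(drifts) / sqrt(length(drifts)), 0)
})

test_that("mode cutoff withholds steering once any atom enters the cutoff", {
  rec <- makeFunnelReceptor()
  lig <- placeLigand(rec, makePolyamineLigand("spermidine"), "+X", 25,
                     seed = 4)
  cfg <- engineConfig(mode = "cutoff", totalSteps = 2000, cycleSteps = 500,
                      timestep = 2, seed = 4, steeringCutoff = 18)
  run <- suppressWarnings(runSteeredDynamics(rec, lig, cfg, solverConfig(scale = 0.5)))
  ev <- events(run)
  expect_equal(ev$gate, ev$minPairDist > 18)
  expect_equal(ev$steered, ev$gate & ev$rawFMax > 0)
})

test_that("identical config and seed reproduce the trajectory bit for bit", {
  rec <- makeFunnelReceptor()
  lig <- placeLigand(rec, makePolyamineLigand("spermidine"), "+X", 30,
                     seed = 11)
  cfg <- engineConfig(mode = "accelerated", totalSteps = 2000,
                      cycleSteps = 500, timestep = 5, seed = 11)
  scfg <- solverConfig(scale = 0.5, tolerance = 1e-3)
  r1 <- suppressWarnings(runSteeredDynamics(rec, lig, cfg, scfg))
  r2 <- suppressWarnings(runSteeredDynamics(rec, lig, cfg, scfg))
  expect_identical(trajectory(r1), trajectory(r2))
  expect_identical(r1@velocities, r2@velocities)
})

test_that("far-field steering pulls a cationic ligand toward the receptor", {
  rec <- makeFunnelReceptor()
  lig <- placeLigand(rec, makePolyamineLigand("spermidine"), "+Y", 45,
                     seed = 6)
  cfg <- engineConfig(mode = "accelerated", totalSteps = 1000,
                      cycleSteps = 500, timestep = 2, seed = 6)
  scfg <- solverConfig(scale = 0.5, tolerance = 1e-3)
  geom <- buildMaps(rec, NULL, sizeGrid(list(rec, lig), scfg), scfg)
  phi <- solvePB(carveCavity(geom, lig, scfg), scfg)
  fs <- forcesFromPotential(phi, lig)
  net <- colSums(forces(fs))
  sep <- geometricCenter(lig) - geometricCenter(rec)
  expect_lt(sum(net * sep), 0)  # net force points back toward the receptor
})
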