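test_that("ligand RMSD: identity, rigid translation, joint-motion invariance", {
  lig <- makePolyamineLigand("spermidine")
  ref <- coords(lig)
  expect_equal(ligandRMSD(lig, ref), 0)
  shifted <- sweep(ref, 2, c(2, 0, 0), "+")
  expect_equal(ligandRMSD(shifted, ref), 2, tolerance = 1e-12)
  ## applying one rigid motion to frame and reference together (receptor
  ## included) leaves the RMSD unchanged
  set.seed(3)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
                2*(q[2]*q[3]+q[1]*q[4]), 1 - 2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
                2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1 - 2*(q[2]^2+q[3]^2)),
              3, 3, byrow = TRUE)
  t0 <- c(4, -2, 7)
  recRef <- coords(makeFunnelReceptor())
  frame <- shifted
  move <- function(m) sweep(m %*% t(R), 2, t0, "+")
  expect_equal(
    ligandRMSD(move(frame), ref, receptor = move(recRef), receptorRef = recRef),
    ligandRMSD(frame, ref), tolerance = 1e-6)
})

test_that("receptor-fit RMSD matches an independent best-fit oracle", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  for (rep in 1:4) {
    A <- matrix(rnorm(15, sd = 3), 5, 3)
    B <- matrix(rnorm(15, sd = 3), 5, 3)
    fit <- pbsteer:::.superposition(A, B)
    ours <- sqrt(mean(rowSums((fit(A) - B)^2)))
    oracle <- bio3d::rmsd(as.vector(t(B)), as.vector(t(A)), fit = TRUE)
    expect_equal(ours, oracle, tolerance = 2e-3)  # bio3d prints 3 decimals
  }
})

test_that("minimal-RMSD density ranks run sets by their minima", {
  lig <- makePolyamineLigand("spermidine")
  ref <- coords(lig)
  mkRun <- function(dists) lapply(dists, function(d)
    sweep(ref, 2, c(d, 0, 0), "+"))
  runsNear <- lapply(c(1, 1, 1, 9), function(m) mkRun(c(m + 3, m)))
  runsFar <- lapply(c(9, 9, 9, 1), function(m) mkRun(c(m + 3, m)))
  dNear <- minRMSDDensity(runsNear, ref)
  dFar <- minRMSDDensity(runsFar, ref)
  expect_equal(sort(dNear$minima), c(1, 1, 1, 9))
  massBelow <- function(d, x0) {
    dx <- diff(d$x[1:2]); sum(d$y[d$x < x0]) * dx
  }
  expect_gt(massBelow(dNear, 5), massBelow(dFar, 5))
  ## the density integrates to ~1
  expect_equal(sum(dNear$y) * diff(dNear$x[1:2]), 1, tolerance = 1e-3)
  expect_error(minRMSDDensity(list(), ref), "no runs")
})

test_that("contact counting matches hand-built geometry", {
  rec <- newStructure(serial = 1:3, atomName = "C",
                      resName = c("AAA", "AAA", "BBB"), chain = "R",
                      resNo = c(7L, 7L, 9L),
                      x = c(0, 1, 10), y = c(0, 3.5, 4.5), z = 0, radius = 2)
  lig <- newStructure(serial = 1L, atomName = "C", x = 0, y = 0, z = 0)
  ## frame: ligand at origin; residue 7 has atoms at 0 and ~3.64 A,
  ## residue 9 at ~11 A
  frame <- matrix(c(1, 3.45, 0), 1, 3)  # 3.45 A from atom1, 3.5 from atom2
  tab <- contactRanking(list(list(frame)), rec, lig, cutoff = 4)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$resNo, 7L)
  expect_equal(tab$count, 2)
  expect_equal(tab$percent, 100)
  ## far ligand: empty table
  tabEmpty <- contactRanking(list(list(matrix(c(50, 50, 50), 1, 3))), rec, lig)
  expect_equal(nrow(tabEmpty), 0L)
  ## frame order and atom order do not matter; percentages sum to 100
  rec2 <- newStructure(serial = 1:3, atomName = "C",
                       resName = c("BBB", "AAA", "AAA"), chain = "R",
                       resNo = c(9L, 7L, 7L),
                       x = c(10, 0, 1), y = c(4.5, 0, 3.5), z = 0, radius = 2)
  frames <- list(frame, matrix(c(9.2, 4.5, 0), 1, 3))
  t1 <- contactRanking(list(frames), rec, lig, cutoff = 4)
  t2 <- contactRanking(list(rev(frames)), rec2, lig, cutoff = 4)
  expect_equal(t1[order(t1$resNo), c("resNo", "count")],
               t2[order(t2$resNo), c("resNo", "count")])
  expect_equal(sum(t1$percent), 100)
})

test_that("hydrogens are excluded from contacts", {
  rec <- newStructure(serial = 1:2, atomName = c("C", "H1"), resName = "AAA",
                      chain = "R", resNo = c(1L, 2L), x = c(0, 0),
                      y = c(3, 3), z = 0, radius = 1.5)
  lig <- newStructure(serial = 1:2, atomName = c("C", "HB"), x = c(0, 0),
                      y = c(0, 0.5), z = 0)
  tab <- contactRanking(list(list(coords(lig))), rec, lig, cutoff = 4)
  expect_equal(tab$resNo, 1L)   # only the heavy receptor atom counts
  expect_equal(tab$count, 1)    # only the heavy ligand atom counts
})

test_that("RMSF: static zero, two-point alternation, isotropic jitter", {
  base <- coords(makePolyamineLigand("spermidine"))
  expect_equal(rmsf(list(base, base, base)), rep(0, 7), tolerance = 1e-12)
  ## an atom alternating +/- d along x around fixed others (frames already
  ## share the rigid receptor frame: no refitting)
  d <- 0.4
  up <- base; up[4, 1] <- up[4, 1] + d
  dn <- base; dn[4, 1] <- dn[4, 1] - d
  r <- rmsf(rep(list(up, dn), 50), fit = FALSE)
  expect_equal(r[4], d, tolerance = 1e-9)
  expect_equal(max(r[-4]), 0, tolerance = 1e-12)
  ## isotropic Gaussian jitter: RMSF -> sigma * sqrt(3)
  set.seed(5)
  sigma <- 0.3
  frames <- lapply(1:8000, function(i) base + matrix(rnorm(21, 0, sigma), 7, 3))
  rj <- rmsf(frames, fit = FALSE)
  expect_equal(mean(rj), sigma * sqrt(3), tolerance = 0.05)
  expect_error(rmsf(list(base)), "2 frames")
})

test_that("gate distance series recovers planted geometry and modes", {
  base <- coords(makePolyamineLigand("spermidine", nBeads = 5))
  f1 <- base; f1[1, ] <- colMeans(base[2:5, ])      # probe at the centroid
  expect_equal(gateDistanceSeries(list(f1), 1, 2:5)$series, 0, tolerance = 1e-12)
  f2 <- base
  f2[1, ] <- colMeans(base[2:5, ]) + c(3, 0, 0)
  expect_equal(gateDistanceSeries(list(f2), 1, 2:5)$series, 3, tolerance = 1e-12)
  expect_error(gateDistanceSeries(list(f1), 1, integer(0)), "empty")
  ## a planted two-state series shows both modes near the planted centres
  set.seed(13)
  frames <- lapply(c(rnorm(300, 11, 0.3), rnorm(300, 16, 0.3)), function(d) {
    f <- base; f[1, ] <- colMeans(base[2:5, ]) + c(d, 0, 0); f
  })
  gd <- gateDistanceSeries(frames, 1, 2:5)
  dens <- gd$density
  peaks <- dens$x[which(diff(sign(diff(dens$y))) == -2) + 1]
  expect_true(any(abs(peaks - 11) < 2 * dens$bw + 0.3))
  expect_true(any(abs(peaks - 16) < 2 * dens$bw + 0.3))
  expect_equal(sum(dens$y) * diff(dens$x[1:2]), 1, tolerance = 1e-3)
})
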