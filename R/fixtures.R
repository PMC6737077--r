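## Synthetic bead-level fixtures: a funnel-shaped charged receptor, flexible
## polyamine-like ligands, and a two-ion toy system with an optional
## intervening low-dielectric body. Bead-level (rather than atomistic)
## models keep PB grids small while preserving the monopole-driven physics
## the steering protocol exercises.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.axisVector <- function(direction) {
  if (is.numeric(direction)) {
    stopifnot(length(direction) == 3L, sum(direction^2) > 0)
    return(direction / sqrt(sum(direction^2)))
  }
  key <- toupper(gsub("\\s", "", direction))
  tab <- list("+X" = c(1, 0, 0), "-X" = c(-1, 0, 0),
              "+Y" = c(0, 1, 0), "-Y" = c(0, -1, 0),
              "+Z" = c(0, 0, 1), "-Z" = c(0, 0, -1),
              "X" = c(1, 0, 0), "Y" = c(0, 1, 0), "Z" = c(0, 0, 1))
  v <- tab[[key]]
  if (is.null(v)) stop("unknown axis label: ", direction, call. = FALSE)
  v
}

## Quasi-uniform points on the unit sphere (Fibonacci lattice).
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

## Rotation matrix carrying unit vector a onto unit vector b.
.rotationOnto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

.checkPacking <- function(xyz, radii, factor = 0.8) {
  if (nrow(xyz) < 2L) return(invisible(TRUE))
  d <- as.matrix(dist(xyz))
  contact <- outer(radii, radii, "+") * factor
  diag(d) <- Inf
  if (any(d < contact))
    stop("infeasible packing: beads overlap beyond the allowed tolerance",
         call. = FALSE)
  invisible(TRUE)
}

#' Build a funnel-shaped charged receptor fixture
#'
#' A rigid spherical shell of neutral beads with an open mouth (a cone
#' around `pocketDirection` left bead-free) and a recessed charged pocket: a
#' ring of beads near the shell centre carrying `pocketCharge` split
#' equally. The negative pocket buried in a low-dielectric shell with a
#' single aperture produces the electrostatic-funnel field pattern that
#' channels a cationic ligand through the mouth toward the pocket. The
#' pocket-centre coordinate is returned in `meta$pocketCenter`.
#'
#' @param nBeads total bead count (shell + pocket ring), >= 20.
#' @param shellRadius shell radius, A.
#' @param pocketDirection mouth axis (axis label or 3-vector).
#' @param pocketDepth recession of the pocket centre from the mouth, A
#'   (default: the shell radius, i.e. the pocket sits at the shell centre).
#' @param pocketCharge total pocket charge, e (negative).
#' @param rimCharge total charge spread over the shell beads, e (default 0).
#' @param nPocket number of pocket-lining beads.
#' @param beadRadius bead radius, A.
#' @param mouthAngle half-angle of the open mouth cone, degrees.
#' @param seed integer seed for the small placement jitter; the same seed
#'   reproduces the structure bit-identically.
#' @return a [Structure-class] with `meta$pocketCenter` and `meta$spec`.
#' @export
makeFunnelReceptor <- function(nBeads = 60, shellRadius = 10,
                               pocketDirection = "+X",
                               pocketDepth = shellRadius,
                               pocketCharge = -10, rimCharge = 0,
                               nPocket = 6, beadRadius = 2,
                               mouthAngle = 60, seed = 1) {
  stopifnot(nBeads >= 20, pocketCharge < 0, nPocket >= 3,
            nBeads > nPocket, shellRadius > 2 * beadRadius)
  dir <- .axisVector(pocketDirection)
  nShell <- nBeads - nPocket
  cosMouth <- cos(mouthAngle * pi / 180)
  ## oversample the Fibonacci lattice until enough points fall outside the
  ## mouth cone, then keep the nShell points deepest from the mouth axis
  nTry <- nShell
  repeat {
    pts <- .fibonacciSphere(nTry)
    keep <- pts %*% c(1, 0, 0) < cosMouth  # cone around +x before rotation
    if (sum(keep) >= nShell) break
    nTry <- ceiling(nTry * 1.25)
  }
  pts <- pts[keep, , drop = FALSE]
  ang <- drop(pts %*% c(1, 0, 0))
  pts <- pts[order(ang)[seq_len(nShell)], , drop = FALSE]
  rot <- .rotationOnto(c(1, 0, 0), dir)
  shell <- pts %*% t(rot) * shellRadius
  ## pocket ring, perpendicular to the mouth axis, slightly behind the
  ## pocket centre so the ligand can settle into it
  pocketCenter <- dir * (shellRadius - pocketDepth)
  ringR <- min(3.5, shellRadius - 2 * beadRadius)
  e1 <- rot %*% c(0, 1, 0); e2 <- rot %*% c(0, 0, 1)
  ## the pocket is a short channel: two staggered rings of beads 5 A
  ## apart along the mouth axis, so an extended polyamine-like chain
  ## binds between them and centres on the charge centroid by symmetry
  channelCentre <- pocketCenter - 1.5 * dir
  nA <- ceiling(nPocket / 2)
  ringOf <- function(n, offset, stagger) {
    a <- 2 * pi * (seq_len(n) - 1) / n + stagger
    t(vapply(a, function(t0) channelCentre + offset * dir +
               ringR * (cos(t0) * drop(e1) + sin(t0) * drop(e2)), numeric(3)))
  }
  ring <- rbind(ringOf(nA, -2.5, 0), ringOf(nPocket - nA, 2.5, pi / nA))
  xyz <- rbind(ring, shell)
  jitter <- .withSeed(seed, matrix(runif(length(xyz), -0.05, 0.05), nrow(xyz), 3))
  xyz <- xyz + jitter
  .checkPacking(xyz, rep(beadRadius, nrow(xyz)))
  charges <- c(rep(pocketCharge / nPocket, nPocket),
               rep(rimCharge / nShell, nShell))
  s <- newStructure(serial = seq_len(nBeads), atomName = "C",
                    resName = c(rep("POC", nPocket), rep("SHL", nShell)),
                    chain = "R", resNo = seq_len(nBeads),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    charge = charges, radius = beadRadius,
                    label = "funnel-receptor",
                    ## the binding site is where its charges are: annotate
                    ## the pocket centre as the centroid of the charged
                    ## pocket-lining beads
                    meta = list(pocketCenter = colMeans(xyz[seq_len(nPocket), ]),
                                mouthDirection = dir,
                                spec = list(nBeads = nBeads,
                                            shellRadius = shellRadius,
                                            pocketDepth = pocketDepth,
                                            pocketCharge = pocketCharge,
                                            rimCharge = rimCharge,
                                            beadRadius = beadRadius,
                                            mouthAngle = mouthAngle,
                                            seed = seed)))
  s
}

#' Build a flexible polyamine-like bead ligand
#'
#' A linear chain of beads connected by harmonic bonds (k = 100
#' kcal/mol/A^2) with harmonic angles (k = 10 kcal/mol/rad^2, equilibrium
#' 180 degrees). The default emulates a spermidine-like tricposition: 7
#' beads with +1 e on beads 1, 4 and 7 (net +3 e). The "adomet" variant
#' carries a single +1 e; "neutral" is an uncharged control.
#'
#' @param variant "spermidine" (+3 e), "adomet" (+1 e) or "neutral";
#'   ignored when `chargedBeads` is given explicitly.
#' @param nBeads chain length.
#' @param bondLength equilibrium bond length, A.
#' @param chargedBeads indices of the charged beads.
#' @param netCharge total charge, split equally over `chargedBeads`.
#' @param beadMass per-bead mass, amu (145 amu spermidine / 7 beads).
#' @param beadRadius bead radius, A.
#' @return a [Structure-class] with bonded topology and masses in `meta`.
#' @export
makePolyamineLigand <- function(variant = c("spermidine", "adomet", "neutral"),
                                nBeads = 7, bondLength = 1.5,
                                chargedBeads = NULL, netCharge = NULL,
                                beadMass = 20.75, beadRadius = 2) {
  variant <- match.arg(variant)
  if (is.null(chargedBeads)) {
    preset <- switch(variant,
      spermidine = list(idx = c(1L, 4L, 7L), q = 3),
      adomet = list(idx = 4L, q = 1),
      neutral = list(idx = integer(0), q = 0))
    chargedBeads <- preset$idx[preset$idx <= nBeads]
    if (is.null(netCharge)) netCharge <- preset$q
  }
  if (is.null(netCharge)) netCharge <- length(chargedBeads)
  if (length(chargedBeads) &&
      (any(chargedBeads < 1L) || any(chargedBeads > nBeads)))
    stop("charged bead indices out of range", call. = FALSE)
  charges <- numeric(nBeads)
  if (length(chargedBeads)) charges[chargedBeads] <- netCharge / length(chargedBeads)
  x <- (seq_len(nBeads) - (nBeads + 1) / 2) * bondLength
  bonds <- if (nBeads > 1L)
    cbind(i = seq_len(nBeads - 1L), j = 2:nBeads, r0 = bondLength, k = 100)
  else cbind(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0))
  angles <- if (nBeads > 2L)
    cbind(i = seq_len(nBeads - 2L), j = 2:(nBeads - 1L), k = 3:nBeads,
          theta0 = pi, kang = 10)
  else cbind(i = integer(0), j = integer(0), k = integer(0),
             theta0 = numeric(0), kang = numeric(0))
  newStructure(serial = seq_len(nBeads),
               atomName = paste0("C", seq_len(nBeads)),
               resName = "LIG", chain = "L", resNo = 1L,
               x = x, y = numeric(nBeads), z = numeric(nBeads),
               charge = charges, radius = beadRadius,
               label = paste0(variant, "-ligand"),
               meta = list(bonds = bonds, angles = angles,
                           mass = rep(beadMass, nBeads)))
}

#' Build the two-ion toy system
#'
#' One +1 e source ion and one +1 e receiving ion at a fixed separation
#' along x, plus a neutral low-dielectric bead cluster (the "receptor
#' body") placed either midway between the ions (`intervening = TRUE`) or
#' far off-axis at the same ion-ion distance. Comparing the force on the
#' receiving ion between the two placements separates models that sense the
#' dielectric environment (PB) from cutoff-truncated pairwise models (GB).
#'
#' @param separation ion-ion distance, A (default 60, which keeps every
#'   body bead outside the default 18 A GB cutoff of both ions).
#' @param intervening logical: place the body between the ions.
#' @param bodyRadius approximate body radius, A (beads on a 3 A lattice).
#' @return list with [Structure-class] elements `source`, `receiver`, `body`.
#' @export
makeTwoIonSystem <- function(separation = 60, intervening = TRUE,
                             bodyRadius = 10) {
  g <- expand.grid(x = seq(-3, 3) * 3, y = seq(-3, 3) * 3, z = seq(-3, 3) * 3)
  keep <- sqrt(g$x^2 + g$y^2 + g$z^2) <= bodyRadius
  body <- as.matrix(g[keep, ])
  bodyExtent <- max(sqrt(rowSums(body^2))) + 2
  if (intervening && separation <= 2 * bodyExtent)
    stop(sprintf("separation (%.1f A) must exceed twice the body extent (%.1f A)",
                 separation, bodyExtent), call. = FALSE)
  centre <- if (intervening) c(0, 0, 0) else c(0, max(60, separation), 0)
  body <- sweep(body, 2, centre, "+")
  ionR <- 2
  mkIon <- function(xpos, lab) newStructure(
    serial = 1L, atomName = "NA", resName = "ION", chain = "I", resNo = 1L,
    x = xpos, y = 0, z = 0, charge = 1, radius = ionR, label = lab)
  src <- mkIon(-separation / 2, "source-ion")
  rec <- mkIon(separation / 2, "receiver-ion")
  ions <- rbind(coords(src), coords(rec))
  dmin <- min(sqrt(rowSums((body[rep(seq_len(nrow(body)), each = 2), ] -
                            ions[rep(1:2, nrow(body)), ])^2)))
  if (dmin < ionR + 2)
    stop("geometric overlap between body and ions", call. = FALSE)
  bodyStruct <- newStructure(
    serial = seq_len(nrow(body)), atomName = "C", resName = "BOD",
    chain = "B", resNo = seq_len(nrow(body)),
    x = body[, 1], y = body[, 2], z = body[, 3],
    charge = 0, radius = 2, label = "neutral-body",
    meta = list(intervening = intervening))
  list(source = src, receiver = rec, body = bodyStruct)
}

#' Place a ligand at a distance from a receptor along an axis
#'
#' Translates the ligand so its geometric centre sits `distance` Angstrom
#' from the receptor geometric centre along `direction`, after applying a
#' random rigid rotation drawn from the seeded RNG.
#'
#' @param receptor,ligand [Structure-class] objects.
#' @param direction axis label ("+X", "-Y", ...) or 3-vector.
#' @param distance centre-to-centre distance, A; must exceed the receptor
#'   bounding radius.
#' @param seed integer seed for the random orientation.
#' @return the translated/rotated ligand [Structure-class].
#' @export
placeLigand <- function(receptor, ligand, direction = "+X", distance = 60,
                        seed = 1) {
  stopifnot(is(receptor, "Structure"), is(ligand, "Structure"))
  rc <- colMeans(coords(receptor))
  rrad <- max(sqrt(rowSums(sweep(coords(receptor), 2, rc)^2)) +
              atoms(receptor)$radius)
  if (!(distance > rrad))
    stop(sprintf("distance (%.1f A) must exceed the receptor bounding radius (%.1f A)",
                 distance, rrad), call. = FALSE)
  dir <- .axisVector(direction)
  xyz <- coords(ligand)
  lc <- colMeans(xyz)
  xyz <- sweep(xyz, 2, lc)
  rot <- .withSeed(seed, {
    ## uniform random rotation from a normalized quaternion
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, rc + distance * dir, "+")
  ## reject atom-atom overlap with the receptor
  rxyz <- coords(receptor)
  rr <- atoms(receptor)$radius; lr <- atoms(ligand)$radius
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt(rowSums(sweep(rxyz, 2, xyz[i, ])^2))
    if (any(d < rr + lr[i]))
      stop("placed ligand overlaps the receptor", call. = FALSE)
  }
  coords(ligand) <- xyz
  ligand
}
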