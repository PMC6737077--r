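## Minimal pairwise Generalized-Born electrostatics with distance cutoffs:
## HCT-style pairwise-descreening Born radii and Still's interaction
## function, with direct (eps = 1) Coulomb for pairs inside the cutoff.
## All r-dependent terms -- including the descreening sum -- are smoothly
## switched to zero between switchingStart and cutoff, so energy and forces
## are continuous while the model remains strictly blind beyond the cutoff:
## precisely the truncation artifact the PB arm exposes.

## CHARMM-style switching function and derivative on [on, off].
.switchFun <- function(r, on, off) {
  s <- ifelse(r <= on, 1, ifelse(r >= off, 0,
    ((off^2 - r^2)^2 * (off^2 + 2 * r^2 - 3 * on^2)) / (off^2 - on^2)^3))
  ds <- ifelse(r <= on | r >= off, 0,
    12 * r * (off^2 - r^2) * (on^2 - r^2) / (off^2 - on^2)^3)
  list(s = s, ds = ds)
}

## HCT descreening integral: (1/4pi) * integral over the (scaled) sphere of
## neighbour j of |x - r_i|^-4, truncated below the intrinsic radius rho of
## atom i. r = centre distance, s = scaled neighbour radius.
.hctH <- function(r, s, rho) {
  U <- r + s
  L <- pmax(rho, abs(r - s))
  h <- 0.5 * ((1 / L - 1 / U) - log(U / L) / (2 * r) +
              (r^2 - s^2) / (4 * r) * (1 / U^2 - 1 / L^2))
  ## shells below |r - s| with an enclosing neighbour (s > r) lie entirely
  ## inside it: integrand is x^-2 from rho up to s - r
  h <- h + ifelse(s - r > rho, 1 / rho - 1 / pmax(s - r, rho), 0)
  h[U <= L] <- 0
  h
}

## dH/dr, accounting for dU/dr = 1 and dL/dr = +/-1 when L = |r - s| > rho.
.hctHderiv <- function(r, s, rho) {
  U <- r + s
  L <- pmax(rho, abs(r - s))
  dL <- ifelse(r - s > rho, 1, ifelse(s - r > rho, -1, 0))
  a <- r^2 - s^2
  expl <- 0.5 * (log(U / L) / (2 * r^2) + (r^2 + s^2) / (4 * r^2) *
                 (1 / U^2 - 1 / L^2))
  dHdU <- 0.5 * (1 / U^2 - 1 / (2 * r * U) - a / (2 * r) / U^3)
  dHdL <- 0.5 * (-1 / L^2 + 1 / (2 * r * L) + a / (2 * r) / L^3)
  out <- expl + dHdU + dHdL * dL
  out <- out + ifelse(s - r > rho, -1 / (s - r)^2, 0)
  out[U <= L] <- 0
  out
}

#' Effective Born radii with cutoff descreening
#'
#' Pairwise-descreening (HCT-style) effective radii: the inverse Born
#' radius of each atom is its inverse intrinsic radius minus the switched
#' sum of descreening integrals over neighbours within the cutoff. An
#' isolated atom recovers its intrinsic radius exactly; any neighbour
#' beyond the cutoff contributes nothing.
#'
#' @param system a [Structure-class] (all atoms descreen, charged or not).
#' @param cfg a [GBConfig-class].
#' @return numeric vector of effective Born radii, A.
#' @export
bornRadii <- function(system, cfg = gbConfig()) {
  stopifnot(is(system, "Structure"))
  xyz <- coords(system)
  rho <- pmax(atoms(system)$radius - cfg@radiusOffset, 0.5)
  n <- nrow(xyz)
  inv <- 1 / rho
  if (n > 1L) {
    D <- as.matrix(dist(xyz))
    if (any(D[upper.tri(D)] < 1e-6))
      stop("overlapping identical atoms", call. = FALSE)
    s <- cfg@radiusScale * rho
    for (i in seq_len(n)) {
      nb <- which(D[i, ] < cfg@cutoff & seq_len(n) != i)
      if (!length(nb)) next
      r <- D[i, nb]
      sw <- .switchFun(r, cfg@switchingStart, cfg@cutoff)
      inv[i] <- inv[i] - sum(.hctH(r, s[nb], rho[i]) * sw$s)
    }
  }
  if (any(inv <= 0))
    stop("descreening sum exceeds the intrinsic term (severe overlap)",
         call. = FALSE)
  1 / inv
}

## Internal: GB + direct Coulomb energy and analytic gradient for a
## combined system. Returns list(energy, grad (n x 3), born).
.gbEnergyGrad <- function(xyz, q, rho, cfg, wantGrad = TRUE) {
  n <- nrow(xyz)
  epsFac <- 1 - 1 / cfg@epsSolvent
  s <- cfg@radiusScale * rho
  D <- as.matrix(dist(xyz))
  if (n > 1L && any(D[upper.tri(D)] < 1e-6))
    stop("overlapping identical atoms", call. = FALSE)

  ## switched descreening sums and Born radii
  inv <- 1 / rho
  Hmat <- matrix(0, n, n); dHmat <- matrix(0, n, n)
  Smat <- matrix(0, n, n); dSmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < cfg@cutoff & seq_len(n) != i)
    if (!length(nb)) next
    r <- D[i, nb]
    sw <- .switchFun(r, cfg@switchingStart, cfg@cutoff)
    Hmat[i, nb] <- .hctH(r, s[nb], rho[i]) * sw$s
    dHmat[i, nb] <- .hctHderiv(r, s[nb], rho[i]) * sw$s +
                    .hctH(r, s[nb], rho[i]) * sw$ds
    Smat[i, nb] <- sw$s; dSmat[i, nb] <- sw$ds
    inv[i] <- inv[i] - sum(Hmat[i, nb])
  }
  if (any(inv <= 0))
    stop("descreening sum exceeds the intrinsic term (severe overlap)",
         call. = FALSE)
  R <- 1 / inv

  kC <- .kCoulomb
  E <- -kC / 2 * epsFac * sum(q^2 / R)        # self (solvation) terms
  dEdR <- kC / 2 * epsFac * q^2 / R^2          # dE_self/dR_i
  dEdr <- matrix(0, n, n)                      # direct pair r-derivatives
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- D[i, j]
      if (r >= cfg@cutoff || q[i] == 0 && q[j] == 0) next
      sw <- .switchFun(r, cfg@switchingStart, cfg@cutoff)
      ee <- exp(-r^2 / (4 * R[i] * R[j]))
      f <- sqrt(r^2 + R[i] * R[j] * ee)
      Ec <- kC * q[i] * q[j] / r
      Eg <- -kC * epsFac * q[i] * q[j] / f
      E <- E + sw$s * (Ec + Eg)
      if (wantGrad) {
        dfdr <- r * (1 - ee / 4) / f
        dEcdr <- -kC * q[i] * q[j] / r^2
        dEgdf <- kC * epsFac * q[i] * q[j] / f^2
        dEdr[i, j] <- dEdr[i, j] + sw$ds * (Ec + Eg) +
                      sw$s * (dEcdr + dEgdf * dfdr)
        dfdRi <- ee * (R[j] + r^2 / (4 * R[i])) / (2 * f)
        dfdRj <- ee * (R[i] + r^2 / (4 * R[j])) / (2 * f)
        dEdR[i] <- dEdR[i] + sw$s * dEgdf * dfdRi
        dEdR[j] <- dEdR[j] + sw$s * dEgdf * dfdRj
      }
    }
  }
  if (!wantGrad) return(list(energy = E, grad = NULL, born = R))

  ## chain rule through the Born radii: dR_i/dr_ij = R_i^2 * d(H S)/dr
  grad <- matrix(0, n, 3L)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- D[i, j]
        tot <- dEdr[i, j] +
               dEdR[i] * R[i]^2 * dHmat[i, j] +
               dEdR[j] * R[j]^2 * dHmat[j, i]
        if (tot == 0) next
        u <- (xyz[i, ] - xyz[j, ]) / r
        grad[i, ] <- grad[i, ] + tot * u
        grad[j, ] <- grad[j, ] - tot * u
      }
    }
  }
  list(energy = E, grad = grad, born = R)
}

#' Generalized-Born + Coulomb energy of a receptor-ligand system
#'
#' Still pairwise GB energy (with HCT Born radii) plus direct Coulomb for
#' pairs within the cutoff, all smoothly switched. Used both as the
#' comparison arm against the PB steering forces and as the correction term
#' of the "scaled" steering mode.
#'
#' @param receptor,ligand [Structure-class] objects (ligand optional).
#' @param cfg a [GBConfig-class].
#' @return energy in kcal/mol.
#' @export
gbEnergy <- function(receptor, ligand = NULL, cfg = gbConfig()) {
  a <- atoms(receptor)
  if (!is.null(ligand)) a <- rbind(a, atoms(ligand))
  res <- .gbEnergyGrad(unname(as.matrix(a[, c("x", "y", "z")])), a$charge,
                       pmax(a$radius - cfg@radiusOffset, 0.5), cfg,
                       wantGrad = FALSE)
  res$energy
}

#' Generalized-Born forces on ligand atoms
#'
#' Analytic derivative of [gbEnergy()] (including the Born-radius chain
#' rule), restricted to the ligand atoms.
#'
#' @param receptor,ligand charged [Structure-class] objects.
#' @param cfg a [GBConfig-class].
#' @return a [ForceSet-class] over the ligand atoms, kcal/mol/A.
#' @export
gbForces <- function(receptor, ligand, cfg = gbConfig()) {
  ra <- atoms(receptor); la <- atoms(ligand)
  a <- rbind(ra, la)
  res <- .gbEnergyGrad(unname(as.matrix(a[, c("x", "y", "z")])), a$charge,
                       pmax(a$radius - cfg@radiusOffset, 0.5), cfg,
                       wantGrad = TRUE)
  idx <- nrow(ra) + seq_len(nrow(la))
  F <- -res$grad[idx, , drop = FALSE]
  new("ForceSet", atomSerials = la$serial, forces = F,
      fMax = max(sqrt(rowSums(F^2))), appliedFactor = 1)
}
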