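## Post-hoc trajectory statistics: ligand RMSD against a reference pose,
## minimal-RMSD probability densities over replicate runs, contact-residue
## ranking, per-atom RMSF and pocket-gate distance distributions.

## Kabsch: rotation R (3x3) such that P %*% R best matches Q (both centred).
.kabschRotation <- function(P, Q) {
  C <- crossprod(P, Q)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## Rigid transform (rotation + translation) superposing mobile onto target;
## returns a function applying it to any n x 3 matrix.
.superposition <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  R <- .kabschRotation(sweep(mobile, 2, cm), sweep(target, 2, ct))
  function(xyz) sweep(sweep(xyz, 2, cm) %*% R, 2, ct, "+")
}

.frameCoords <- function(x) {
  if (is(x, "Structure")) coords(x) else as.matrix(x)
}

.heavySelection <- function(structure, selection = NULL) {
  if (!is.null(selection)) return(selection)
  if (is(structure, "Structure")) which(!atoms(structure)$isH)
  else seq_len(nrow(.frameCoords(structure)))
}

#' Ligand RMSD against a reference pose
#'
#' Pose error of a ligand frame: when receptor coordinates are supplied for
#' both frame and reference, the frame is first superposed onto the
#' reference via a least-squares (Kabsch) fit of the receptor atoms, then
#' the RMSD is computed over the selected ligand atoms without further
#' fitting. With a rigid fixed receptor the superposition is the identity
#' and the RMSD is direct.
#'
#' @param ligand frame ligand ([Structure-class] or n x 3 matrix).
#' @param reference reference ligand pose (same atom order).
#' @param receptor,receptorRef optional frame/reference receptor
#'   coordinates used for the superposition.
#' @param selection atom indices (default: heavy atoms when `ligand` is a
#'   Structure, all atoms otherwise).
#' @return RMSD in A.
#' @export
ligandRMSD <- function(ligand, reference, receptor = NULL,
                       receptorRef = NULL, selection = NULL) {
  sel <- .heavySelection(ligand, selection)
  P <- .frameCoords(ligand)
  Q <- .frameCoords(reference)
  if (nrow(P) != nrow(Q))
    stop("frame and reference selections do not correspond 1:1", call. = FALSE)
  if (!is.null(receptor) && !is.null(receptorRef)) {
    tr <- .superposition(.frameCoords(receptor), .frameCoords(receptorRef))
    P <- tr(P)
  }
  P <- P[sel, , drop = FALSE]; Q <- Q[sel, , drop = FALSE]
  sqrt(mean(rowSums((P - Q)^2)))
}

.runFrames <- function(run) {
  if (is(run, "SteeringRun")) run@trajectory else run
}

#' Per-frame ligand RMSD of a trajectory
#'
#' @param run a [SteeringRun-class] or list of frame coordinate matrices.
#' @param reference reference ligand pose.
#' @param selection atom indices (default heavy atoms).
#' @return numeric vector of per-frame RMSD, A.
#' @export
trajectoryRMSD <- function(run, reference, selection = NULL) {
  frames <- .runFrames(run)
  if (is(run, "SteeringRun") && is.null(selection))
    selection <- which(!atoms(run@ligand)$isH)
  vapply(frames, function(f)
    ligandRMSD(f, reference, selection = selection), numeric(1))
}

#' Minimal-RMSD probability density over replicate runs
#'
#' Takes the minimum ligand RMSD reached in each replicate run and returns
#' a Gaussian kernel density over those minima (Silverman's rule-of-thumb
#' bandwidth by default) -- the distribution of the best pose each
#' replicate achieved.
#'
#' @param runs list of [SteeringRun-class] objects (or frame lists), >= 2.
#' @param reference reference ligand pose.
#' @param bw kernel bandwidth (default `"nrd0"`, Silverman's rule).
#' @param histogram logical: also return hist-style break counts.
#' @param selection atom indices.
#' @return list with `minima`, `x`, `y` (density grid), `bw` and optionally
#'   `hist`.
#' @export
minRMSDDensity <- function(runs, reference, bw = "nrd0", histogram = FALSE,
                           selection = NULL) {
  if (length(runs) < 1L) stop("no runs supplied", call. = FALSE)
  if (length(runs) < 2L) stop("need at least 2 runs for a density", call. = FALSE)
  minima <- vapply(runs, function(r)
    min(trajectoryRMSD(r, reference, selection)), numeric(1))
  dn <- if (sd(minima) == 0)
    list(x = minima[1] + seq(-1, 1, length.out = 201) * 0.5,
         y = stats::dnorm(seq(-1, 1, length.out = 201) * 0.5, sd = 0.1),
         bw = 0.1)
  else stats::density(minima, bw = bw)
  out <- list(minima = minima, x = dn$x, y = dn$y, bw = dn$bw)
  if (histogram) out$hist <- graphics::hist(minima, plot = FALSE)
  out
}

#' Contact-residue ranking
#'
#' For every saved frame, a receptor residue scores one contact per (ligand
#' heavy atom, receptor heavy atom) pair within `cutoff`; counts are summed
#' over frames and runs and the top residues are reported with their
#' percentage share of all contacts. `perResidueFrame = TRUE` switches to a
#' binary unit: at most one contact per residue per frame.
#'
#' @param runs list of [SteeringRun-class] objects (or frame lists).
#' @param receptor receptor [Structure-class] (taken from the first run if
#'   omitted); must carry residue annotation.
#' @param ligand ligand [Structure-class] (for the heavy-atom mask when
#'   `runs` are bare frame lists).
#' @param cutoff contact distance, A (default 4).
#' @param topN number of residues to report.
#' @param perResidueFrame logical: binary per-residue-per-frame counting.
#' @return data.frame with resNo, resName, count, percent (percent over all
#'   contacting residues, so the full table sums to 100).
#' @export
contactRanking <- function(runs, receptor = NULL, ligand = NULL, cutoff = 4,
                           topN = 10, perResidueFrame = FALSE) {
  if (is(runs, "SteeringRun")) runs <- list(runs)
  if (is.null(receptor) && is(runs[[1]], "SteeringRun"))
    receptor <- runs[[1]]@receptor
  if (is.null(ligand) && is(runs[[1]], "SteeringRun"))
    ligand <- runs[[1]]@ligand
  stopifnot(is(receptor, "Structure"))
  ra <- atoms(receptor)
  rHeavy <- which(!ra$isH)
  if (!length(rHeavy)) stop("receptor has no heavy atoms", call. = FALSE)
  rx <- coords(receptor)[rHeavy, , drop = FALSE]
  resKey <- paste(ra$chain[rHeavy], ra$resNo[rHeavy], ra$resName[rHeavy])
  lHeavy <- if (is.null(ligand)) NULL else which(!atoms(ligand)$isH)
  counts <- numeric(0)
  for (run in runs) {
    frames <- .runFrames(run)
    for (f in frames) {
      lx <- as.matrix(f)
      if (!is.null(lHeavy)) lx <- lx[lHeavy, , drop = FALSE]
      if (!nrow(lx)) stop("ligand has no heavy atoms", call. = FALSE)
      ## pairwise distances receptor-heavy x ligand-heavy
      d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
      hit <- d2 <= cutoff^2
      perRes <- if (perResidueFrame)
        tapply(rowSums(hit) > 0, resKey, any) + 0
      else tapply(rowSums(hit), resKey, sum) + 0
      if (!length(counts)) counts <- setNames(numeric(length(perRes)),
                                              names(perRes))
      counts <- counts + perRes[names(counts)]
    }
  }
  counts <- counts[counts > 0]
  if (!length(counts))
    return(data.frame(resNo = integer(0), resName = character(0),
                      count = numeric(0), percent = numeric(0)))
  ord <- order(counts, decreasing = TRUE)
  counts <- counts[ord]
  parts <- do.call(rbind, strsplit(names(counts), " "))
  res <- data.frame(chain = parts[, 1], resNo = as.integer(parts[, 2]),
                    resName = parts[, 3], count = as.numeric(counts),
                    percent = 100 * as.numeric(counts) / sum(counts),
                    row.names = NULL)
  utils::head(res, topN)
}

#' Root-mean-square fluctuation per atom
#'
#' Every frame is superposed onto the mean structure (least squares over
#' the selection, iterated once: the mean is recomputed after the first
#' superposition), then `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`.
#'
#' @param run a [SteeringRun-class] or list of frame matrices (>= 2 frames).
#' @param selection atom indices used for the superposition and report
#'   (default all).
#' @param fit logical: superpose frames before measuring (default TRUE;
#'   set FALSE for trajectories already expressed in a fixed receptor
#'   frame, where the superposition is the identity by construction).
#' @return numeric vector of per-atom RMSF, A.
#' @export
rmsf <- function(run, selection = NULL, fit = TRUE) {
  frames <- .runFrames(run)
  if (length(frames) < 2L)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  frames <- lapply(frames, as.matrix)
  if (is.null(selection)) selection <- seq_len(nrow(frames[[1]]))
  frames <- lapply(frames, function(f) f[selection, , drop = FALSE])
  fitted <- frames
  if (fit) {
    mean1 <- Reduce(`+`, frames) / length(frames)
    fitted <- lapply(frames, function(f) .superposition(f, mean1)(f))
    mean2 <- Reduce(`+`, fitted) / length(fitted)
    fitted <- lapply(fitted, function(f) .superposition(f, mean2)(f))
  }
  mu <- Reduce(`+`, fitted) / length(fitted)
  msd <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - mu)^2))) /
         length(fitted)
  sqrt(msd)
}

#' Gate-distance series between a probe atom and a group centroid
#'
#' Per frame, the distance between one probe atom and the centroid of a
#' group of atoms (e.g. a pocket-gate residue against the pocket-lining
#' loop), plus a kernel density over the series; the customary way to
#' compare open/closed (apo/holo) pocket conformations.
#'
#' @param run a [SteeringRun-class] or list of frame matrices.
#' @param probe single atom index.
#' @param group non-empty vector of atom indices.
#' @param bw density bandwidth (default Silverman).
#' @return list with `series` (per-frame distance, A) and `density`.
#' @export
gateDistanceSeries <- function(run, probe, group, bw = "nrd0") {
  frames <- .runFrames(run)
  stopifnot(length(probe) == 1L)
  if (!length(group)) stop("empty atom group", call. = FALSE)
  series <- vapply(frames, function(f) {
    f <- as.matrix(f)
    sqrt(sum((f[probe, ] - colMeans(f[group, , drop = FALSE]))^2))
  }, numeric(1))
  dens <- if (length(series) >= 2L && sd(series) > 0)
    stats::density(series, bw = bw) else NULL
  list(series = series, density = dens)
}
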