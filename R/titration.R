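## Quadratic single-site binding isotherm: given total protein P_t and
## total ligand L_t, the bound-protein concentration is the physical root
## of  P_b^2 - (K_d + P_t + L_t) P_b + P_t L_t = 0, and the corrected
## fluorescence is a linear mix of free and bound coefficients,
##   F_c = f_p (P_t - P_b) + f_pb P_b.
## The fitter recovers (K_d, f_p, f_pb) from titration data by nonlinear
## least squares with K_d parameterized on a log scale.

#' Bound-protein concentration from the quadratic isotherm
#'
#' The physical (smaller) root of the single-site binding quadratic,
#' `P_b = ((K_d + P_t + L_t) - sqrt((K_d + P_t + L_t)^2 - 4 P_t L_t)) / 2`,
#' clamped into `[0, min(P_t, L_t)]` against floating-point underflow.
#'
#' @param kd dissociation constant, molar (>= 0).
#' @param pt total protein concentration, molar.
#' @param lt total ligand concentration, molar (vectorized).
#' @return bound concentration P_b, molar.
#' @export
boundFraction <- function(kd, pt, lt) {
  stopifnot(kd >= 0, pt >= 0, all(lt >= 0))
  b <- kd + pt + lt
  disc <- pmax(b^2 - 4 * pt * lt, 0)
  pb <- (b - sqrt(disc)) / 2
  pmin(pmax(pb, 0), pmin(pt, lt))
}

#' Model corrected fluorescence of a titration point
#'
#' @param kd,pt,lt as in [boundFraction()].
#' @param fp fluorescence coefficient of the free protein.
#' @param fpb fluorescence coefficient of the bound protein.
#' @return modelled corrected fluorescence.
#' @export
modelFluorescence <- function(kd, fp, fpb, pt, lt) {
  pb <- boundFraction(kd, pt, lt)
  fp * (pt - pb) + fpb * pb
}

#' Generate a synthetic fluorescence titration
#'
#' Forward model plus multiplicative Gaussian noise
#' (`F_c * (1 + N(0, noiseSd))`), deterministic under `seed`. Replicates
#' share the concentration grid and the true parameters but have
#' independent noise.
#'
#' @param kd,fp,fpb,pt true parameters.
#' @param lt strictly increasing ligand concentration grid, molar.
#' @param noiseSd relative noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param nReplicates number of replicate series.
#' @return a [TitrationSeries-class].
#' @export
makeTitration <- function(kd, fp, fpb, pt, lt, noiseSd = 0, seed = 1,
                          nReplicates = 1) {
  stopifnot(noiseSd >= 0, all(diff(lt) > 0))
  fc0 <- modelFluorescence(kd, fp, fpb, pt, lt)
  fc <- .withSeed(seed, {
    as.numeric(vapply(seq_len(nReplicates), function(r)
      fc0 * (1 + rnorm(length(lt), 0, noiseSd)), numeric(length(lt))))
  })
  new("TitrationSeries", lt = rep(lt, nReplicates), fc = fc, pt = pt,
      replicate = rep(seq_len(nReplicates), each = length(lt)))
}

#' Fit the dissociation constant from titration data
#'
#' Nonlinear least squares over (log10 K_d, f_p, f_pb), with per-replicate
#' fluorescence coefficients and a shared K_d when the series carries
#' replicates. Without an initial guess, a multi-start over K_d decades
#' around P_t picks the best basin. Standard errors come from the
#' Gauss-Newton curvature at the optimum.
#'
#' @param series a [TitrationSeries-class] (>= 4 points recommended,
#'   spanning concentrations below and above P_t).
#' @param initialGuess optional named list/vector with `kd`, `fp`, `fpb`.
#' @return a [BindingFit-class].
#' @export
fitKd <- function(series, initialGuess = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  validObject(series)
  lt <- series@lt; fc <- series@fc; pt <- series@pt
  repl <- as.integer(factor(series@replicate))
  nr <- max(repl)
  if (length(lt) < 4L)
    warning("fewer than 4 titration points; the fit is ill-determined")
  if (sd(fc) == 0)
    stop("degenerate series: constant fluorescence", call. = FALSE)

  residFun <- function(par) {
    kd <- 10^par[1]
    fp <- par[1 + seq_len(nr)]
    fpb <- par[1 + nr + seq_len(nr)]
    fc - modelFluorescence(kd, fp[repl], fpb[repl], pt, lt)
  }
  coefStart <- function(kd) {
    ## linear least squares for (fp, fpb) per replicate at fixed kd
    pb <- boundFraction(kd, pt, lt)
    fp <- numeric(nr); fpb <- numeric(nr)
    for (r in seq_len(nr)) {
      i <- repl == r
      X <- cbind(pt - pb[i], pb[i])
      cf <- tryCatch(qr.solve(X, fc[i]), error = function(e) c(fc[i][1] / pt, fc[i][length(fc[i])] / pt))
      fp[r] <- cf[1]; fpb[r] <- cf[2]
    }
    c(fp, fpb)
  }
  starts <- if (!is.null(initialGuess)) {
    ig <- as.list(initialGuess)
    list(c(log10(ig$kd),
           rep(ig$fp %||% coefStart(ig$kd)[1], nr),
           rep(ig$fpb %||% coefStart(ig$kd)[nr + 1], nr)))
  } else {
    lapply(log10(pt) + seq(-3, 3), function(lk) c(lk, coefStart(10^lk)))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = residFun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("titration fit failed from every start", call. = FALSE)
  fit <- best$fit
  par <- fit$par
  conv <- fit$info %in% 1:4
  dof <- max(length(fc) - length(par), 1L)
  sigma2 <- best$rss / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, length(par)) else sqrt(pmax(diag(covm), 0))
  names(se) <- c("log10Kd", paste0("fp", seq_len(nr)), paste0("fpb", seq_len(nr)))
  new("BindingFit", kd = 10^par[1], fp = par[1 + seq_len(nr)],
      fpb = par[1 + nr + seq_len(nr)], residualNorm = best$rss,
      converged = conv, se = se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
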