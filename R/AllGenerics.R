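#' Accessors for pbsteer objects
#'
#' Small accessor family: `atoms()` returns the atom table of a
#' [Structure-class]; `coords()` its n x 3 coordinate matrix (settable);
#' `netCharge()` the summed partial charge; `nAtoms()` the atom count;
#' `forces()` / `appliedFactor()` / `fMax()` the slots of a
#' [ForceSet-class]; `gridValues()`, `gridOrigin()`, `gridSpacing()` and
#' `gridDims()` those of a [PotentialGrid-class]; `trajectory()` and
#' `events()` those of a [SteeringRun-class].
#'
#' @param x object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "Structure", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname accessors
#' @export
setMethod("coords<-", "Structure", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
#' @rdname accessors
#' @export
setMethod("netCharge", "Structure", function(x) sum(x@atoms$charge))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))
#' @rdname accessors
#' @export
setMethod("structureLabel", "Structure", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("structureMeta", function(x) standardGeneric("structureMeta"))
#' @rdname accessors
#' @export
setMethod("structureMeta", "Structure", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("forces", function(x) standardGeneric("forces"))
#' @rdname accessors
#' @export
setMethod("forces", "ForceSet", function(x) x@forces)

#' @rdname accessors
#' @export
setGeneric("appliedFactor", function(x) standardGeneric("appliedFactor"))
#' @rdname accessors
#' @export
setMethod("appliedFactor", "ForceSet", function(x) x@appliedFactor)

#' @rdname accessors
#' @export
setGeneric("fMax", function(x) standardGeneric("fMax"))
#' @rdname accessors
#' @export
setMethod("fMax", "ForceSet", function(x) x@fMax)

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setMethod("gridValues", "PotentialGrid", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setMethod("gridOrigin", "PotentialGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "GridGeometry", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setMethod("gridSpacing", "PotentialGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "GridGeometry", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setMethod("gridDims", "PotentialGrid", function(x) x@dims)
#' @rdname accessors
#' @export
setMethod("gridDims", "GridGeometry", function(x) x@dims)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "PotentialGrid", function(x) x@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "BindingFit", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname accessors
#' @export
setMethod("trajectory", "SteeringRun", function(x) x@trajectory)

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setMethod("events", "SteeringRun", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))
#' @rdname accessors
#' @export
setMethod("kd", "BindingFit", function(x) x@kd)

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure '%s': %d atoms, net charge %+.3f e\n",
              object@label, nrow(object@atoms), netCharge(object)))
  xyz <- coords(object)
  rng <- apply(xyz, 2, range)
  cat(sprintf("  extent: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] A\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "PotentialGrid", function(object) {
  cat(sprintf("PotentialGrid %d x %d x %d, spacing %.3f A\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing))
  cat(sprintf("  potential range [%.4g, %.4g] kcal/(mol e); %s after %d sweeps (residual %.2e)\n",
              min(object@values), max(object@values),
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
})

setMethod("show", "ForceSet", function(object) {
  cat(sprintf("ForceSet on %d atoms: |F|max %.4g kcal/mol/A (factor %.4g)\n",
              length(object@atomSerials), object@fMax, object@appliedFactor))
})

setMethod("show", "SteeringRun", function(object) {
  cat(sprintf("SteeringRun (mode %s): %d steps, %d cycles, %d frames%s\n",
              object@config@mode, object@config@totalSteps,
              nrow(object@events), length(object@trajectory),
              if (object@completed) "" else " [ABORTED]"))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: Kd = %.4g M (%s), rss %.4g\n",
              object@kd, if (object@converged) "converged" else "not converged",
              object@residualNorm))
})
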