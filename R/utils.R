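#' Combine several structures into one
#'
#' Concatenates atom tables (re-serialized to stay unique) into a single
#' [Structure-class]; used e.g. to present "receptor plus neutral body" as
#' one field source to the PB solver.
#'
#' @param ... [Structure-class] objects.
#' @param label label of the combined structure.
#' @return a [Structure-class].
#' @export
combineStructures <- function(..., label = "combined") {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is(parts[[1]], "Structure"))
    parts <- parts[[1]]
  stopifnot(all(vapply(parts, is, logical(1), "Structure")))
  a <- do.call(rbind, lapply(parts, atoms))
  a$serial <- seq_len(nrow(a))
  new("Structure", atoms = a, label = label)
}

#' Geometric centre of a structure
#'
#' @param x a [Structure-class].
#' @return 3-vector, A.
#' @export
geometricCenter <- function(x) colMeans(coords(x))
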