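## Multi-frame XYZ trajectory I/O. Coordinates are printed to 3 decimals,
## the frame comment line carries the time in ps ("t= 12.500 ps").

#' Write a multi-frame XYZ trajectory
#'
#' @param frames either a list of [Structure-class] snapshots with identical
#'   atom ordering, or a [SteeringRun-class] (its saved ligand frames are
#'   written).
#' @param path output file path.
#' @param times optional frame times in ps (taken from the run when `frames`
#'   is a [SteeringRun-class]; defaults to 0, 1, 2, ... otherwise).
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(frames, path, times = NULL) {
  if (is(frames, "SteeringRun")) {
    atomNames <- atoms(frames@ligand)$atomName
    xyz <- frames@trajectory
    if (is.null(times)) times <- frames@times
  } else {
    stopifnot(is.list(frames), length(frames) > 0L,
              all(vapply(frames, is, logical(1), "Structure")))
    atomNames <- atoms(frames[[1]])$atomName
    counts <- vapply(frames, nAtoms, integer(1))
    if (length(unique(counts)) != 1L)
      stop("inconsistent atom counts across frames", call. = FALSE)
    xyz <- lapply(frames, coords)
  }
  if (is.null(times)) times <- seq_along(xyz) - 1
  stopifnot(length(times) == length(xyz))
  element <- sub("^[^A-Za-z]*", "", atomNames)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (f in seq_along(xyz)) {
    writeLines(as.character(length(atomNames)), con)
    writeLines(sprintf("t= %.3f ps", times[f]), con)
    writeLines(sprintf("%-4s %12.3f %12.3f %12.3f", element,
                       xyz[[f]][, 1], xyz[[f]][, 2], xyz[[f]][, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file path.
#' @return a list with `atomNames` (character), `frames` (list of n x 3
#'   coordinate matrices) and `times` (ps, parsed from the comment lines;
#'   NA where absent).
#' @export
readTrajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); atomNames <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ header at line ", i, call. = FALSE)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    if (any(vapply(tok, length, integer(1)) < 4L))
      stop("malformed XYZ coordinate line near line ", i, call. = FALSE)
    if (is.null(atomNames)) atomNames <- vapply(tok, `[[`, character(1), 1L)
    m <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in ", path, call. = FALSE)
  list(atomNames = atomNames, frames = frames, times = times)
}
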