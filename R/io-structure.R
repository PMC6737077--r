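## Structure I/O: PQR (read/write) and a minimal PDB ATOM/HETATM reader.
## PQR files circulate in two dialects -- whitespace-separated and PDB-style
## fixed columns; both are accepted on input, whitespace-separated is emitted.

.inferIsH <- function(atomName) {
  ## element = first alphabetic character of the atom name (PQR names may
  ## carry leading digits, e.g. "1HB")
  el <- sub("^[^A-Za-z]*", "", atomName)
  toupper(substr(el, 1L, 1L)) == "H"
}

#' Build a Structure from raw atom fields
#'
#' Low-level constructor used by the readers and the fixture generators.
#' Missing chains default to "A" so downstream residue keys are
#' deterministic; hydrogen flags are inferred from the atom name.
#'
#' @param serial,atomName,resName,chain,resNo,x,y,z,charge,radius atom fields.
#' @param label molecule label.
#' @param meta optional annotation list.
#' @return a [Structure-class].
#' @export
newStructure <- function(serial, atomName, resName = "UNK", chain = "A",
                         resNo = 1L, x, y, z, charge = 0, radius = 0,
                         label = "", meta = list()) {
  n <- length(x)
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    serial = as.integer(serial),
    atomName = as.character(atomName),
    resName = rep_len(as.character(resName), n),
    chain = rep_len(as.character(chain), n),
    resNo = rep_len(as.integer(resNo), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = rep_len(as.numeric(charge), n),
    radius = rep_len(as.numeric(radius), n),
    stringsAsFactors = FALSE)
  atoms$isH <- .inferIsH(atoms$atomName)
  new("Structure", atoms = atoms, label = label, meta = meta)
}

.parsePQRLine <- function(line, lineNo) {
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  ## Tolerate both dialects: after record name, the last two numeric tokens
  ## are charge and radius, the three before them are x, y, z. Chain id is
  ## optional (pdb2pqr often omits it).
  if (length(tok) < 9L)
    stop(sprintf("malformed PQR line %d: expected >= 9 fields, got %d",
                 lineNo, length(tok)), call. = FALSE)
  nums <- suppressWarnings(as.numeric(tok))
  lastNum <- length(tok)
  if (any(is.na(nums[(lastNum - 4L):lastNum])))
    stop(sprintf("malformed PQR line %d: trailing fields not numeric", lineNo),
         call. = FALSE)
  hasChain <- length(tok) >= 10L && is.na(nums[5L])
  list(serial = as.integer(nums[2L]),
       atomName = tok[3L],
       resName = tok[4L],
       chain = if (hasChain) tok[5L] else "A",
       resNo = as.integer(nums[if (hasChain) 6L else 5L]),
       x = nums[lastNum - 4L], y = nums[lastNum - 3L], z = nums[lastNum - 2L],
       charge = nums[lastNum - 1L], radius = nums[lastNum])
}

#' Read a PQR structure file
#'
#' Accepts whitespace-separated and fixed-column PQR dialects: one atom per
#' ATOM/HETATM record, with the last two numeric fields read as partial
#' charge (e) and radius (A).
#'
#' @param path PQR file path.
#' @param label molecule label (defaults to the file name).
#' @return a [Structure-class].
#' @export
readPQR <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  recs <- lapply(which(keep), function(i) .parsePQRLine(lines[i], i))
  g <- function(f) vapply(recs, function(r) r[[f]], vector(mode = class(recs[[1]][[f]]), 1L))
  newStructure(serial = g("serial"), atomName = g("atomName"),
               resName = g("resName"), chain = g("chain"), resNo = g("resNo"),
               x = g("x"), y = g("y"), z = g("z"),
               charge = g("charge"), radius = g("radius"),
               label = if (is.null(label)) basename(path) else label)
}

#' Write a Structure to a PQR file
#'
#' Emits the whitespace-separated dialect. Round-trips through [readPQR()]
#' losslessly at the printed precision (coordinates to 1e-3 A, charges to
#' 1e-4 e).
#'
#' @param structure a [Structure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePQR <- function(structure, path) {
  stopifnot(is(structure, "Structure"))
  a <- atoms(structure)
  lines <- sprintf("ATOM  %5d %-4s %-4s %s %4d %11.3f %11.3f %11.3f %8.4f %7.4f",
                   a$serial, a$atomName, a$resName, a$chain, a$resNo,
                   a$x, a$y, a$z, a$charge, a$radius)
  ok <- tryCatch({ writeLines(c(lines, "END"), path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a minimal PDB file (coordinates and names only)
#'
#' Parses ATOM/HETATM fixed columns for identity and coordinates; charges
#' and radii are set to zero and must be assigned afterwards (e.g. from a
#' user lookup table). Only the first model is read; alternate locations
#' other than blank/"A" are dropped.
#'
#' @param path PDB file path.
#' @param label molecule label.
#' @return a [Structure-class] with zero charges and radii.
#' @export
readPDBMinimal <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  end <- grep("^ENDMDL", lines)[1]
  if (!is.na(end)) lines <- lines[seq_len(end - 1L)]
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  alt <- substr(lines, 17L, 17L)
  lines <- lines[alt %in% c(" ", "A")]
  num <- function(from, to) as.numeric(substr(lines, from, to))
  newStructure(serial = as.integer(num(7, 11)),
               atomName = trimws(substr(lines, 13, 16)),
               resName = trimws(substr(lines, 18, 20)),
               chain = trimws(substr(lines, 22, 22)),
               resNo = as.integer(num(23, 26)),
               x = num(31, 38), y = num(39, 46), z = num(47, 54),
               label = if (is.null(label)) basename(path) else label)
}
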