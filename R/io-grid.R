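## OpenDX scalar-grid I/O, the standard carrier for PB potential maps.
## Data ordering follows the DX convention: the z index varies fastest.

#' Write a potential grid as an OpenDX scalar field
#'
#' @param grid a [PotentialGrid-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDX <- function(grid, path) {
  stopifnot(is(grid, "PotentialGrid"))
  validObject(grid)
  d <- grid@dims; h <- grid@spacing; o <- grid@origin
  n <- prod(d)
  vals <- as.vector(aperm(grid@values, c(3, 2, 1)))  # z fastest
  pad <- (-length(vals)) %% 3L
  if (pad) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  dataLines <- apply(m, 1L, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  header <- c(
    "# OpenDX scalar field written by pbsteer",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", o[1], o[2], o[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", h),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", h),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", h),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  footer <- c('attribute "dep" string "positions"',
              'object "regular positions regular connections" class field',
              'component "positions" value 1',
              'component "connections" value 2',
              'component "data" value 3')
  tryCatch(writeLines(c(header, dataLines, footer), path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read an OpenDX scalar field into a potential grid
#'
#' Only regular grids with axis-aligned, equal deltas are supported (the
#' form [writeDX()] emits and PB tools exchange).
#'
#' @param path DX file path.
#' @return a [PotentialGrid-class].
#' @export
readDX <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX grid file: ", path, call. = FALSE)
  dims <- as.integer(tail(strsplit(trimws(gp), "[[:space:]]+")[[1]], 3L))
  origin <- as.numeric(strsplit(trimws(sub("^origin", "",
    grep("^origin", lines, value = TRUE)[1])), "[[:space:]]+")[[1]])
  deltas <- do.call(rbind, lapply(grep("^delta", lines, value = TRUE)[1:3],
    function(l) as.numeric(strsplit(trimws(sub("^delta", "", l)),
                                    "[[:space:]]+")[[1]])))
  offDiag <- deltas; diag(offDiag) <- 0
  if (any(abs(offDiag) > 0) || length(unique(signif(diag(deltas), 10))) != 1L)
    stop("only uniform axis-aligned DX grids are supported", call. = FALSE)
  spacing <- deltas[1, 1]
  dataStart <- grep("data follows", lines)[1]
  body <- lines[(dataStart + 1L):length(lines)]
  body <- body[!grepl("^(attribute|object|component)", body)]
  vals <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]),
                                     "[[:space:]]+")))
  n <- prod(dims)
  if (length(vals) < n)
    stop(sprintf("DX data truncated: expected %d values, found %d",
                 n, length(vals)), call. = FALSE)
  arr <- aperm(array(vals[seq_len(n)], dim = rev(dims)), c(3, 2, 1))
  new("PotentialGrid", origin = origin, spacing = spacing,
      dims = as.integer(dims), values = arr)
}
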