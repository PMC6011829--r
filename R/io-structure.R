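#' Read a molecular structure from PDB or XYZ
#'
#' PDB files are parsed with `bio3d::read.pdb()` (coordinates at the format's
#' 0.001 Angstrom precision).  XYZ files use the plain Cartesian dialect:
#' an atom-count line, a comment line, then `element x y z` records.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"xyz"`; guessed from the file extension when
#'   omitted.
#' @return A [molecular_system()].
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("3", "water", "O 0 0 0", "H 0.96 0 0", "H -0.24 0.93 0"), f)
#' read_structure(f)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) stop("empty file: ", path, call. = FALSE)
  switch(format,
         pdb = read_structure_pdb(path, lines),
         xyz = read_structure_xyz(path, lines))
}

read_structure_pdb <- function(path, lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  # validate coordinate fields up-front so malformed records name their line
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54)))))) {
      stop("malformed ATOM record at line ", i, " of ", path, call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elements <- at$elesy
  if (is.null(elements) || any(is.na(elements) | !nzchar(trimws(elements)))) {
    elements <- gsub("[^A-Za-z]", "", substr(trimws(at$elety), 1, 2))
    elements <- paste0(substr(elements, 1, 1),
                       tolower(substr(elements, 2, 2)))
  }
  molecular_system(
    tibble::tibble(
      element = trimws(elements),
      name = trimws(at$elety),
      residue_id = as.integer(at$resno),
      x = at$x, y = at$y, z = at$z
    ),
    title = basename(path)
  )
}

read_structure_xyz <- function(path, lines) {
  frames <- parse_multixyz(lines, path)
  molecular_system(frames$atoms_template(frames$frames[[1]]),
                   title = frames$comment[1])
}

#' Write a molecular structure to PDB or XYZ
#'
#' @param system A [molecular_system()].
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(system, "molecular_system"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  at <- system$atoms
  if (format == "pdb") {
    n <- nrow(at)
    bio3d::write.pdb(file = path, xyz = as.vector(t(coords(system))),
                     type = rep("ATOM", n), resno = at$residue_id,
                     resid = rep("MOL", n), eleno = at$index + 1L,
                     elety = at$name, elesy = at$element)
  } else {
    writeLines(format_xyz_frame(coords(system), at$element, system$title), path)
  }
  invisible(path)
}

format_xyz_frame <- function(xyz, elements, comment = "") {
  c(as.character(nrow(xyz)),
    as.character(comment),
    sprintf("%-3s %14.6f %14.6f %14.6f",
            elements, xyz[, 1], xyz[, 2], xyz[, 3]))
}

# Parse a (possibly multi-frame) XYZ file into coordinate matrices.
parse_multixyz <- function(lines, path) {
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  comments <- character()
  elements <- NULL
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    frame_no <- frame_no + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) {
      stop("expected atom count at line ", i, " of ", path,
           " (frame ", frame_no, ")", call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("frame ", frame_no, " of ", path, " is truncated: declared ", n,
           " atoms but file ends early", call. = FALSE)
    }
    comments <- c(comments, trimws(lines[i + 1L]))
    rec <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rec), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) {
      stop("malformed XYZ record at line ", i + 1L + bad[1], " of ", path,
           call. = FALSE)
    }
    el <- vapply(toks, `[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      t(vapply(toks, function(t) t[2:4], character(3))))), ncol = 3,
      byrow = FALSE)
    if (anyNA(xyz)) {
      stop("non-numeric coordinate in frame ", frame_no, " of ", path,
           call. = FALSE)
    }
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("frame ", frame_no, " has ", length(el),
           " atoms; previous frames have ", length(elements), call. = FALSE)
    }
    frames[[frame_no]] <- xyz
    i <- i + 2L + n
  }
  list(
    frames = frames,
    comment = comments,
    elements = elements,
    atoms_template = function(xyz) {
      tibble::tibble(element = elements,
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
  )
}
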