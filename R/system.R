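#' Build a molecular system from an atom table
#'
#' A `molecular_system` is the basic structure container: a tibble of atoms
#' (one row per atom) plus a title.  All analysis functions in the package
#' consume and return this type or plain tibbles derived from it.
#'
#' @param atoms A data frame with columns `index` (0-based, unique,
#'   consecutive), `element` (chemical symbol, non-empty), `name` (short atom
#'   label), `residue_id` (integer) and coordinates `x`, `y`, `z` in Angstrom.
#'   `index`, `name` and `residue_id` are filled in when missing.
#' @param title Free-text title carried through readers/writers.
#'
#' @return An object of class `molecular_system`: a list with elements
#'   `atoms` (tibble) and `title`.
#' @examples
#' water <- molecular_system(
#'   tibble::tibble(element = c("O", "H", "H"),
#'                  x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0),
#'   title = "water"
#' )
#' n_atoms(water)
#' @export
molecular_system <- function(atoms, title = "") {
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  if (n == 0L) stop("molecular_system needs at least one atom", call. = FALSE)
  if (!all(c("element", "x", "y", "z") %in% names(atoms))) {
    stop("atom table must have columns element, x, y, z", call. = FALSE)
  }
  if (!"index" %in% names(atoms)) atoms$index <- seq_len(n) - 1L
  if (!"name" %in% names(atoms)) atoms$name <- atoms$element
  if (!"residue_id" %in% names(atoms)) atoms$residue_id <- 1L
  atoms <- dplyr::select(atoms, "index", "element", "name", "residue_id",
                         "x", "y", "z")
  if (!identical(as.integer(atoms$index), seq_len(n) - 1L)) {
    stop("atom indices must be unique and consecutive from 0", call. = FALSE)
  }
  if (any(!nzchar(atoms$element)) || anyNA(atoms$element)) {
    stop("every atom needs a non-empty element symbol", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  structure(list(atoms = atoms, title = as.character(title)[1]),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", x$title, "\n", sep = "")
  cat(n_atoms(x), "atoms,", length(unique(x$atoms$residue_id)), "residues\n")
  print(x$atoms, n = 6)
  invisible(x)
}

#' Number of atoms in a system
#' @param system A [molecular_system()].
#' @return Integer atom count.
#' @export
n_atoms <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  nrow(system$atoms)
}

#' Coordinates of a system as a matrix
#' @param system A [molecular_system()].
#' @return An `n_atoms x 3` numeric matrix (Angstrom).
#' @export
coords <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  unname(as.matrix(system$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a system
#' @param system A [molecular_system()].
#' @param xyz An `n_atoms x 3` numeric matrix.
#' @return The system with new coordinates.
#' @export
set_coords <- function(system, xyz) {
  stopifnot(inherits(system, "molecular_system"))
  xyz <- as.matrix(xyz)
  if (!identical(dim(xyz), c(n_atoms(system), 3L)) &&
      !identical(dim(xyz), as.integer(c(n_atoms(system), 3)))) {
    stop("coordinate matrix must be n_atoms x 3", call. = FALSE)
  }
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z <- xyz[, 3]
  system
}

#' Build a trajectory from frames and a topology
#'
#' @param frames List of `n_atoms x 3` coordinate matrices (Angstrom), one per
#'   frame, all with the topology's atom count.
#' @param topology A [molecular_system()] giving atom identities.
#' @param frame_interval Time between stored frames, ps (metadata supplied by
#'   the caller; trajectories on disk carry no time axis).
#'
#' @return An object of class `trajectory`: list with `frames`, `topology`,
#'   `frame_interval`.
#' @export
trajectory <- function(frames, topology, frame_interval = 20) {
  stopifnot(inherits(topology, "molecular_system"))
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frames must be a non-empty list of coordinate matrices", call. = FALSE)
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0 ps", call. = FALSE)
  }
  na <- n_atoms(topology)
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != na || ncol(f) != 3) {
      stop(sprintf("frame %d has %d atoms; topology has %d", i, nrow(f), na),
           call. = FALSE)
    }
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  structure(list(frames = frames, topology = topology,
                 frame_interval = as.numeric(frame_interval)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", n_atoms(x$topology),
      " atoms, interval ", x$frame_interval, " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  length(traj$frames)
}
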