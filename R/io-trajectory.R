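#' Read a multi-frame trajectory
#'
#' Multi-model XYZ is the canonical interchange format: consecutive XYZ
#' blocks with a constant atom count.  Multi-MODEL PDB is also accepted.
#' The time axis is not stored on disk; `frame_interval` is caller-supplied
#' metadata (default 20 ps, a typical analysis stride).
#'
#' @param path Path to a multi-model XYZ (or multi-MODEL PDB) file.
#' @param frame_interval Time between frames, ps.
#' @param topology Optional [molecular_system()] supplying atom names and
#'   residue ids; built from the first frame's elements when omitted.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, frame_interval = 20, topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) stop("empty file: ", path, call. = FALSE)
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    frames <- lapply(seq_len(nrow(xyz)),
                     function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    if (is.null(topology)) topology <- read_structure(path, "pdb")
  } else {
    parsed <- parse_multixyz(lines, path)
    frames <- parsed$frames
    if (is.null(topology)) {
      topology <- molecular_system(parsed$atoms_template(frames[[1]]),
                                   title = parsed$comment[1])
    }
  }
  trajectory(frames, topology, frame_interval)
}

#' Write a trajectory as multi-model XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  el <- traj$topology$atoms$element
  out <- unlist(lapply(seq_along(traj$frames), function(i) {
    format_xyz_frame(traj$frames[[i]], el, paste("frame", i))
  }))
  writeLines(out, path)
  invisible(path)
}
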