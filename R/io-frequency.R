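#' Construct a frequency dataset for thermochemistry
#'
#' Bundles everything the rigid-rotor/harmonic-oscillator model needs about
#' one optimized structure: the electronic energy, per-atom masses and
#' coordinates (for moments of inertia), harmonic frequencies, the external
#' symmetry number and the spin multiplicity.  A transition state carries
#' exactly one negative entry in `frequencies`, encoding its imaginary mode.
#'
#' @param electronic_energy Electronic energy, kcal/mol.
#' @param masses Atomic masses, amu (one per atom).
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param frequencies Harmonic frequencies, cm^-1.  A single negative value
#'   is allowed only when `is_transition_state` is `TRUE`.
#' @param symmetry_number External rotational symmetry number (>= 1).
#' @param multiplicity Electronic spin multiplicity (>= 1).
#' @param is_transition_state Logical saddle-point flag.
#' @param elements Optional element symbols (cosmetic).
#' @param title Optional label.
#' @return An object of class `frequency_dataset`.
#' @export
frequency_dataset <- function(electronic_energy, masses, coords, frequencies,
                              symmetry_number = 1L, multiplicity = 1L,
                              is_transition_state = FALSE,
                              elements = NULL, title = "") {
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 3)
  masses <- as.numeric(masses)
  frequencies <- as.numeric(frequencies)
  if (length(masses) != nrow(coords)) {
    stop("need one mass per atom (", nrow(coords), " atoms, ",
         length(masses), " masses)", call. = FALSE)
  }
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (symmetry_number < 1 || multiplicity < 1) {
    stop("symmetry_number and multiplicity must be >= 1", call. = FALSE)
  }
  n_neg <- sum(frequencies < 0)
  if (is_transition_state && n_neg != 1L) {
    stop("a transition state must have exactly one negative (imaginary) ",
         "frequency; found ", n_neg, call. = FALSE)
  }
  if (!is_transition_state && n_neg > 0L) {
    stop("a minimum must have no negative frequencies; found ", n_neg,
         call. = FALSE)
  }
  structure(list(
    electronic_energy = as.numeric(electronic_energy),
    masses = masses, coords = coords, frequencies = frequencies,
    symmetry_number = as.integer(symmetry_number),
    multiplicity = as.integer(multiplicity),
    is_transition_state = isTRUE(is_transition_state),
    elements = elements %||% rep("X", length(masses)),
    title = title
  ), class = "frequency_dataset")
}

#' @export
print.frequency_dataset <- function(x, ...) {
  cat("<frequency_dataset> ", x$title,
      if (x$is_transition_state) " (transition state)", "\n", sep = "")
  cat(length(x$masses), "atoms,", length(x$frequencies), "modes, sigma =",
      x$symmetry_number, "\n")
  invisible(x)
}

#' Read a frequency dataset from key-value text
#'
#' The dialect is plain text: `key: value` lines for `title`,
#' `electronic_energy` (kcal/mol), `symmetry_number`, `multiplicity` and
#' `is_transition_state` (`yes`/`no`), then an `atoms:` block with one
#' `element mass x y z` record per atom (amu, Angstrom) and a `frequencies:`
#' block with whitespace-separated wavenumbers (cm^-1).  Lines starting with
#' `#` are comments.  See `write_frequency_dataset()` for the emitter.
#'
#' @param path Path to the file.
#' @return A [frequency_dataset()].
#' @export
read_frequency_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)

  kv <- list()
  atoms <- character()
  freqs <- character()
  block <- NA_character_
  for (ln in lines) {
    if (grepl("^atoms:\\s*$", ln)) { block <- "atoms"; next }
    if (grepl("^frequencies:\\s*$", ln)) { block <- "frequencies"; next }
    if (grepl("^[A-Za-z_]+:", ln)) {
      block <- NA_character_
      key <- sub(":.*$", "", ln)
      kv[[trimws(key)]] <- trimws(sub("^[A-Za-z_]+:", "", ln))
      next
    }
    if (identical(block, "atoms")) atoms <- c(atoms, ln)
    else if (identical(block, "frequencies")) freqs <- c(freqs, ln)
    else stop("unexpected line outside any block in ", path, ": ", ln,
              call. = FALSE)
  }
  if (!length(atoms)) stop("no atoms: block in ", path, call. = FALSE)
  toks <- strsplit(trimws(atoms), "\\s+")
  if (any(vapply(toks, length, 1L) != 5L)) {
    stop("atoms: records must be 'element mass x y z' in ", path,
         call. = FALSE)
  }
  freq_vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(freqs),
                                                           "\\s+"))))
  if (anyNA(freq_vals)) stop("non-numeric frequency in ", path, call. = FALSE)
  frequency_dataset(
    electronic_energy = as.numeric(kv$electronic_energy %||% 0),
    masses = as.numeric(vapply(toks, `[`, "", 2L)),
    coords = matrix(as.numeric(t(vapply(toks, function(t) t[3:5],
                                        character(3)))), ncol = 3,
                    byrow = FALSE),
    frequencies = freq_vals,
    symmetry_number = as.integer(kv$symmetry_number %||% 1L),
    multiplicity = as.integer(kv$multiplicity %||% 1L),
    is_transition_state = tolower(kv$is_transition_state %||% "no") %in%
      c("yes", "true", "1"),
    elements = vapply(toks, `[`, "", 1L),
    title = kv$title %||% basename(path)
  )
}

#' Write a frequency dataset in the package's key-value dialect
#' @param state A [frequency_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_dataset <- function(state, path) {
  stopifnot(inherits(state, "frequency_dataset"))
  out <- c(
    paste("title:", state$title),
    sprintf("electronic_energy: %.10g", state$electronic_energy),
    paste("symmetry_number:", state$symmetry_number),
    paste("multiplicity:", state$multiplicity),
    paste("is_transition_state:",
          if (state$is_transition_state) "yes" else "no"),
    "atoms:",
    sprintf("%-3s %12.8f %14.8f %14.8f %14.8f",
            state$elements, state$masses,
            state$coords[, 1], state$coords[, 2], state$coords[, 3]),
    "frequencies:",
    if (length(state$frequencies)) {
      paste(sprintf("%.6f", state$frequencies), collapse = " ")
    } else character()
  )
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
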