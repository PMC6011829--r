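#' Read a per-atom force-field parameter table
#'
#' Expects a CSV with header `index,charge,epsilon,rmin_half,pb_radius`:
#' partial charge in e, Lennard-Jones well depth in kcal/mol and rmin/2 in
#' Angstrom, and the Poisson-Boltzmann cavity radius in Angstrom.  Values are
#' passed through without unit conversion.
#'
#' @param path Path to the CSV file.
#' @param n_atoms Optional expected atom count; indices 0..n_atoms-1 must then
#'   all be present.
#' @return A tibble of class `ff_parameters` with one row per atom, sorted by
#'   `index`.
#' @export
read_parameter_table <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  ff_parameters(tab, n_atoms = n_atoms)
}

#' Validate a per-atom parameter table
#'
#' @param tab Data frame with columns `index`, `charge`, `epsilon`,
#'   `rmin_half`, `pb_radius`.
#' @inheritParams read_parameter_table
#' @return A tibble of class `ff_parameters`.
#' @export
ff_parameters <- function(tab, n_atoms = NULL) {
  tab <- tibble::as_tibble(tab)
  need <- c("index", "charge", "epsilon", "rmin_half", "pb_radius")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("parameter table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(tab$index[duplicated(tab$index)])
  if (length(dup)) {
    stop("duplicated atom indices in parameter table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(tab$epsilon < 0)) stop("lj epsilon must be >= 0", call. = FALSE)
  if (any(tab$pb_radius <= 0)) stop("pb_radius must be > 0", call. = FALSE)
  if (!is.null(n_atoms)) {
    missing_idx <- setdiff(seq_len(n_atoms) - 1L, tab$index)
    if (length(missing_idx)) {
      stop("parameter table missing atom indices: ",
           paste(missing_idx, collapse = ", "), call. = FALSE)
    }
    if (nrow(tab) != n_atoms) {
      stop("parameter table has ", nrow(tab), " rows for ", n_atoms, " atoms",
           call. = FALSE)
    }
  }
  tab <- dplyr::arrange(tab[, need], .data$index)
  class(tab) <- c("ff_parameters", class(tab))
  tab
}

#' Write a parameter table as CSV
#' @param params An [ff_parameters()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  readr::write_csv(tibble::as_tibble(unclass(params))[,
    c("index", "charge", "epsilon", "rmin_half", "pb_radius")], path)
  invisible(path)
}
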