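# Trajectory geometry statistics: hydrogen-bond detection and occupancy,
# cavity-axis depth metrics, Kabsch superposition and guest RMSD.
#
# All atom selections are vectors of values from the `index` column of the
# system's atom table (0-based, as stored).

sel_rows <- function(system_or_n, sel, what = "selection") {
  n <- if (inherits(system_or_n, "molecular_system")) n_atoms(system_or_n)
       else as.integer(system_or_n)
  sel <- as.integer(sel)
  if (length(sel) == 0L) stop(what, " is empty", call. = FALSE)
  if (any(sel < 0L | sel >= n)) {
    stop(what, " contains atom indices outside 0..", n - 1L, call. = FALSE)
  }
  sel + 1L
}

#' Hydrogen-bond geometric criterion
#'
#' An H-bond X-H...Y counts as formed when the H...Y distance is strictly
#' below `max_h_acceptor_distance` and the deviation from linearity,
#' 180 degrees minus the X-H...Y angle, is strictly below
#' `max_linearity_deviation`.
#'
#' @param max_h_acceptor_distance H...acceptor distance bound, Angstrom.
#' @param max_linearity_deviation Bound on (180 - angle(X-H...Y)), degrees.
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_h_acceptor_distance = 2.2,
                            max_linearity_deviation = 90) {
  if (max_h_acceptor_distance <= 0 || max_linearity_deviation <= 0) {
    stop("criterion thresholds must be strictly positive", call. = FALSE)
  }
  structure(list(max_h_acceptor_distance = max_h_acceptor_distance,
                 max_linearity_deviation = max_linearity_deviation),
            class = "hbond_criterion")
}

#' Host reference frame: cavity center and rim-to-rim axis
#'
#' The center is the unweighted geometric center of the host's heavy atoms
#' (hydrogens excluded).  The axis is the unit vector from the narrow-rim
#' centroid to the wide-rim centroid, so positive depths point toward the
#' wide (secondary-hydroxyl) rim of a cyclodextrin-like host.
#'
#' @param system A [molecular_system()].
#' @param host_selection Atom indices of the host.
#' @param rim_narrow,rim_wide Disjoint, non-empty atom index sets marking the
#'   two rims.
#' @param frame Optional `n x 3` coordinate matrix overriding the system's
#'   coordinates (used by per-frame wrappers).
#' @return A list of class `host_frame_axes` with `center` (3-vector,
#'   Angstrom) and `axis` (unit 3-vector).
#' @export
host_frame <- function(system, host_selection, rim_narrow, rim_wide,
                       frame = NULL) {
  xyz <- if (is.null(frame)) coords(system) else as.matrix(frame)
  host_rows <- sel_rows(nrow(xyz), host_selection, "host_selection")
  nr <- sel_rows(nrow(xyz), rim_narrow, "rim_narrow")
  wr <- sel_rows(nrow(xyz), rim_wide, "rim_wide")
  if (length(intersect(nr, wr))) {
    stop("rim selections must be disjoint", call. = FALSE)
  }
  heavy <- host_rows[system$atoms$element[host_rows] != "H"]
  if (!length(heavy)) stop("host selection has no heavy atoms", call. = FALSE)
  center <- colMeans(xyz[heavy, , drop = FALSE])
  v <- colMeans(xyz[wr, , drop = FALSE]) - colMeans(xyz[nr, , drop = FALSE])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("rim centroids coincide; axis undefined", call. = FALSE)
  structure(list(center = as.numeric(center), axis = as.numeric(v / nv)),
            class = "host_frame_axes")
}

#' Detect hydrogen bonds in one frame
#'
#' @param frame `n x 3` coordinate matrix, Angstrom.
#' @param donors Two-column matrix (or data frame) of atom indices: heavy
#'   donor X in column 1, its hydrogen H in column 2.
#' @param acceptors Vector of acceptor atom indices Y.
#' @param criterion An [hbond_criterion()].
#' @return A tibble with one row per formed bond: `donor_x`, `donor_h`,
#'   `acceptor`, `distance` (Angstrom), `linearity_deviation` (degrees).
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criterion = hbond_criterion()) {
  frame <- as.matrix(frame)
  donors <- matrix(as.integer(as.matrix(donors)), ncol = 2)
  x_rows <- sel_rows(nrow(frame), donors[, 1], "donor X")
  h_rows <- sel_rows(nrow(frame), donors[, 2], "donor H")
  y_rows <- sel_rows(nrow(frame), acceptors, "acceptors")

  res <- vector("list", nrow(donors) * length(y_rows))
  k <- 0L
  for (i in seq_len(nrow(donors))) {
    x <- frame[x_rows[i], ]
    h <- frame[h_rows[i], ]
    xh <- x - h
    if (sum(xh^2) < 1e-20) {
      stop("donor pair (", donors[i, 1], ",", donors[i, 2],
           ") has coincident X,H coordinates; angle undefined", call. = FALSE)
    }
    for (j in seq_along(y_rows)) {
      y <- frame[y_rows[j], ]
      hy <- y - h
      d <- sqrt(sum(hy^2))
      if (d >= criterion$max_h_acceptor_distance || d < 1e-12) next
      cosang <- sum(xh * hy) / (sqrt(sum(xh^2)) * d)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi  # X-H...Y angle
      dev <- 180 - ang
      if (dev < criterion$max_linearity_deviation) {
        k <- k + 1L
        res[[k]] <- tibble::tibble(
          donor_x = donors[i, 1], donor_h = donors[i, 2],
          acceptor = as.integer(acceptors[j]),
          distance = d, linearity_deviation = dev)
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(donor_x = integer(), donor_h = integer(),
                          acceptor = integer(), distance = numeric(),
                          linearity_deviation = numeric()))
  }
  dplyr::bind_rows(res[seq_len(k)])
}

#' Hydrogen-bond occurrence percentage over a trajectory
#'
#' A frame counts as H-bonded when at least one donor-acceptor triple
#' satisfies the criterion; the occurrence percentage is 100 x (bonded
#' frames) / (total frames).  Per-triple percentages are reported alongside.
#'
#' @inheritParams detect_hbonds
#' @param traj A [trajectory()].
#' @return A list of class `hbond_occupancy` with `occupancy_percent`
#'   (frame-level), `per_pair` (tibble: triple, frames, percent),
#'   `per_frame` (logical vector) and `n_frames`.
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criterion = hbond_criterion()) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames", call. = FALSE)
  hits <- purrr::map(traj$frames, detect_hbonds,
                     donors = donors, acceptors = acceptors,
                     criterion = criterion)
  per_frame <- vapply(hits, function(h) nrow(h) > 0L, logical(1))
  per_pair <- dplyr::bind_rows(hits, .id = "frame") |>
    dplyr::distinct(.data$frame, .data$donor_x, .data$donor_h,
                    .data$acceptor) |>
    dplyr::count(.data$donor_x, .data$donor_h, .data$acceptor,
                 name = "n_frames") |>
    dplyr::mutate(percent = 100 * .data$n_frames / nf)
  structure(list(
    occupancy_percent = 100 * sum(per_frame) / nf,
    per_pair = per_pair,
    per_frame = per_frame,
    n_frames = nf
  ), class = "hbond_occupancy")
}

#' @export
print.hbond_occupancy <- function(x, ...) {
  cat(sprintf("<hbond_occupancy> %.2f%% of %d frames contain an H-bond\n",
              x$occupancy_percent, x$n_frames))
  if (nrow(x$per_pair)) print(x$per_pair, n = 10)
  invisible(x)
}

#' Signed cavity-depth metrics for one frame
#'
#' For each selection, the signed projection of (selection centroid - host
#' center) onto the host axis: positive values sit toward the wide rim,
#' negative values deep toward the narrow rim.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param axes A [host_frame_axes()] for the same frame.
#' @param selections Named list of atom index vectors (e.g. whole guest,
#'   cyclohexyl moiety, imide moiety).
#' @return A tibble with columns `selection`, `depth` (Angstrom).
#' @export
depth_metrics <- function(frame, axes, selections) {
  stopifnot(inherits(axes, "host_frame_axes"))
  frame <- as.matrix(frame)
  if (is.null(names(selections)) || any(!nzchar(names(selections)))) {
    names(selections) <- paste0("d", seq_along(selections))
  }
  depth <- vapply(seq_along(selections), function(i) {
    rows <- sel_rows(nrow(frame), selections[[i]], names(selections)[i])
    cen <- colMeans(frame[rows, , drop = FALSE])
    sum((cen - axes$center) * axes$axis)
  }, numeric(1))
  tibble::tibble(selection = names(selections), depth = depth)
}

#' Depth-metric summary over a trajectory
#'
#' Recomputes the host frame per trajectory frame (the host tumbles), then
#' summarises each selection's signed depth as mean and standard deviation.
#'
#' @inheritParams depth_metrics
#' @inheritParams host_frame
#' @param traj A [trajectory()].
#' @return A tibble with columns `selection`, `mean`, `sd`, `n_frames`.
#' @export
depth_profile <- function(traj, host_selection, rim_narrow, rim_wide,
                          selections) {
  stopifnot(inherits(traj, "trajectory"))
  purrr::map_dfr(traj$frames, function(fr) {
    ax <- host_frame(traj$topology, host_selection, rim_narrow, rim_wide,
                     frame = fr)
    depth_metrics(fr, ax, selections)
  }) |>
    dplyr::group_by(.data$selection) |>
    dplyr::summarise(mean = mean(.data$depth),
                     sd = stats::sd(.data$depth),
                     n_frames = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$selection, names(selections)))
}

# Kabsch least-squares superposition: returns the proper rotation R and
# translation t minimizing ||mobile %*% t(R) + t - target||^2 row-wise.
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) < 3L) {
    stop("need at least 3 alignment atoms; rotation underdetermined",
         call. = FALSE)
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)              # sum_i p_i q_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(ct - as.numeric(R %*% cm)))
}

apply_kabsch <- function(fit, xyz) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Guest RMSD after host superposition
#'
#' Each frame is least-squares superposed onto the reference using the
#' alignment selection (Kabsch, uniform weights, proper rotations only);
#' the RMSD is then computed over the guest selection.  An RMSD series like
#' this, thresholded with [classify_bound()], is how bound and unbound guest
#' states are separated.
#'
#' @param traj A [trajectory()].
#' @param reference `n x 3` reference coordinates (same atom order as the
#'   trajectory topology).
#' @param align_selection Atom indices used for superposition (>= 3, usually
#'   the host).
#' @param rmsd_selection Atom indices over which RMSD is evaluated (usually
#'   the guest).
#' @return A tibble with columns `frame`, `time_ps`, `rmsd` (Angstrom).
#' @export
guest_rmsd <- function(traj, reference, align_selection, rmsd_selection) {
  stopifnot(inherits(traj, "trajectory"))
  reference <- as.matrix(reference)
  if (nrow(reference) != n_atoms(traj$topology)) {
    stop("reference must have the trajectory's atom count", call. = FALSE)
  }
  ar <- sel_rows(nrow(reference), align_selection, "align_selection")
  if (length(ar) < 3L) {
    stop("need at least 3 alignment atoms; rotation underdetermined",
         call. = FALSE)
  }
  gr <- sel_rows(nrow(reference), rmsd_selection, "rmsd_selection")
  rmsd <- vapply(traj$frames, function(fr) {
    fit <- kabsch(fr[ar, , drop = FALSE], reference[ar, , drop = FALSE])
    moved <- apply_kabsch(fit, fr[gr, , drop = FALSE])
    sqrt(mean(rowSums((moved - reference[gr, , drop = FALSE])^2)))
  }, numeric(1))
  tibble::tibble(frame = seq_along(rmsd),
                 time_ps = (seq_along(rmsd) - 1) * traj$frame_interval,
                 rmsd = rmsd)
}
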