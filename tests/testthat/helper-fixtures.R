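# Shared fixtures and independent oracles, all built in code.

# A 3-atom water PDB written through a literal template (independent of the
# package's writer).
write_water_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.117  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.000   0.757  -0.469  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1       0.000  -0.757  -0.469  1.00  0.00           H",
    "END"), path)
  path
}

random_system <- function(n, seed = 1) {
  set.seed(seed)
  molecular_system(tibble::tibble(
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    x = stats::runif(n, -5, 5), y = stats::runif(n, -5, 5),
    z = stats::runif(n, -5, 5)))
}

# Uniformly random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_transform <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

# Brute-force Coulomb oracle: explicit double loop.
coulomb_brute <- function(xa, qa, xb, qb) {
  e <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    e <- e + 332.0637 * qa[i] * qb[j] / sqrt(sum((xa[i, ] - xb[j, ])^2))
  }
  e
}

# Brute-force Lennard-Jones oracle.
lj_brute <- function(xa, pa, xb, pb) {
  e <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    eps <- sqrt(pa$epsilon[i] * pb$epsilon[j])
    rm <- pa$rmin_half[i] + pb$rmin_half[j]
    e <- e + eps * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

# Brute-force H-bond frame recount: double loop over frames and pairs with
# literal distance/angle arithmetic.
hbond_frames_brute <- function(traj, donors, acceptors, dmax = 2.2,
                               devmax = 90) {
  n_hit <- 0L
  for (f in traj$frames) {
    hit <- FALSE
    for (i in seq_len(nrow(donors))) {
      x <- f[donors[i, 1] + 1, ]; h <- f[donors[i, 2] + 1, ]
      for (a in acceptors) {
        y <- f[a + 1, ]
        d <- sqrt(sum((y - h)^2))
        if (d >= dmax) next
        v1 <- x - h; v2 <- y - h
        ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
        if ((180 - ang) < devmax) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) n_hit <- n_hit + 1L
  }
  n_hit
}

# A single-frame system with one donor (X,H) and one acceptor Y at a chosen
# H..Y distance and X-H..Y angle (degrees).
hbond_geometry <- function(dist, angle) {
  x <- c(0, 0, 0); h <- c(1, 0, 0)
  th <- (180 - angle) * pi / 180   # deviation from linearity
  y <- h + dist * c(cos(th), sin(th), 0)
  rbind(x, h, y)
}
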