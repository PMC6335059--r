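# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles, sharing no code with the package paths
# they check.

# Kabsch-Sander hydrogen-bond energy from raw coordinates, with its own
# amide-H construction (bisector rule, 1.01 A from N).
oracle_ks_energy <- function(N_don, CA_don, Cprev_don, C_acc, O_acc) {
  nrm <- function(v) v / sqrt(sum(v^2))
  h_dir <- -nrm(nrm(Cprev_don - N_don) + nrm(CA_don - N_don))
  H <- N_don + 1.01 * h_dir
  dd <- function(p, q) sqrt(sum((p - q)^2))
  0.084 * 332 * (1 / dd(O_acc, N_don) + 1 / dd(C_acc, H) -
                   1 / dd(O_acc, H) - 1 / dd(C_acc, N_don))
}

# Brute-force sphere-probe radius at one z: exhaustive 0.1 A in-plane grid.
oracle_probe_radius <- function(xyz, vdw, z, half_extent = 3, step = 0.1) {
  g <- seq(-half_extent, half_extent, by = step)
  ctr <- as.matrix(expand.grid(x = g, y = g))
  best <- -Inf
  dz2 <- (xyz[, 3] - z)^2
  for (i in seq_len(nrow(ctr))) {
    d <- sqrt((xyz[, 1] - ctr[i, 1])^2 + (xyz[, 2] - ctr[i, 2])^2 + dz2)
    cl <- min(d - vdw)
    if (cl > best) best <- cl
  }
  max(best, 0)
}

# Textbook pooled two-sample t statistic and two-tailed p.
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# 9 x 9 elastic-network Hessian for a linear triatomic chain, written out
# by hand from the pairwise block definition.
oracle_triatomic_hessian <- function(xyz, cutoff, gamma) {
  n <- 3L
  H <- matrix(0, 9, 9)
  for (i in 1:2) for (j in (i + 1):3) {
    dx <- xyz[j, ] - xyz[i, ]
    d2 <- sum(dx^2)
    if (d2 > cutoff^2) next
    blk <- -gamma * (dx %o% dx) / d2
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a rigid transform to every frame of a trajectory
transform_traj <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  for (f in seq_len(n_frames(traj)))
    traj$coords[, , f] <- traj$coords[, , f] %*% t(R) +
      matrix(shift, n_atoms(traj), 3, byrow = TRUE)
  traj
}
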