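# Elastic-network deformation energy of the pre-protein, spin-label
# distance distributions, and steered-passage time extraction.

#' Build an anisotropic elastic-network model
#'
#' Standard Calpha anisotropic network model: node pairs within the cutoff
#' are connected by Hookean springs of constant gamma; the 3N x 3N Hessian
#' has off-diagonal blocks \eqn{-\gamma \Delta x \Delta x^T / d^2} and
#' diagonal blocks equal to minus the row sum. A connected non-degenerate
#' 3-D structure has exactly six zero modes (rigid translations and
#' rotations); more indicates a disconnected network and is flagged.
#'
#' @param xyz numeric matrix \code{[n, 3]} of node (Calpha) coordinates,
#'   Angstrom; at least 3 non-collinear nodes for a 3-D structure.
#' @param cutoff spring cutoff, Angstrom (default 15).
#' @param gamma spring constant (arbitrary units).
#' @return object of class \code{"enm"}: \code{xyz}, \code{hessian},
#'   \code{cutoff}, \code{gamma}, \code{eig} (eigendecomposition, values
#'   ascending), \code{n_zero_modes}, \code{connected}.
#' @export
build_enm <- function(xyz, cutoff = 15, gamma = 1) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 nodes")
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- xyz[j, ] - xyz[i, ]
      d2 <- sum(dx * dx)
      if (d2 > cutoff^2 || d2 == 0) next
      blk <- -gamma * outer(dx, dx) / d2
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  # ascending eigenvalues
  ord <- order(eig$values)
  eig$values <- eig$values[ord]
  eig$vectors <- eig$vectors[, ord, drop = FALSE]
  scale <- max(abs(eig$values), 1)
  nzero <- sum(abs(eig$values) < 1e-8 * scale)
  connected <- nzero <= 6L
  if (!connected)
    warning("elastic network is disconnected or degenerate: ", nzero,
            " zero modes")
  structure(list(xyz = xyz, hessian = H, cutoff = cutoff, gamma = gamma,
                 eig = eig, n_zero_modes = nzero, connected = connected),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat(sprintf("Elastic network model: %d nodes, cutoff %g A, %d zero modes%s\n",
              nrow(x$xyz), x$cutoff, x$n_zero_modes,
              if (x$connected) "" else " (disconnected)"))
  invisible(x)
}

# per-node deformation energy of one displacement field v (n x 3):
# e_i = sum over neighbours j of gamma * [(v_i - v_j) . (x_i - x_j) / d]^2
deformation_one <- function(xyz, v, cutoff, gamma) {
  n <- nrow(xyz)
  e <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- xyz[i, ] - xyz[j, ]
      d2 <- sum(dx * dx)
      if (d2 > cutoff^2 || d2 == 0) next
      proj <- sum((v[i, ] - v[j, ]) * dx) / sqrt(d2)
      contrib <- gamma * proj * proj
      e[i] <- e[i] + contrib
      e[j] <- e[j] + contrib
    }
  }
  e
}

#' Per-residue deformation energy over the first non-trivial modes
#'
#' For each of the first \code{n_modes} non-trivial normal modes (the modes
#' after the six rigid-body zero modes, each normalised to unit length),
#' the local deformation carried by node i is the sum over its network
#' neighbours of \eqn{\gamma [(v_i - v_j)\cdot(x_i - x_j)/d_{ij}]^2}: the
#' squared bond-length distortion, a measure of internal (non-rigid) motion
#' at that residue. The field is the sum over the analysed modes; it is
#' non-negative everywhere and exactly zero for rigid-body displacement
#' fields. Optionally normalised to a unit maximum per structure.
#'
#' @param model an \code{"enm"}.
#' @param n_modes number of non-trivial modes (default 3).
#' @param normalise if TRUE, scale the field to max 1.
#' @return numeric vector of per-node deformation energies.
#' @export
deformation_energy <- function(model, n_modes = 3, normalise = FALSE) {
  n <- nrow(model$xyz)
  ev <- model$eig$values
  scale <- max(abs(ev), 1)
  nontrivial <- which(abs(ev) >= 1e-8 * scale)
  if (length(nontrivial) < n_modes)
    stop("only ", length(nontrivial), " non-trivial modes available")
  modes <- nontrivial[seq_len(n_modes)]
  e <- numeric(n)
  for (m in modes) {
    v <- matrix(model$eig$vectors[, m], ncol = 3, byrow = TRUE)
    v <- v / sqrt(sum(v * v))
    e <- e + deformation_one(model$xyz, v, model$cutoff, model$gamma)
  }
  if (normalise && max(e) > 0) e <- e / max(e)
  e
}

#' Deformation energy of an arbitrary displacement field
#'
#' Same per-node measure as [deformation_energy()] for a user-supplied
#' displacement field (e.g. a rigid translation or an infinitesimal
#' rotation, for which the field is zero).
#'
#' @param model an \code{"enm"}.
#' @param v displacement field, matrix \code{[n, 3]}.
#' @return numeric vector of per-node energies.
#' @export
deformation_field <- function(model, v) {
  deformation_one(model$xyz, as.matrix(v), model$cutoff, model$gamma)
}

#' Spin-label distance distribution across an ensemble
#'
#' Per frame, the distance between the unweighted centroids of two atom
#' groups (e.g. the N-O "ON" groups of paired nitroxide spin labels);
#' the sample is summarised by a Gaussian kernel-density estimate
#' (Silverman bandwidth) evaluated on a fixed 0.1 Angstrom (0.01 nm) grid.
#' The modal distance is the grid argmax; the FWHH is the width of the KDE
#' at half its maximum, linearly interpolated at the crossings (of the peak
#' containing the mode, with a multimodality flag when other peaks also
#' rise above half height). A (near-)degenerate ensemble is reported with
#' \code{degenerate = TRUE}: its FWHH is the bandwidth-limited minimum.
#'
#' @param traj a \code{"trajectory"}.
#' @param groupA_sel,groupB_sel atom indices of the two groups (non-empty).
#' @param frames frame indices (default all).
#' @return object of class \code{"distance_distribution"}: \code{samples}
#'   (Angstrom), \code{grid}, \code{density}, \code{modal}, \code{fwhh},
#'   \code{bandwidth}, \code{multimodal}, \code{degenerate}.
#' @export
label_distance_series <- function(traj, groupA_sel, groupB_sel,
                                  frames = NULL) {
  if (length(groupA_sel) == 0L || length(groupB_sel) == 0L)
    stop("label group selections must be non-empty")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  d <- vapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    ca <- colMeans(xyz[groupA_sel, , drop = FALSE])
    cb <- colMeans(xyz[groupB_sel, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  degenerate <- length(unique(round(d, 9))) < 2L
  bw <- if (degenerate) 0.1 else stats::bw.nrd0(d)
  grid <- seq(floor(min(d) - 4 * bw), ceiling(max(d) + 4 * bw), by = 0.1)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, d, bw)), numeric(1))
  imax <- which.max(dens)
  modal <- grid[imax]
  half <- dens[imax] / 2
  above <- dens >= half
  # contiguous run containing the mode
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- which(runs$values & starts <= imax & ends >= imax)
  lo_i <- starts[k]; hi_i <- ends[k]
  interp <- function(i1, i2) {
    # crossing between grid[i1] (below) and grid[i2] (above)
    if (i1 < 1L || i1 > length(grid)) return(grid[i2])
    grid[i1] + (half - dens[i1]) / (dens[i2] - dens[i1]) *
      (grid[i2] - grid[i1])
  }
  lo <- interp(lo_i - 1L, lo_i)
  hi <- interp(hi_i + 1L, hi_i)
  multimodal <- sum(runs$values) > 1L
  structure(list(samples = d, grid = grid, density = dens, modal = modal,
                 fwhh = hi - lo, bandwidth = bw, multimodal = multimodal,
                 degenerate = degenerate),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "Distance distribution: n = %d, modal %.2f A, FWHH %.2f A%s%s\n",
    length(x$samples), x$modal, x$fwhh,
    if (x$multimodal) " (multimodal)" else "",
    if (x$degenerate) " (degenerate: bandwidth-limited)" else ""))
  invisible(x)
}

#' Extract the passage time of a substrate region through the pore
#'
#' Tracks the signed axial (z) offset of the region's centre of mass
#' relative to the pore-ring centre of mass. The passage time is the first
#' frame time at which the offset has changed sign relative to the starting
#' side and reaches the exit offset in magnitude; if that never happens the
#' record is "did not pass" (NA time).
#'
#' @param traj a \code{"trajectory"}.
#' @param region_sel atom indices of the substrate region.
#' @param pore_sel atom indices of the pore-ring residues.
#' @param exit_offset exit distance beyond the pore plane, Angstrom.
#' @return list of class \code{"passage_record"}: \code{passage_time} (ps,
#'   NA if it did not pass), \code{passed}, \code{start_side} (+1/-1),
#'   \code{offsets} (per-frame z offsets).
#' @export
passage_times <- function(traj, region_sel, pore_sel, exit_offset = 5) {
  if (length(region_sel) == 0L || length(pore_sel) == 0L)
    stop("region and pore selections must be non-empty")
  nf <- n_frames(traj)
  off <- vapply(seq_len(nf), function(f) {
    xyz <- frame_coords(traj, f)
    mean(xyz[region_sel, 3]) - mean(xyz[pore_sel, 3])
  }, numeric(1))
  side0 <- sign(off[1])
  if (side0 == 0) stop("region starts in the pore plane; start side undefined")
  crossed <- sign(off) == -side0 & abs(off) >= exit_offset - 1e-9
  idx <- which(crossed)
  if (length(idx) == 0L) {
    structure(list(passage_time = NA_real_, passed = FALSE,
                   start_side = side0, offsets = off),
              class = "passage_record")
  } else {
    structure(list(passage_time = traj$times[idx[1]] - traj$times[1],
                   passed = TRUE, start_side = side0, offsets = off),
              class = "passage_record")
  }
}

#' @export
print.passage_record <- function(x, ...) {
  if (x$passed) cat(sprintf("Passage at %g ps\n", x$passage_time))
  else cat("Did not pass\n")
  invisible(x)
}

#' Compare passage times between helical and unstructured substrates
#'
#' Ratio of group mean passage times (helix / coil) with a two-tailed
#' two-sample t-test on the per-replicate times. Records that did not pass
#' are excluded; their counts are reported.
#'
#' @param helix,coil lists of \code{"passage_record"} objects (or numeric
#'   vectors of passage times); >= 2 passed records per group.
#' @param test \code{"student"} or \code{"welch"}.
#' @return list: \code{ratio} (mean helix time / mean coil time), \code{t},
#'   \code{df}, \code{p}, \code{n_helix}, \code{n_coil},
#'   \code{n_did_not_pass}.
#' @export
passage_ratio <- function(helix, coil, test = c("student", "welch")) {
  test <- match.arg(test)
  times_of <- function(x) {
    if (is.numeric(x)) return(list(t = x[!is.na(x)], dnp = sum(is.na(x))))
    t <- vapply(x, `[[`, numeric(1), "passage_time")
    list(t = t[!is.na(t)], dnp = sum(is.na(t)))
  }
  h <- times_of(helix); c_ <- times_of(coil)
  if (length(h$t) < 2L || length(c_$t) < 2L)
    stop("need >= 2 passed records per group")
  tt <- asymmetry_test(h$t, c_$t, test = test)
  list(ratio = mean(h$t) / mean(c_$t), t = tt$t, df = tt$df, p = tt$p,
       n_helix = length(h$t), n_coil = length(c_$t),
       n_did_not_pass = h$dnp + c_$dnp)
}
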