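# Sphere-probe pore-radius profiling (HOLE-style), per-side cavity-volume
# integration by the trapezoidal rule, and pre-protein/channel contact
# fractions.

# clearance of a probe centre p = (cx, cy, z): smallest gap to any atom
# surface (3-D distance minus vdW radius). Negative inside an atom.
probe_clearance <- function(cxy, z, xyz, vdw) {
  dx <- xyz[, 1] - cxy[1]
  dy <- xyz[, 2] - cxy[2]
  dz <- xyz[, 3] - z
  min(sqrt(dx * dx + dy * dy + dz * dz) - vdw)
}

#' Sphere-probe pore-radius profile
#'
#' At each axial step the largest sphere centred in that plane that touches
#' no atom is found: the clearance \eqn{f(c) = \min_i (|c - x_i| - vdw_i)}
#' is maximised over the in-plane centre c by Nelder-Mead restarted from
#' five deterministically jittered seeds (0.5 Angstrom jitter), walking
#' along the axis seeded from the previous step's centre (step 0: the
#' pore-ring centroid). The search is confined to a 15 Angstrom in-plane
#' trust region around the seed; an optimum on that boundary means the
#' probe escaped the channel wall and the z level is flagged "burst" with
#' the radius capped at the boundary value. A seed inside an atom gives
#' radius 0 with a warning.
#'
#' @param traj a \code{"trajectory"}.
#' @param ring_resid pore-ring residue indices used to seed the profile
#'   (configurable; e.g. the four pore Ile residues).
#' @param frame frame index.
#' @param exclude atom indices to drop before profiling (e.g. the
#'   pre-protein when profiling the empty channel), or NULL.
#' @param zlim axial range relative to the pore-ring origin, Angstrom.
#' @param dz axial step, Angstrom (0.5 to match the trapezoid partitions).
#' @param trust_radius in-plane trust region, Angstrom.
#' @param origin optional explicit origin overriding the ring centroid
#'   (used by the synthetic fixtures, whose walls are not residues).
#' @return data.frame of class \code{"channel_profile"}: \code{z} (relative
#'   to origin), \code{radius}, \code{cx}, \code{cy} (centre path, absolute
#'   coordinates), \code{burst}.
#' @export
pore_profile <- function(traj, ring_resid = NULL, frame = 1L, exclude = NULL,
                         zlim = c(-6.5, 6.5), dz = 0.5, trust_radius = 15,
                         origin = NULL) {
  if (is.null(origin)) {
    cf <- channel_frame(traj, resid = ring_resid, frame = frame)
    origin <- cf$origin
  }
  xyz <- frame_coords(traj, frame)
  vdw <- traj$atoms$vdw
  keep <- setdiff(seq_len(n_atoms(traj)), exclude)
  if (length(keep) == 0L) stop("no atoms left after exclusion")
  xyz <- xyz[keep, , drop = FALSE]
  vdw <- vdw[keep]
  zs <- seq(zlim[1], zlim[2], by = dz)
  n <- length(zs)
  radius <- numeric(n); cx <- numeric(n); cy <- numeric(n)
  burst <- logical(n)
  # walk from z = 0 outwards in both directions, seeding each step from the
  # previous centre so the path follows the channel
  order_idx <- order(abs(zs), zs)
  seed_centre <- origin[1:2]
  seed_by_z <- list(pos = seed_centre, neg = seed_centre)
  jitters <- rbind(c(0, 0), c(0.5, 0), c(-0.5, 0), c(0, 0.5), c(0, -0.5))
  blocked <- numeric(0)
  for (i in order_idx) {
    zabs <- origin[3] + zs[i]
    seed <- if (zs[i] >= 0) seed_by_z$pos else seed_by_z$neg
    # a seed buried in an atom means the channel is occluded at this level
    if (probe_clearance(seed, zabs, xyz, vdw) < 0) {
      radius[i] <- 0
      cx[i] <- seed[1]; cy[i] <- seed[2]
      blocked <- c(blocked, zs[i])
      next
    }
    obj <- function(c2) {
      pen <- max(0, sqrt(sum((c2 - seed)^2)) - trust_radius)
      -(probe_clearance(c2, zabs, xyz, vdw) - 1e6 * pen * pen)
    }
    best <- NULL
    for (j in seq_len(nrow(jitters))) {
      st <- seed + jitters[j, ]
      opt <- stats::optim(st, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 500))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    ctr <- best$par
    r <- max(probe_clearance(ctr, zabs, xyz, vdw), 0)
    drift <- sqrt(sum((ctr - seed)^2))
    if (drift > trust_radius - 0.1) {
      burst[i] <- TRUE
    }
    radius[i] <- r
    cx[i] <- ctr[1]; cy[i] <- ctr[2]
    if (zs[i] >= 0) seed_by_z$pos <- ctr
    if (zs[i] <= 0) seed_by_z$neg <- ctr
  }
  if (length(blocked))
    warning("profile seed lies inside an atom at z = ",
            paste(sort(blocked), collapse = ", "), "; radius set to 0")
  out <- data.frame(z = zs, radius = radius, cx = cx, cy = cy, burst = burst)
  class(out) <- c("channel_profile", "data.frame")
  attr(out, "origin") <- origin
  out
}

#' @export
print.channel_profile <- function(x, ...) {
  cat(sprintf("Channel profile: %d steps, z in [%g, %g] A, radius %0.2f-%0.2f A%s\n",
              nrow(x), min(x$z), max(x$z), min(x$radius), max(x$radius),
              if (any(x$burst)) sprintf(" (%d burst)", sum(x$burst)) else ""))
  invisible(x)
}

#' Per-side cavity volumes from a pore profile
#'
#' Integrates \eqn{\pi r(z)^2} by the trapezoidal rule with 0.5 Angstrom
#' partitions over |z| in [0, 6.5] on each side of the pore ring:
#' cytoplasmic z > 0, exterior z < 0. Exact for a constant radius.
#'
#' @param profile a \code{"channel_profile"} covering at least
#'   [-6.5, +6.5] Angstrom on the 0.5 Angstrom grid.
#' @param zmax per-side integration limit, Angstrom.
#' @return list with \code{v_cyt}, \code{v_ext} (cubic Angstrom) and their
#'   ratio \code{cyt_over_ext}.
#' @export
cavity_volumes <- function(profile, zmax = 6.5) {
  z <- profile$z
  dz <- 0.5
  grid <- seq(0, zmax, by = dz)
  side <- function(sgn) {
    zz <- sgn * grid
    idx <- match(round(zz, 6), round(z, 6))
    if (anyNA(idx))
      stop("profile does not cover |z| <= ", zmax,
           " on the ", dz, " A grid")
    r <- profile$radius[idx]
    y <- pi * r^2
    sum((y[-1] + y[-length(y)]) / 2) * dz
  }
  v_cyt <- side(+1); v_ext <- side(-1)
  list(v_cyt = v_cyt, v_ext = v_ext,
       cyt_over_ext = if (v_ext > 0) v_cyt / v_ext else NA_real_)
}

#' Aggregate per-snapshot cavity volumes
#'
#' @param volumes list of [cavity_volumes()] results (one per snapshot).
#' @return data.frame with one row per side: median, first and third
#'   quartile of the per-snapshot volumes.
#' @export
aggregate_volumes <- function(volumes) {
  vc <- vapply(volumes, `[[`, numeric(1), "v_cyt")
  ve <- vapply(volumes, `[[`, numeric(1), "v_ext")
  summ <- function(v) c(median = stats::median(v),
                        q1 = unname(stats::quantile(v, 0.25)),
                        q3 = unname(stats::quantile(v, 0.75)))
  out <- rbind(data.frame(side = "cytoplasmic", t(summ(vc)), n = length(vc)),
               data.frame(side = "exterior", t(summ(ve)), n = length(ve)))
  out
}

#' Fraction of pre-protein residues in contact with the channel
#'
#' A pre-protein residue is in contact in a frame when the minimum
#' heavy-atom (non-hydrogen) distance to any channel atom is below the
#' cutoff (0.3 nm = 3 Angstrom). The fraction is averaged over the window's
#' residues within each frame, then over frames.
#'
#' @param traj a \code{"trajectory"}.
#' @param pp_window inclusive residue interval of the pre-protein window.
#' @param pp_chain chain of the pre-protein.
#' @param channel_sel atom indices of the channel.
#' @param cutoff contact cutoff, Angstrom.
#' @param frames frame indices (default all).
#' @return list with \code{fraction} (scalar), \code{per_frame},
#'   \code{per_residue} (fraction of frames each residue is in contact).
#' @export
contact_fraction <- function(traj, pp_window, pp_chain = "P", channel_sel,
                             cutoff = 3, frames = NULL) {
  if (length(channel_sel) == 0L) stop("channel selection is empty")
  pp_res <- pp_window[1]:pp_window[2]
  pp_idx <- select_atoms(traj, resid = pp_res, chain = pp_chain,
                         heavy = TRUE)
  if (length(pp_idx) == 0L) stop("pre-protein selection is empty")
  ch_idx <- channel_sel[traj$atoms$element[channel_sel] != "H"]
  if (length(ch_idx) == 0L) stop("channel selection has no heavy atoms")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  resof <- traj$atoms$resid[pp_idx]
  contact_mat <- matrix(FALSE, nrow = length(pp_res), ncol = length(frames))
  for (fi in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[fi])
    pxyz <- xyz[pp_idx, , drop = FALSE]
    cxyz <- xyz[ch_idx, , drop = FALSE]
    d2 <- outer(rowSums(pxyz^2), rowSums(cxyz^2), "+") -
      2 * pxyz %*% t(cxyz)
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    for (ri in seq_along(pp_res)) {
      da <- mind[resof == pp_res[ri]]
      contact_mat[ri, fi] <- length(da) > 0 && min(da) < cutoff
    }
  }
  per_frame <- colMeans(contact_mat)
  list(fraction = mean(per_frame), per_frame = per_frame,
       per_residue = stats::setNames(rowMeans(contact_mat), pp_res))
}

#' Mean and s.e.m. of replicate contact fractions
#'
#' @param fractions numeric vector of per-replicate window-average contact
#'   fractions.
#' @return list with \code{mean}, \code{sem}, \code{n}.
#' @export
aggregate_contacts <- function(fractions) {
  list(mean = mean(fractions), sem = sem(fractions), n = length(fractions))
}
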