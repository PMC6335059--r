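# Prism-sliced water MSD analysis and power-law exponent fitting.
# The analysed region is a rectangular prism centred on the pore-ring
# origin (default 5 x 5 x 12 nm, 24 slices of 0.5 nm), matching the
# water-dynamics protocol around SecY.

#' Prism specification for water slicing
#'
#' @param cross_section in-plane extent (x, y) of the prism, Angstrom.
#' @param height axial extent, Angstrom.
#' @param slice_thickness slice thickness, Angstrom; \code{height} must be
#'   an integer multiple of it.
#' @param origin centre of the prism (pore-ring origin), length-3 Angstrom.
#' @return list of class \code{"prism_spec"}; \code{n_slices} is the slice
#'   count (24 for the default 120/5 partition).
#' @export
prism_spec <- function(cross_section = c(50, 50), height = 120,
                       slice_thickness = 5, origin = c(0, 0, 0)) {
  n <- height / slice_thickness
  if (abs(n - round(n)) > 1e-9)
    stop("height must be an integer multiple of slice_thickness")
  structure(list(cross_section = cross_section, height = height,
                 slice_thickness = slice_thickness, origin = origin,
                 n_slices = as.integer(round(n))),
            class = "prism_spec")
}

#' Assign water particles to prism slices
#'
#' Membership is decided once, from each particle's position at the first
#' analysed frame (origin-time assignment; particles are not re-binned as
#' they drift). Particles outside the prism at the origin time are excluded
#' (index NA). Slices are numbered 0-based from the exterior end
#' (z = -height/2) so the first cytoplasmic slice above the origin has index
#' \code{n_slices / 2}.
#'
#' @param traj a \code{"trajectory"}.
#' @param prism a \code{"prism_spec"}.
#' @param water_sel atom indices of the waters (default: all atoms).
#' @param frame origin frame for the assignment.
#' @return integer vector (length of \code{water_sel}) of 0-based slice
#'   indices, NA for excluded particles.
#' @export
assign_slices <- function(traj, prism, water_sel = NULL, frame = 1L) {
  if (is.null(water_sel)) water_sel <- seq_len(n_atoms(traj))
  if (length(water_sel) == 0L) stop("water selection is empty")
  xyz <- frame_coords(traj, frame)[water_sel, , drop = FALSE]
  rel <- sweep(xyz, 2, prism$origin)
  half_xy <- prism$cross_section / 2
  half_z <- prism$height / 2
  inside <- abs(rel[, 1]) <= half_xy[1] & abs(rel[, 2]) <= half_xy[2] &
    rel[, 3] >= -half_z & rel[, 3] < half_z
  idx <- rep(NA_integer_, length(water_sel))
  idx[inside] <- as.integer(floor((rel[inside, 3] + half_z) /
                                    prism$slice_thickness))
  idx[!is.na(idx) & idx == prism$n_slices] <- prism$n_slices - 1L
  idx
}

#' Per-slice mean squared displacement
#'
#' MSD(t) is averaged over member particles and over all sliding time
#' origins (every frame, overlapping): \eqn{MSD(\Delta) = \langle |r(t_0 +
#' \Delta) - r(t_0)|^2 \rangle}. MSD(0) = 0 exactly. Particles that leave
#' the prism mid-window are kept (membership is fixed at the origin time);
#' set \code{censor_leavers} to drop any particle that strays outside the
#' prism at any analysed frame.
#'
#' @param traj a \code{"trajectory"} (frames must be evenly spaced).
#' @param membership 0-based slice index per atom of \code{water_sel}
#'   (from [assign_slices()]); NA particles are skipped.
#' @param water_sel atom indices matching \code{membership} (default all).
#' @param prism prism spec, only needed when \code{censor_leavers = TRUE}.
#' @param censor_leavers drop particles that exit the prism mid-run.
#' @return object of class \code{"slice_msd"}: list with \code{t} (lag
#'   times, ps) and \code{msd} (matrix lags x slices, Angstrom^2; NA column
#'   for empty slices) and \code{n} (particles per slice).
#' @export
slice_msd <- function(traj, membership, water_sel = NULL, prism = NULL,
                      censor_leavers = FALSE) {
  if (is.null(water_sel)) water_sel <- seq_len(n_atoms(traj))
  stopifnot(length(membership) == length(water_sel))
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames for MSD")
  slices0 <- sort(unique(membership[!is.na(membership)]))
  if (censor_leavers) {
    if (is.null(prism)) stop("prism needed to censor leavers")
    half_xy <- prism$cross_section / 2
    half_z <- prism$height / 2
    for (f in seq_len(nf)) {
      rel <- sweep(frame_coords(traj, f)[water_sel, , drop = FALSE], 2,
                   prism$origin)
      out <- abs(rel[, 1]) > half_xy[1] | abs(rel[, 2]) > half_xy[2] |
        abs(rel[, 3]) > half_z
      membership[out] <- NA_integer_
    }
  }
  all_slices <- if (length(slices0)) seq(0L, max(slices0)) else integer(0)
  lags <- seq_len(nf - 1L)
  msd <- matrix(NA_real_, nrow = nf, ncol = length(all_slices),
                dimnames = list(NULL, all_slices))
  nper <- integer(length(all_slices))
  for (si in seq_along(all_slices)) {
    s <- all_slices[si]
    members <- water_sel[!is.na(membership) & membership == s]
    nper[si] <- length(members)
    if (length(members) == 0L) next
    x <- traj$coords[members, , , drop = FALSE]
    m <- length(members)
    acc <- numeric(nf)
    acc[1] <- 0
    for (d in lags) {
      diff <- x[, , (1L + d):nf, drop = FALSE] - x[, , 1L:(nf - d),
                                                   drop = FALSE]
      # mean over particles and origins of the squared 3-D displacement
      acc[d + 1L] <- sum(diff * diff) / (m * (nf - d))
    }
    msd[, si] <- acc
  }
  structure(list(t = traj$times - traj$times[1], msd = msd,
                 n = stats::setNames(nper, all_slices),
                 slices = all_slices),
            class = "slice_msd")
}

#' Fit a power law MSD(t) = k t^A
#'
#' Least-squares straight line on (log t, log MSD) over the fit window; the
#' exponent A is the slope and k = exp(intercept). By default the window is
#' the final 25 ps of the curve. Non-positive MSD values in the window are
#' dropped; at least 5 points must remain.
#'
#' @param t lag times, ps.
#' @param msd MSD values, Angstrom^2.
#' @param window length of the terminal fit window, ps.
#' @return list of class \code{"msd_fit"}: \code{k}, \code{A}, \code{r2},
#'   \code{n_points}, \code{window}.
#' @export
fit_power_law <- function(t, msd, window = 25) {
  stopifnot(length(t) == length(msd))
  tmax <- max(t)
  keep <- t >= tmax - window & t > 0 & is.finite(msd)
  keep <- keep & msd > 0
  if (sum(keep) < 5L)
    stop("fewer than 5 positive (t, MSD) points in the fit window")
  lt <- log(t[keep]); lm_ <- log(msd[keep])
  fit <- stats::lm(lm_ ~ lt)
  sst <- sum((lm_ - mean(lm_))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(k = exp(unname(stats::coef(fit)[1])),
                 A = unname(stats::coef(fit)[2]),
                 r2 = min(max(r2, 0), 1),
                 n_points = sum(keep), window = window),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD power-law fit: A = %.3f, k = %.3g (r^2 = %.4f, %d points)\n",
              x$A, x$k, x$r2, x$n_points))
  invisible(x)
}

#' Per-slice MSD exponent profile across replicate simulations
#'
#' For each replicate trajectory, waters are assigned to prism slices at
#' the origin time, per-slice MSD curves are computed and the terminal
#' window fitted to MSD = k t^A; the exponent A per slice is then averaged
#' across replicates with its standard error.
#'
#' @param trajs list of replicate \code{"trajectory"} objects (>= 2 for a
#'   standard error).
#' @param prism a \code{"prism_spec"}.
#' @param water_sel atom indices of waters (same topology in all
#'   replicates), default all atoms.
#' @param window power-law fit window, ps.
#' @return data.frame of class \code{"slice_series"}: \code{slice} (0-based),
#'   \code{z_mid} (Angstrom, relative to the origin), \code{A_mean},
#'   \code{A_sem}, \code{n_rep}, \code{n_waters} (mean per replicate).
#' @export
slice_exponent_profile <- function(trajs, prism, water_sel = NULL,
                                   window = 25) {
  if (length(trajs) < 2L) stop("need >= 2 replicate trajectories")
  ns <- prism$n_slices
  A <- matrix(NA_real_, nrow = ns, ncol = length(trajs))
  nw <- matrix(0L, nrow = ns, ncol = length(trajs))
  for (r in seq_along(trajs)) {
    traj <- trajs[[r]]
    mem <- assign_slices(traj, prism, water_sel)
    sm <- slice_msd(traj, mem, water_sel)
    for (si in seq_along(sm$slices)) {
      s <- sm$slices[si]
      if (s >= ns || sm$n[si] == 0L) next
      nw[s + 1L, r] <- sm$n[si]
      fit <- tryCatch(fit_power_law(sm$t, sm$msd[, si], window),
                      error = function(e) NULL)
      if (!is.null(fit)) A[s + 1L, r] <- fit$A
    }
  }
  a_mean <- rowMeans(A, na.rm = TRUE)
  a_sem <- apply(A, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- data.frame(slice = seq_len(ns) - 1L,
                    z_mid = -prism$height / 2 +
                      (seq_len(ns) - 0.5) * prism$slice_thickness,
                    A_mean = ifelse(is.nan(a_mean), NA, a_mean),
                    A_sem = a_sem,
                    n_rep = rowSums(!is.na(A)),
                    n_waters = rowMeans(nw))
  class(out) <- c("slice_series", "data.frame")
  out
}
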