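# Synthetic-data generators. Every input class the pipeline consumes can be
# produced here with known ground truth, so each analysis stage is testable
# at desk scale. All generators are deterministic given (arguments, seed).

# Ideal backbone internal coordinates (Angstrom / degrees).
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.8, omega = 180)

# Place atom d given positions a, b, c, bond |c-d|, angle b-c-d and
# dihedral a-b-c-d (degrees). Natural-extension reference frame.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal polypeptide backbone
#'
#' Constructs N, CA, C, O atoms per residue from ideal internal coordinates
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom, standard angles,
#' trans peptide bonds) with prescribed backbone dihedrals. Defaults:
#' alpha-helix phi/psi -57/-47, 3_10-helix -49/-26; coil dihedrals are drawn
#' uniformly from the extended region (phi in [-180, -60], psi in [90, 180])
#' so that no i -> i+3/i+4 hydrogen bonds can form.
#'
#' @param n_residues number of residues (>= 4 for \code{"alpha"}, >= 3 for
#'   \code{"three_ten"}).
#' @param kind \code{"alpha"}, \code{"three_ten"} or \code{"coil"}.
#' @param phi,psi optional explicit dihedrals (degrees), scalar or length
#'   \code{n_residues}; override the kind defaults.
#' @param sequence optional one-letter amino-acid string of length
#'   \code{n_residues} (controls residue names, e.g. to place prolines);
#'   default poly-alanine.
#' @param chain chain identifier.
#' @param seed RNG seed (used for coil sampling).
#' @return single-frame \code{"trajectory"}.
#' @export
build_backbone <- function(n_residues, kind = c("alpha", "three_ten", "coil"),
                           phi = NULL, psi = NULL, sequence = NULL,
                           chain = "P", seed = 1L) {
  kind <- match.arg(kind)
  minr <- switch(kind, alpha = 4L, three_ten = 3L, coil = 2L)
  if (n_residues < minr)
    stop("n_residues must be >= ", minr, " for kind '", kind, "'")
  defaults <- switch(kind,
                     alpha = c(-57, -47),
                     three_ten = c(-49, -26),
                     coil = NULL)
  if (kind == "coil") {
    dih <- with_seed(seed, list(phi = stats::runif(n_residues, -180, -60),
                                psi = stats::runif(n_residues, 90, 180)))
    if (is.null(phi)) phi <- dih$phi
    if (is.null(psi)) psi <- dih$psi
  } else {
    if (is.null(phi)) phi <- defaults[1]
    if (is.null(psi)) psi <- defaults[2]
  }
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)

  if (!is.null(sequence)) {
    seq1 <- strsplit(sequence, "")[[1]]
    if (length(seq1) != n_residues)
      stop("sequence length must equal n_residues")
    resnames <- bio3d::aa123(seq1)
  } else {
    resnames <- rep("ALA", n_residues)
  }

  pos <- matrix(NA_real_, nrow = 4L * n_residues, ncol = 3)
  # atom order: N, CA, C, O per residue
  idx <- function(i, k) (i - 1L) * 4L + k  # k: 1=N 2=CA 3=C 4=O
  b <- .BB
  pos[idx(1, 1), ] <- c(0, 0, 0)
  pos[idx(1, 2), ] <- c(b$b_n_ca, 0, 0)
  a0 <- b$a_n_ca_c * pi / 180
  pos[idx(1, 3), ] <- pos[idx(1, 2), ] +
    b$b_ca_c * c(-cos(a0), sin(a0), 0)
  for (i in seq_len(n_residues)) {
    N <- pos[idx(i, 1), ]; CA <- pos[idx(i, 2), ]; C <- pos[idx(i, 3), ]
    # carbonyl O in the peptide plane, anti to the next N
    pos[idx(i, 4), ] <- place_atom(N, CA, C, b$b_c_o, b$a_ca_c_o,
                                   psi[i] + 180)
    if (i < n_residues) {
      Nn <- place_atom(N, CA, C, b$b_c_n, b$a_ca_c_n, psi[i])
      CAn <- place_atom(CA, C, Nn, b$b_n_ca, b$a_c_n_ca, b$omega)
      Cn <- place_atom(C, Nn, CAn, b$b_ca_c, b$a_n_ca_c, phi[i + 1])
      pos[idx(i + 1, 1), ] <- Nn
      pos[idx(i + 1, 2), ] <- CAn
      pos[idx(i + 1, 3), ] <- Cn
    }
  }
  atoms <- data.frame(
    serial = seq_len(4L * n_residues),
    name = rep(c("N", "CA", "C", "O"), n_residues),
    element = rep(c("N", "C", "C", "O"), n_residues),
    resname = rep(resnames, each = 4L),
    resid = rep(seq_len(n_residues), each = 4L),
    chain = chain, stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element)
  trajectory(atoms, pos)
}

#' Analytic accessible radius of a synthetic channel
#'
#' @param spec list returned as the \code{"channel_spec"} attribute of
#'   [build_channel()] (fields \code{r0}, \code{slope_cyt},
#'   \code{slope_ext}).
#' @param z axial coordinate(s), Angstrom; cytoplasmic side is z > 0.
#' @return radius r(z) = r0 + slope_side * |z| in Angstrom.
#' @export
channel_radius <- function(spec, z) {
  slope <- ifelse(z >= 0, spec$slope_cyt, spec$slope_ext)
  spec$r0 + slope * abs(z)
}

#' Analytic per-side cavity volume of a synthetic channel
#'
#' Closed form of the solid-of-revolution integral
#' \eqn{\int_0^{z_{max}} \pi (r_0 + s z)^2 dz}.
#'
#' @param spec channel spec (see [channel_radius()]).
#' @param side \code{"cytoplasmic"} or \code{"exterior"}.
#' @param zmax integration limit, Angstrom (default 6.5).
#' @return volume in cubic Angstrom.
#' @export
channel_side_volume <- function(spec, side = c("cytoplasmic", "exterior"),
                                zmax = 6.5) {
  side <- match.arg(side)
  s <- if (side == "cytoplasmic") spec$slope_cyt else spec$slope_ext
  r0 <- spec$r0
  pi * (r0^2 * zmax + r0 * s * zmax^2 + s^2 * zmax^3 / 3)
}

#' Build a channel-shaped wall of pseudo-atoms
#'
#' Tiles a surface of revolution with pseudo-atoms of van der Waals radius
#' \code{wall_vdw} such that the sphere-probe accessible radius at every
#' axial position is exactly r(z) = r0 + slope * |z| (slope per side). For
#' a sloped wall a sphere centred in the plane at z touches the wall
#' obliquely, so the atom centres are laid on the envelope surface
#' \eqn{\rho(z) = (r_0 + vdw + s |z|) / \sqrt{1 - s^2}}, which has
#' perpendicular clearance r(z) from every on-axis point; for a cylinder
#' this reduces to centres at r0 + vdw. The analytic profile is recoverable
#' from the \code{"channel_spec"} attribute; the discretisation error of a
#' profiled radius is below \code{wall_atom_spacing / 2}. Wall slopes must
#' be below 1 Angstrom/Angstrom.
#'
#' @param shape \code{"cylinder"} (slopes forced to 0),
#'   \code{"hourglass"} (equal slopes) or \code{"asymmetric-hourglass"}.
#' @param r0 waist (pore-ring) radius, Angstrom.
#' @param slope_cyt,slope_ext wall slope per side, Angstrom per Angstrom.
#' @param half_length axial half-extent of the analysed region, Angstrom;
#'   walls are tiled a little beyond it so a probe at the boundary is still
#'   enclosed.
#' @param wall_atom_spacing nominal spacing of wall atoms, Angstrom.
#' @param wall_vdw van der Waals radius of wall atoms, Angstrom.
#' @return single-frame \code{"trajectory"} with attribute
#'   \code{"channel_spec"}.
#' @export
build_channel <- function(shape = c("cylinder", "hourglass",
                                    "asymmetric-hourglass"),
                          r0 = 3, slope_cyt = 0, slope_ext = 0,
                          half_length = 6.5, wall_atom_spacing = 0.5,
                          wall_vdw = 1.5) {
  shape <- match.arg(shape)
  if (shape == "cylinder") slope_cyt <- slope_ext <- 0
  if (shape == "hourglass") slope_ext <- slope_cyt
  if (r0 <= 0) stop("r0 must be positive")
  if (abs(slope_cyt) >= 1 || abs(slope_ext) >= 1)
    stop("wall slopes must have magnitude < 1")
  spec <- list(shape = shape, r0 = r0, slope_cyt = slope_cyt,
               slope_ext = slope_ext, half_length = half_length,
               wall_atom_spacing = wall_atom_spacing, wall_vdw = wall_vdw)
  step <- wall_atom_spacing
  zpad <- half_length + 2
  zs <- seq(-zpad, zpad, by = step)
  rows <- lapply(zs, function(z) {
    s <- if (z >= 0) slope_cyt else slope_ext
    rc <- (r0 + wall_vdw + s * abs(z)) / sqrt(1 - s^2)
    nth <- max(8L, ceiling(2 * pi * rc / step))
    th <- 2 * pi * (seq_len(nth) - 1L) / nth
    cbind(rc * cos(th), rc * sin(th), z)
  })
  xyz <- do.call(rbind, rows)
  # at the waist of an asymmetric channel the wide side's probe spheres
  # overlap the narrow side's wall; atoms strictly inside the union of
  # target spheres B((0,0,z'), r(z') + wall_vdw) are pruned so the wall is
  # the realizable envelope of the requested profile
  if (slope_cyt != slope_ext) {
    zp <- seq(-zpad, zpad, by = 0.05)
    Rz <- channel_radius(spec, zp) + wall_vdw
    rho2 <- xyz[, 1]^2 + xyz[, 2]^2
    inside <- vapply(seq_len(nrow(xyz)), function(i) {
      any(rho2[i] + (xyz[i, 3] - zp)^2 < (Rz - 1e-6)^2)
    }, logical(1))
    xyz <- xyz[!inside, , drop = FALSE]
  }
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = "W", element = "X",
                      resname = "WAL", resid = seq_len(n), chain = "W",
                      vdw = wall_vdw, stringsAsFactors = FALSE)
  out <- trajectory(atoms, xyz)
  attr(out, "channel_spec") <- spec
  out
}

# Stationary fractional Gaussian noise by circulant embedding
# (Davies-Harte). Returns an n x m matrix of m independent series with
# increment variance sigma2 and Hurst exponent H.
fgn_sample <- function(n, m, H, sigma2) {
  if (H <= 0 || H > 1) stop("Hurst exponent must be in (0, 1]")
  if (sigma2 == 0 || m == 0L) return(matrix(0, n, m))
  if (H == 1) {
    # perfectly correlated increments: one normal per series, repeated
    v <- stats::rnorm(m, sd = sqrt(sigma2))
    return(matrix(rep(v, each = n), n, m))
  }
  if (n == 1L) return(matrix(stats::rnorm(m, sd = sqrt(sigma2)), 1L, m))
  k <- 0:n
  gam <- sigma2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                         abs(k - 1)^(2 * H))
  M <- 2L * n
  circ <- c(gam[1:(n + 1)], gam[n:2])
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0  # guard tiny negative round-off
  w <- matrix(0 + 0i, M, m)
  w[1, ] <- stats::rnorm(m)
  w[n + 1, ] <- stats::rnorm(m)
  nin <- n - 1L
  if (nin > 0L) {
    u <- matrix(stats::rnorm(nin * m), nin, m)
    v <- matrix(stats::rnorm(nin * m), nin, m)
    z <- (u + 1i * v) / sqrt(2)
    w[2:n, ] <- z
    w[M:(n + 2), ] <- Conj(z)
  }
  x <- Re(stats::mvfft(sqrt(lam) * w)) / sqrt(M)
  x[1:n, , drop = FALSE]
}

#' Build a synthetic water bath with position-dependent diffusive dynamics
#'
#' Particles start uniformly in an orthorhombic box centred on the origin
#' and move by fractional Gaussian noise increments with Hurst exponent H
#' evaluated at each particle's initial z (particles do not change regime
#' mid-run). The per-dimension increment variance is
#' \eqn{2 D \, dt^{2H}}, so the ensemble MSD obeys
#' \eqn{MSD(t) = 6 D t^{2H}}: the ground-truth power-law exponent is 2H and
#' H = 0.5 reduces to normal Brownian motion with MSD = 6 D t.
#'
#' @param n_particles number of water pseudo-atoms.
#' @param box box edge lengths (3 values, Angstrom), centred at the origin.
#' @param H Hurst exponent in (0, 1]: a scalar, or a function of the initial
#'   z coordinate (Angstrom) returning H.
#' @param D diffusion coefficient, Angstrom^2/ps.
#' @param dt frame interval, ps.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return \code{"trajectory"} of water oxygens with attribute
#'   \code{"bath_H"} giving each particle's ground-truth H.
#' @export
build_bath <- function(n_particles, box = c(50, 50, 120), H = 0.5, D = 0.1,
                       dt = 0.5, n_frames = 100, seed = 1L) {
  stopifnot(n_particles >= 1, n_frames >= 2, dt > 0, D >= 0)
  with_seed(seed, {
    x0 <- cbind(stats::runif(n_particles, -box[1] / 2, box[1] / 2),
                stats::runif(n_particles, -box[2] / 2, box[2] / 2),
                stats::runif(n_particles, -box[3] / 2, box[3] / 2))
    Hp <- if (is.function(H)) vapply(x0[, 3], H, numeric(1)) else
      rep_len(H, n_particles)
    if (any(Hp <= 0 | Hp > 1)) stop("Hurst exponent must be in (0, 1]")
    nsteps <- n_frames - 1L
    coords <- array(NA_real_, dim = c(n_particles, 3, n_frames))
    coords[, , 1] <- x0
    for (h in unique(Hp)) {
      sel <- which(Hp == h)
      sigma2 <- 2 * D * dt^(2 * h)
      inc <- fgn_sample(nsteps, 3L * length(sel), h, sigma2)
      dim(inc) <- c(nsteps, length(sel), 3L)
      for (f in seq_len(nsteps)) {
        coords[sel, , f + 1L] <- coords[sel, , f] + inc[f, , ]
      }
    }
    atoms <- data.frame(serial = seq_len(n_particles), name = "OW",
                        element = "O", resname = "HOH",
                        resid = seq_len(n_particles), chain = "S",
                        stringsAsFactors = FALSE)
    atoms$vdw <- vdw_radius(atoms$element)
    out <- trajectory(atoms, coords, times = (seq_len(n_frames) - 1) * dt,
                      box = box)
    attr(out, "bath_H") <- Hp
    out
  })
}

#' Duplicate a 9-residue seed into an 18-residue substrate
#'
#' The pre-protein substrates threaded through the channel are built by
#' duplicating a nine-residue seed either mirrored (seed followed by its
#' reverse) or in tandem (seed repeated).
#'
#' @param seed9 character string of exactly 9 one-letter residue codes.
#' @param mode \code{"mirrored"} or \code{"tandem"}.
#' @return 18-character substrate sequence.
#' @export
construct_substrate <- function(seed9, mode = c("mirrored", "tandem")) {
  mode <- match.arg(mode)
  if (!is.character(seed9) || length(seed9) != 1L || nchar(seed9) != 9L)
    stop("seed9 must be a single string of 9 residues")
  rev9 <- paste(rev(strsplit(seed9, "")[[1]]), collapse = "")
  if (mode == "mirrored") paste0(seed9, rev9) else paste0(seed9, seed9)
}

#' Substitute a residue window with glycine
#'
#' @param seq one-letter sequence string.
#' @param window inclusive 1-based residue interval \code{c(start, end)}, or
#'   NULL / zero-length for the identity.
#' @return sequence with the window replaced by G, same length.
#' @export
glycine_scan <- function(seq, window) {
  if (is.null(window) || length(window) == 0L) return(seq)
  stopifnot(length(window) == 2L)
  n <- nchar(seq)
  if (window[1] < 1L || window[2] > n || window[1] > window[2])
    stop("window [", window[1], ", ", window[2],
         "] out of range for sequence of length ", n)
  chars <- strsplit(seq, "")[[1]]
  chars[window[1]:window[2]] <- "G"
  paste(chars, collapse = "")
}

#' Build a replicate HDX uptake table with known truth
#'
#' Replicate uptakes are the true uptake plus Gaussian noise, clipped to
#' [0, exchangeable amides] where the exchangeable-amide count of a peptide
#' spanning residues start..end is end - start (the N-terminal residue does
#' not retain deuterium).
#'
#' @param truth data.frame with columns \code{peptide_id}, \code{start},
#'   \code{end}, \code{state} (\code{"ATP"}/\code{"ADP"}),
#'   \code{timepoint} (minutes), \code{uptake} (Da, the true value).
#' @param noise_sd replicate noise standard deviation, Da.
#' @param n_replicates replicates per cell (default 3, as for triplicate
#'   HDX measurements).
#' @param seed RNG seed.
#' @return data.frame of class \code{"uptake_table"} with one row per
#'   replicate measurement.
#' @export
build_hdx_table <- function(truth, noise_sd = 0.05, n_replicates = 3L,
                            seed = 1L) {
  need <- c("peptide_id", "start", "end", "state", "timepoint", "uptake")
  if (!all(need %in% names(truth)))
    stop("truth must have columns ", paste(need, collapse = ", "))
  with_seed(seed, {
    idx <- rep(seq_len(nrow(truth)), each = n_replicates)
    out <- truth[idx, c("peptide_id", "start", "end", "state", "timepoint")]
    out$replicate <- rep(seq_len(n_replicates), times = nrow(truth))
    up <- truth$uptake[idx] + stats::rnorm(length(idx), 0, noise_sd)
    amides <- pmax(out$end - out$start, 1L)
    out$uptake <- pmin(pmax(up, 0), amides)
    rownames(out) <- NULL
    class(out) <- c("uptake_table", "data.frame")
    out
  })
}

#' Build a paired spin-label ensemble with a known distance distribution
#'
#' Each frame holds two nitroxide-oxygen pseudo-atoms whose centroid
#' separation is drawn from Normal(mean, sd), truncated at zero.
#'
#' @param n number of frames (ensemble members).
#' @param mean,sd distance distribution parameters, Angstrom.
#' @param seed RNG seed.
#' @return \code{"trajectory"} with atoms named ON in residues 1 (label A)
#'   and 2 (label B).
#' @export
build_label_ensemble <- function(n, mean = 27, sd = 1.7, seed = 1L) {
  with_seed(seed, {
    d <- stats::rnorm(n, mean, sd)
    d[d <= 0] <- .Machine$double.eps
    coords <- array(0, dim = c(2L, 3L, n))
    coords[2, 1, ] <- d
    atoms <- data.frame(serial = 1:2, name = "ON", element = "O",
                        resname = c("SL1", "SL2"), resid = 1:2,
                        chain = "X", stringsAsFactors = FALSE)
    atoms$vdw <- vdw_radius(atoms$element)
    trajectory(atoms, coords, times = seq_len(n) - 1)
  })
}

#' Build a steered-passage time series
#'
#' Produces a two-atom trajectory: a fixed pore pseudo-atom at the origin
#' and a substrate-region pseudo-atom at (0, 0, z(t)), for testing
#' passage-time extraction against closed-form crossing times.
#'
#' @param z numeric vector of axial offsets (Angstrom) of the region
#'   centre of mass relative to the pore ring, one per frame.
#' @param dt frame interval, ps.
#' @return \code{"trajectory"} with residue 1 = pore (resname POR) and
#'   residue 2 = region (resname REG).
#' @export
build_passage_series <- function(z, dt = 1) {
  n <- length(z)
  coords <- array(0, dim = c(2L, 3L, n))
  coords[2, 3, ] <- z
  atoms <- data.frame(serial = 1:2, name = c("P", "R"), element = "C",
                      resname = c("POR", "REG"), resid = 1:2, chain = "Z",
                      stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element)
  trajectory(atoms, coords, times = (seq_len(n) - 1) * dt)
}
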