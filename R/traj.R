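#' @keywords internal
"_PACKAGE"

# van der Waals radii (Angstrom) used when the source file carries no radius.
.VDW_TABLE <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.VDW_DEFAULT <- 1.70

#' Resolve an element symbol from an atom name
#'
#' Strips leading digits and whitespace from a PDB-style atom name and takes
#' the first alphabetic character, uppercased. This is the documented lookup
#' used whenever a structure file does not state the element.
#'
#' @param name character vector of atom names (e.g. "CA", "1HB", "OXT").
#' @return character vector of element symbols.
#' @export
element_from_name <- function(name) {
  stripped <- sub("^[0-9 ]+", "", name)
  toupper(substr(stripped, 1L, 1L))
}

#' van der Waals radius for an element
#'
#' Lookup table: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Angstrom.
#' Unknown elements fall back to 1.70 Angstrom with a warning.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  element <- toupper(element)
  r <- unname(.VDW_TABLE[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default vdW radius ", .VDW_DEFAULT, " A")
    r[is.na(r)] <- .VDW_DEFAULT
  }
  r
}

#' Construct a trajectory object
#'
#' The central container of the package: an atom table plus an ordered stack
#' of coordinate frames. Coordinates are in Angstrom, times in picoseconds.
#' No periodic-boundary imaging is applied by any analysis operator; inputs
#' are assumed pre-imaged.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resid} (1-based, as in the source
#'   file), \code{chain}, \code{vdw} (Angstrom). Missing \code{element} is
#'   resolved via [element_from_name()]; missing \code{vdw} via
#'   [vdw_radius()].
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}, or a matrix
#'   \code{[n_atoms, 3]} for a single frame.
#' @param times numeric vector of frame times (ps), non-negative and strictly
#'   increasing. Defaults to \code{0, 1, 2, ...}.
#' @param box optional orthorhombic box lengths (3 values, Angstrom).
#' @return an object of class \code{"trajectory"}.
#' @export
trajectory <- function(atoms, coords, times = NULL, box = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (n_frames < 1L) stop("a trajectory needs at least one frame")
  if (nrow(atoms) != n_atoms)
    stop("coordinate count (", n_atoms, ") does not match atom count (",
         nrow(atoms), ")")
  if (is.null(atoms$element)) atoms$element <- element_from_name(atoms$name)
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  if (any(atoms$vdw <= 0)) stop("vdw radii must be positive")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n_atoms)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(times)) times <- seq_len(n_frames) - 1
  if (length(times) != n_frames)
    stop("times length must equal the number of frames")
  if (any(times < 0) || (n_frames > 1L && any(diff(times) <= 0)))
    stop("frame times must be non-negative and strictly increasing")
  structure(list(atoms = atoms, coords = coords,
                 times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "atoms,", dim(x$coords)[3], "frames\n")
  cat("  time range:", x$times[1], "-", x$times[length(x$times)], "ps\n")
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a \code{"trajectory"}.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a \code{"trajectory"}.
#' @param frame 1-based frame index.
#' @return numeric matrix \code{[n_atoms, 3]}.
#' @export
frame_coords <- function(traj, frame = 1L) {
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Select atom indices by attributes
#'
#' All given filters are combined with AND; vector-valued filters match any
#' of the values. Residue indexing follows the source file (1-based) and
#' residue windows are inclusive closed intervals.
#'
#' @param traj a \code{"trajectory"}.
#' @param resid integer vector of residue indices, or NULL.
#' @param name atom names, or NULL.
#' @param chain chain identifiers, or NULL.
#' @param element element symbols, or NULL.
#' @param resname residue names, or NULL.
#' @param heavy if TRUE, drop hydrogens.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, resid = NULL, name = NULL, chain = NULL,
                         element = NULL, resname = NULL, heavy = FALSE) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid))   keep <- keep & a$resid %in% resid
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (heavy)             keep <- keep & a$element != "H"
  which(keep)
}

#' Channel coordinate frame from the pore-ring selection
#'
#' The channel origin is the unweighted centroid of the selected pore-ring
#' atoms in the requested frame (recomputed per frame); the axis is taken
#' from the channel-frame arguments, by convention the laboratory +z with the
#' cytoplasmic side at z > 0 after the user has aligned the membrane normal
#' to z.
#'
#' @param traj a \code{"trajectory"}.
#' @param resid pore-ring residue indices (e.g. the four pore Ile residues
#'   78, 183, 275, 404); which residues constitute the ring is configurable.
#' @param frame 1-based frame index.
#' @param chain optional chain filter for the ring selection.
#' @param axis unit axis vector, default \code{c(0, 0, 1)}.
#' @return list with \code{origin} (length-3, Angstrom) and \code{axis}.
#' @export
channel_frame <- function(traj, resid, frame = 1L, chain = NULL,
                          axis = c(0, 0, 1)) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8) stop("axis must be a unit vector")
  idx <- select_atoms(traj, resid = resid, chain = chain)
  if (length(idx) == 0L) {
    avail <- sort(unique(traj$atoms$resid))
    stop("pore-ring selection is empty; available residues: ",
         paste(utils::head(avail, 30), collapse = ", "),
         if (length(avail) > 30) " ..." else "")
  }
  xyz <- frame_coords(traj, frame)
  list(origin = colMeans(xyz[idx, , drop = FALSE]), axis = axis)
}

#' Which side of the channel a z coordinate falls on
#'
#' The cytoplasmic and exterior cavities partition the axis (excluding
#' z = 0): cytoplasmic is z > 0 (sign +1), exterior z < 0 (sign -1).
#'
#' @param z numeric axial coordinates relative to the pore-ring origin.
#' @return character vector, \code{"cytoplasmic"}, \code{"exterior"} or NA
#'   at exactly 0.
#' @export
cavity_side <- function(z) {
  out <- rep(NA_character_, length(z))
  out[z > 0] <- "cytoplasmic"
  out[z < 0] <- "exterior"
  out
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# run expr with a temporarily seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
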