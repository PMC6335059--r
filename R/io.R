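#' Read a structure or trajectory file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{pdb}{a standard single-model PDB; parsed with bio3d.}
#'   \item{multimodel-pdb}{a PDB with MODEL/ENDMDL records; one frame per
#'     MODEL, all models must share the atom list.}
#'   \item{xyztraj}{a plain-text trajectory dialect: a header line
#'     \code{"natoms dt_ps"}, then per-frame blocks of \code{natoms} lines
#'     \code{"name resid chain x y z"} (coordinates in Angstrom). Frame
#'     times are \code{(frame_index - 1) * dt_ps}.}
#' }
#'
#' @param path file path.
#' @param dialect one of \code{"pdb"}, \code{"multimodel-pdb"},
#'   \code{"xyztraj"}; default guesses from the extension (.pdb is read as
#'   multi-model aware, .xyztraj as the trajectory dialect).
#' @return a \code{"trajectory"}.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "multimodel-pdb",
                                             "xyztraj")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xyztraj$", path)) "xyztraj" else "multimodel-pdb"
  }
  switch(dialect,
         "pdb" = ,
         "multimodel-pdb" = read_pdb_traj(path),
         "xyztraj" = read_xyztraj(path))
}

read_pdb_traj <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  bad <- is.na(el) | el == ""
  if (any(bad)) el[bad] <- element_from_name(a$elety[bad])
  atoms <- data.frame(serial = a$eleno, name = a$elety,
                      element = toupper(el), resname = a$resid,
                      resid = a$resno, chain = ifelse(is.na(a$chain), "A",
                                                      a$chain),
                      stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(atoms, coords, times = seq_len(nf) - 1)
}

read_xyztraj <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*$", raw)
  lines <- raw[keep]
  lineno <- which(keep)  # original file line numbers for error reporting
  if (length(lines) < 1L) stop("empty xyztraj file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L)
    stop("xyztraj line ", lineno[1], ": header must be 'natoms dt_ps'")
  natoms <- suppressWarnings(as.integer(hdr[1]))
  dt <- suppressWarnings(as.numeric(hdr[2]))
  if (is.na(natoms) || natoms < 1L || is.na(dt) || dt <= 0)
    stop("xyztraj line ", lineno[1], ": malformed header '", lines[1], "'")
  body <- lines[-1]
  body_lineno <- lineno[-1]
  allparts <- strsplit(trimws(body), "\\s+")
  nfld <- lengths(allparts)
  if (any(nfld != 6L)) {
    bad <- which(nfld != 6L)[1]
    stop("xyztraj line ", body_lineno[bad],
         ": expected 6 fields 'name resid chain x y z', got ", nfld[bad])
  }
  if (length(body) %% natoms != 0L)
    stop("xyztraj: ", length(body), " atom lines is not a multiple of natoms = ",
         natoms, " (atom-count mismatch between frames)")
  nf <- length(body) %/% natoms
  coords <- array(NA_real_, dim = c(natoms, 3, nf))
  name <- resid <- chain <- NULL
  for (f in seq_len(nf)) {
    rows <- ((f - 1L) * natoms + 1L):(f * natoms)
    parts <- allparts[rows]
    m <- do.call(rbind, parts)
    xyz <- suppressWarnings(apply(m[, 4:6, drop = FALSE], 2, as.numeric))
    xyz <- matrix(xyz, ncol = 3)
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1, any))[1]
      stop("xyztraj line ", body_lineno[rows[bad]],
           ": non-numeric coordinate")
    }
    coords[, , f] <- xyz
    if (f == 1L) {
      name <- m[, 1]; resid <- suppressWarnings(as.integer(m[, 2]))
      chain <- m[, 3]
      if (anyNA(resid))
        stop("xyztraj line ", body_lineno[rows[which(is.na(resid))[1]]],
             ": non-integer residue index")
    } else if (!all(m[, 1] == name)) {
      stop("xyztraj frame ", f, ": atom names differ from frame 1")
    }
  }
  atoms <- data.frame(serial = seq_len(natoms), name = name,
                      element = element_from_name(name),
                      resname = "UNK", resid = resid, chain = chain,
                      stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element)
  trajectory(atoms, coords, times = (seq_len(nf) - 1) * dt)
}

#' Write a trajectory to file
#'
#' @param traj a \code{"trajectory"}.
#' @param path output path.
#' @param dialect \code{"pdb"} writes one MODEL per frame (a single frame
#'   yields a plain PDB); \code{"xyztraj"} writes the plain-text dialect of
#'   [read_structure()]. Coordinates are written to 3 decimal places (PDB
#'   precision).
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(traj, path, dialect = c("pdb", "xyztraj")) {
  dialect <- match.arg(dialect)
  if (dialect == "pdb") write_pdb_traj(traj, path) else
    write_xyztraj(traj, path)
  invisible(path)
}

write_pdb_traj <- function(traj, path) {
  a <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial %% 100000L,
      ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      a$resname, substr(a$chain, 1, 1), a$resid %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_xyztraj <- function(traj, path) {
  nf <- n_frames(traj)
  dt <- if (nf > 1L) traj$times[2] - traj$times[1] else 1
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %g", n_atoms(traj), dt), con)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%s %d %s %.3f %.3f %.3f", a$name, a$resid, a$chain,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}
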