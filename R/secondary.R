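# Hydrogen-bond based secondary-structure assignment (Kabsch-Sander
# electrostatic criterion, four-label subset: H alpha-helix, G 3_10-helix,
# T hydrogen-bonded turn, C no structure) and per-cavity degree-of-folding
# statistics. Only the labels observed inside the channel are assigned; the
# full 8-state DSSP machine (beta bridges/sheets, bends, pi-helix) is out
# of scope.

# Kabsch-Sander constants: partial-charge product 0.084 e^2, electrostatic
# coupling 332 kcal*A/(mol*e^2), bond cutoff -0.5 kcal/mol.
.KS <- list(q1q2 = 0.084, coupling = 332, cutoff = -0.5)

# Backbone atom coordinates per residue of a chain in one frame. Returns a
# list per residue: N, CA, C, O (each length-3 or NULL), resname, resid.
backbone_table <- function(traj, frame, chain) {
  a <- traj$atoms
  sel <- which(a$chain == chain)
  if (length(sel) == 0L) stop("chain '", chain, "' not found")
  xyz <- frame_coords(traj, frame)
  resids <- sort(unique(a$resid[sel]))
  lapply(resids, function(r) {
    ii <- sel[a$resid[sel] == r]
    nm <- a$name[ii]
    pick <- function(what) {
      j <- ii[match(what, nm)]
      if (is.na(j)) NULL else xyz[j, ]
    }
    list(resid = r, resname = a$resname[ii[1]],
         N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"))
  })
}

# Amide-H position: 1.01 A from N, opposite the bisector of the C(prev)-N
# and CA-N directions. First residue of a chain has no donor H; proline
# has no amide H at all.
amide_h <- function(res, prev) {
  if (is.null(prev) || res$resname == "PRO") return(NULL)
  if (is.null(res$N) || is.null(res$CA) || is.null(prev$C)) return(NULL)
  u <- prev$C - res$N; u <- u / sqrt(sum(u^2))
  v <- res$CA - res$N; v <- v / sqrt(sum(v^2))
  bis <- u + v
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-9) return(NULL)
  res$N - 1.01 * bis / nb
}

ks_energy_xyz <- function(N, H, C, O) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  .KS$q1q2 * .KS$coupling *
    (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' Electrostatic energy of the putative hydrogen bond from the donor
#' residue's amide N-H to the acceptor residue's carbonyl C=O:
#' \deqn{E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' in kcal/mol. The bond exists iff E < -0.5 kcal/mol. The amide H is
#' placed 1.01 Angstrom from N opposite the bisector of the preceding
#' carbonyl-C and CA directions; the first residue of a chain and prolines
#' have no donor. Sequence-adjacent pairs (|i - j| < 2) are never bonded.
#'
#' @param traj a \code{"trajectory"}.
#' @param donor,acceptor residue indices (as in the source file).
#' @param frame frame index.
#' @param chain chain identifier.
#' @return energy in kcal/mol, or NA when the donor has no amide H or a
#'   backbone atom is missing.
#' @export
ks_hbond_energy <- function(traj, donor, acceptor, frame = 1L, chain = "P") {
  bb <- backbone_table(traj, frame, chain)
  resids <- vapply(bb, `[[`, numeric(1), "resid")
  di <- match(donor, resids); ai <- match(acceptor, resids)
  if (is.na(di) || is.na(ai)) stop("residue not present in chain")
  ks_energy_pair(bb, di, ai)
}

# indices into the backbone table, not residue numbers
ks_energy_pair <- function(bb, di, ai) {
  if (abs(bb[[di]]$resid - bb[[ai]]$resid) < 2L) return(NA_real_)
  don <- bb[[di]]; acc <- bb[[ai]]
  if (is.null(acc$C) || is.null(acc$O) || is.null(don$N)) return(NA_real_)
  H <- amide_h(don, if (di > 1L) bb[[di - 1L]] else NULL)
  if (is.null(H)) return(NA_real_)
  ks_energy_xyz(don$N, H, acc$C, acc$O)
}

#' Assign secondary-structure labels per residue per frame
#'
#' A Kabsch-Sander n-turn at residue i (n = 3, 4) exists when the carbonyl
#' of residue i accepts a hydrogen bond from the amide of residue i + n.
#' Two consecutive 4-turns (at i and i + 1) make residues i+1 .. i+4
#' alpha-helical (H); two consecutive 3-turns make residues i+1 .. i+3
#' 3_10-helical (G), with H taking precedence on overlap. Residues inside
#' any single n-turn not already H/G are hydrogen-bonded turn (T);
#' everything else is no-structure (C).
#'
#' @param traj a \code{"trajectory"}.
#' @param chain chain to assign.
#' @param frames frame indices (default all).
#' @return character matrix \code{[n_residues, n_frames]} with rownames the
#'   residue indices; entries in {"H", "G", "T", "C"}.
#' @export
assign_ss <- function(traj, chain = "P", frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  bb0 <- backbone_table(traj, frames[1], chain)
  nres <- length(bb0)
  if (nres < 3L) stop("chain must have at least 3 residues")
  resids <- vapply(bb0, `[[`, numeric(1), "resid")
  out <- matrix("C", nrow = nres, ncol = length(frames),
                dimnames = list(resids, NULL))
  incomplete <- vapply(bb0, function(r)
    is.null(r$N) || is.null(r$CA) || is.null(r$C) || is.null(r$O),
    logical(1))
  if (any(incomplete))
    warning("skipping residue(s) with missing backbone atoms: ",
            paste(resids[incomplete], collapse = ", "))
  for (fi in seq_along(frames)) {
    bb <- backbone_table(traj, frames[fi], chain)
    turn <- function(n) {
      t <- rep(FALSE, nres)
      for (i in seq_len(nres - n)) {
        if (incomplete[i] || incomplete[i + n]) next
        e <- ks_energy_pair(bb, i + n, i)  # donor i+n -> acceptor i
        t[i] <- !is.na(e) && e < .KS$cutoff
      }
      t
    }
    t3 <- turn(3L); t4 <- turn(4L)
    lab <- rep("C", nres)
    # T: inside any single n-turn
    for (i in which(t3)) lab[(i + 1):(i + 2)] <- "T"
    for (i in which(t4)) lab[(i + 1):(i + 3)] <- "T"
    # G: consecutive 3-turns
    for (i in which(t3[-nres] & t3[-1])) lab[(i + 1):(i + 3)] <- "G"
    # H: consecutive 4-turns, precedence over G
    for (i in which(t4[-nres] & t4[-1])) lab[(i + 1):(i + 4)] <- "H"
    out[, fi] <- lab
  }
  out
}

#' Degree of folding of a residue window
#'
#' The fraction of residue-frame pairs inside a window (typically the nine
#' residues assigned to one cavity) whose label is in the folded set
#' ({H, G, T} by default; restrict to {H, G} to exclude turns). With a list
#' of replicate label matrices the per-replicate fractions are aggregated
#' as mean and s.e.m.
#'
#' @param labels a label matrix from [assign_ss()], or a list of them (one
#'   per replicate simulation).
#' @param window inclusive residue interval \code{c(start, end)}; must be
#'   non-empty and present in the labels.
#' @param frames optional column (frame) indices to analyse.
#' @param folded labels counted as folded.
#' @return for a single matrix, a numeric fraction; for a list, an object
#'   of class \code{"folding_degree"} with fields \code{fractions},
#'   \code{mean}, \code{sem}, \code{n}.
#' @export
folding_degree <- function(labels, window, frames = NULL,
                           folded = c("H", "G", "T")) {
  one <- function(m) {
    rn <- as.integer(rownames(m))
    rows <- which(rn >= window[1] & rn <= window[2])
    if (length(rows) == 0L) stop("window contains no residues")
    cols <- if (is.null(frames)) seq_len(ncol(m)) else frames
    if (length(cols) == 0L) stop("frame interval is empty")
    mean(m[rows, cols] %in% folded)
  }
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be a non-empty interval c(start, end)")
  if (is.matrix(labels)) return(one(labels))
  fr <- vapply(labels, one, numeric(1))
  structure(list(fractions = fr, mean = mean(fr),
                 sem = sem(fr), n = length(fr)),
            class = "folding_degree")
}

#' @export
print.folding_degree <- function(x, ...) {
  cat(sprintf("Degree of folding: %.4f +/- %.4f (s.e.m., n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Two-sample t-test for cavity folding asymmetry
#'
#' Compares per-replicate folding fractions between the cytoplasmic and
#' exterior cavities with a two-tailed two-sample t-test (Student's
#' equal-variance test by default; Welch available). Degenerate inputs with
#' exactly zero variance in both groups and different means are rejected
#' rather than reported as p = 0.
#'
#' @param cyt,ext \code{"folding_degree"} objects or numeric vectors of
#'   per-replicate fractions (>= 2 each).
#' @param test \code{"student"} or \code{"welch"}.
#' @return list with \code{t}, \code{df}, \code{p} (two-tailed),
#'   \code{mean_cyt}, \code{mean_ext}.
#' @export
asymmetry_test <- function(cyt, ext, test = c("student", "welch")) {
  test <- match.arg(test)
  x <- if (inherits(cyt, "folding_degree")) cyt$fractions else cyt
  y <- if (inherits(ext, "folding_degree")) ext$fractions else ext
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 replicates per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  mean_cyt = mean(x), mean_ext = mean(y)))
    stop("both groups have exactly zero variance; t-test undefined")
  }
  ht <- stats::t.test(x, y, var.equal = (test == "student"),
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_cyt = mean(x), mean_ext = mean(y))
}
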