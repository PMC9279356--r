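# Core data model: Topology, Frame, Trajectory.
#
# A Topology is chain/residue/atom bookkeeping without coordinates; a
# Trajectory couples one Topology with an ordered stack of coordinate frames
# and a frame -> nanosecond mapping.  Residue numbering is 1-based PDB author
# numbering and is never rewritten on read.  Phospho-residues are ordinary
# residues named Y2P/T2P (PTR/TPO are aliased on read).

PHOSPHO_ALIASES <- c(PTR = "Y2P", TPO = "T2P")

# Standard atomic masses (u) for centre-of-mass calculations; unknown
# elements fall back to carbon.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.90,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38,
  FE = 55.845, SE = 78.971
)

element_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- ATOMIC_MASSES[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a Topology
#'
#' A Topology holds the chain/residue/atom structure of a molecular system.
#' Per-atom force-field style parameters (charge, Lennard-Jones sigma and
#' epsilon, intrinsic radius) are optional and can be populated later with
#' [attach_parameters()].
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, and optionally `charge`, `lj_sigma`,
#'   `lj_epsilon`, `radius`.
#' @return An object of class `Topology`: the validated atom table plus
#'   derived `chains` (ordered chain ids) and `residues` (one row per
#'   residue, ordered by chain then residue number).
#' @export
topology <- function(atoms) {
  req <- c("serial", "name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("charge", "lj_sigma", "lj_epsilon", "radius")) {
    if (is.null(atoms[[opt]])) atoms[[opt]] <- NA_real_
  }
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  atoms$name <- as.character(atoms$name)
  atoms$element <- toupper(as.character(atoms$element))
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL

  chains <- unique(atoms$chain)
  rkey <- paste(atoms$chain, atoms$resid, sep = "|")
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain = atoms$chain[first],
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    stringsAsFactors = FALSE
  )
  ord <- order(match(residues$chain, chains), residues$resid)
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL

  structure(
    list(atoms = atoms, chains = chains, residues = residues),
    class = "Topology"
  )
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf(
    "Topology: %d atoms, %d residues, %d chain(s) [%s]\n",
    nrow(x$atoms), nrow(x$residues), length(x$chains),
    paste(x$chains, collapse = ", ")
  ))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a Trajectory
#'
#' @param top a [topology()] object.
#' @param coords numeric array of dimension (atoms, 3, frames), in Angstrom.
#' @param frame_interval_ns time spacing between stored frames, in ns.
#'   Frame i (1-based) is mapped to time (i - 1) * frame_interval_ns.
#' @param times_ns optional explicit frame times; must be strictly increasing.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(top, coords, frame_interval_ns = 0.1, times_ns = NULL) {
  if (!inherits(top, "Topology")) stop("`top` must be a Topology")
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an (atoms x 3 x frames) array")
  }
  if (dim(coords)[1] != n_atoms(top)) {
    stop(sprintf(
      "coordinate rows (%d) do not match topology atom count (%d)",
      dim(coords)[1], n_atoms(top)
    ))
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (frame_interval_ns <= 0) stop("frame_interval_ns must be > 0")
  nf <- dim(coords)[3]
  if (is.null(times_ns)) times_ns <- (seq_len(nf) - 1) * frame_interval_ns
  if (length(times_ns) != nf) stop("times_ns length must equal frame count")
  if (nf > 1L && any(diff(times_ns) <= 0)) stop("frame times must be strictly increasing")
  if (any(times_ns < 0)) stop("frame times must be >= 0")
  structure(
    list(
      topology = top, coords = coords,
      times_ns = as.numeric(times_ns),
      frame_interval_ns = frame_interval_ns
    ),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d atoms, %.4g ns/frame, span %.4g ns\n",
    n_frames(x), n_atoms(x$topology), x$frame_interval_ns,
    if (n_frames(x) > 0) max(x$times_ns) else 0
  ))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates
#' @param traj a [trajectory()] object.
#' @param i frame index (1-based).
#' @return N x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = FALSE][, , 1]
}

# Indices of frames whose time is inside [from_ns, to_ns]; NULL bounds are
# open.  Used by every windowed analysis.
window_frames <- function(traj, window = NULL) {
  t <- traj$times_ns
  if (is.null(window)) return(seq_along(t))
  from <- if (is.null(window$from_ns)) -Inf else window$from_ns
  to <- if (is.null(window$to_ns)) Inf else window$to_ns
  idx <- which(t >= from & t <= to)
  if (length(idx) == 0L) stop("empty analysis window")
  idx
}
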