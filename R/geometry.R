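# Internal-coordinate geometry: placing atoms from bond/angle/dihedral and
# building schematic peptide backbones from (phi, psi) dihedrals.  Used by
# the synthetic-trajectory generator and by tests that need ideal helices.

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame placement: returns the position `d`
#' such that |c-d| = `bond`, angle(b,c,d) = `angle_deg` and dihedral
#' (a,b,c,d) = `dihedral_deg`.
#'
#' @param a,b,c 3-vectors defining the reference frame.
#' @param bond bond length c-d (Angstrom).
#' @param angle_deg bond angle b-c-d (degrees).
#' @param dihedral_deg dihedral a-b-c-d (degrees).
#' @return 3-vector position of d.
#' @export
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Ideal backbone internal coordinates (Engh-Huber-like averages).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.0,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

#' Build a schematic peptide backbone from dihedrals
#'
#' Builds an n-residue poly-alanine-like backbone (N, H, CA, C, O per
#' residue; no H on residue 1) with ideal bond lengths/angles and the given
#' (phi, psi) per residue (omega fixed at 180).  Canonical dihedrals:
#' alpha-helix (-57, -47); 3-10 helix (-49, -26); extended (-140, 135).
#'
#' @param phi,psi numeric vectors (degrees), recycled to `n_res`.
#' @param n_res number of residues.
#' @param with_h reconstruct amide hydrogens (default TRUE).
#' @param with_cb add a beta-carbon per residue (alanine-like side chain).
#' @return list: `coords` (matrix), `atoms` data.frame (name, resid).
#' @export
build_backbone <- function(phi, psi, n_res = length(phi), with_h = TRUE,
                           with_cb = FALSE) {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  g <- BB_GEOM
  coords <- list(); names_out <- character(0); resid_out <- integer(0)
  add <- function(p, nm, ri) {
    coords[[length(coords) + 1L]] <<- p
    names_out[length(names_out) + 1L] <<- nm
    resid_out[length(resid_out) + 1L] <<- ri
  }
  # residue 1 seed
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- CA1 + g$ca_c * c(cos((180 - g$ang_n_ca_c) * pi / 180),
                         sin((180 - g$ang_n_ca_c) * pi / 180), 0)
  prevN <- N1; prevCA <- CA1; prevC <- C1
  add(N1, "N", 1L); add(CA1, "CA", 1L); add(C1, "C", 1L)
  O1 <- place_atom(N1, CA1, C1, g$c_o, g$ang_ca_c_o, psi[1] + 180)
  add(O1, "O", 1L)
  if (with_cb) add(place_atom(N1, C1, CA1, 1.53, 110.5, 122.5), "CB", 1L)

  for (i in 2L:n_res) {
    Ni <- place_atom(prevN, prevCA, prevC, g$c_n, g$ang_ca_c_n, psi[i - 1])
    CAi <- place_atom(prevCA, prevC, Ni, g$n_ca, g$ang_c_n_ca, 180)  # omega
    Ci <- place_atom(prevC, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
    add(Ni, "N", i)
    if (with_h) {
      # H on N, trans to the carbonyl O of the preceding residue
      Oprev <- coords[[which(names_out == "O" & resid_out == i - 1L)]]
      u <- (prevC - Oprev); u <- u / sqrt(sum(u^2))
      add(Ni + g$n_h * u, "H", i)
    }
    add(CAi, "CA", i); add(Ci, "C", i)
    Oi <- place_atom(Ni, CAi, Ci, g$c_o, g$ang_ca_c_o, psi[i] + 180)
    add(Oi, "O", i)
    if (with_cb) add(place_atom(Ni, Ci, CAi, 1.53, 110.5, 122.5), "CB", i)
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
  }
  list(
    coords = do.call(rbind, coords),
    atoms = data.frame(name = names_out, resid = resid_out,
                       stringsAsFactors = FALSE)
  )
}

#' Build a one-chain trajectory from a backbone
#'
#' Convenience wrapper for tests: wraps [build_backbone()] output in a
#' [trajectory()] with the given chain id and residue name.
#'
#' @param phi,psi dihedrals (degrees), see [build_backbone()].
#' @param n_res residue count.
#' @param chain chain id.
#' @param resname residue name for every residue.
#' @param with_h include amide hydrogens.
#' @return A 1-frame [trajectory()].
#' @export
backbone_trajectory <- function(phi, psi, n_res = length(phi), chain = "A",
                                resname = "ALA", with_h = TRUE,
                                with_cb = FALSE) {
  bb <- build_backbone(phi, psi, n_res, with_h = with_h, with_cb = with_cb)
  at <- data.frame(
    serial = seq_len(nrow(bb$atoms)),
    name = bb$atoms$name,
    element = substr(bb$atoms$name, 1, 1),
    resname = resname, resid = bb$atoms$resid, chain = chain,
    stringsAsFactors = FALSE
  )
  trajectory(topology(at), bb$coords, frame_interval_ns = 0.1)
}
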