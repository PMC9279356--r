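# DSSP secondary-structure assignment.
#
# Backbone H-bonds are scored with the Kabsch-Sander electrostatic energy
# E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol and accepted
# below -0.5 kcal/mol.  n-turns (n = 3, 4, 5) follow from i+n -> i bonds;
# two consecutive 4-turns give H, 3-turns G, 5-turns I; bridges/ladders give
# B/E; leftover turns T and bends S; priority H > E > G > I > B > T > S > C.
# Prolines never donate; chain breaks (CA-CA > 4.5 A) split the search.

KS_Q <- 0.084 * 332  # kcal*A/mol, Kabsch-Sander coupling constant
KS_CUTOFF <- -0.5    # kcal/mol
SS_PRIORITY <- c(H = 1, E = 2, G = 3, I = 4, B = 5, T = 6, S = 7, C = 8)

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' @param C,O acceptor carbonyl carbon and oxygen positions (Angstrom).
#' @param N,H donor amide nitrogen and hydrogen positions.
#' @return Energy in kcal/mol; an H-bond is assigned below -0.5 kcal/mol.
#' @export
ks_hbond_energy <- function(C, O, N, H) {
  r_on <- sqrt(sum((O - N)^2))
  r_ch <- sqrt(sum((C - H)^2))
  r_oh <- sqrt(sum((O - H)^2))
  r_cn <- sqrt(sum((C - N)^2))
  if (min(r_on, r_ch, r_oh, r_cn) < 1e-6) {
    stop("coincident atoms in hydrogen-bond energy evaluation")
  }
  KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Extract a per-residue backbone table for one frame: positions of
# N, CA, C, O (+ H, reconstructed when absent) and bookkeeping flags.
backbone_table <- function(xyz, top) {
  at <- top$atoms
  res <- top$residues
  nr <- nrow(res)
  get1 <- function(chain, resid, name) {
    i <- which(at$chain == chain & at$resid == resid & at$name == name)
    if (length(i) == 0L) return(NULL)
    xyz[i[1], ]
  }
  bb <- vector("list", nr)
  for (r in seq_len(nr)) {
    ch <- res$chain[r]; ri <- res$resid[r]
    bb[[r]] <- list(
      chain = ch, resid = ri, resname = res$resname[r],
      N = get1(ch, ri, "N"), CA = get1(ch, ri, "CA"),
      C = get1(ch, ri, "C"), O = get1(ch, ri, "O"),
      H = get1(ch, ri, "H"),
      complete = FALSE, is_pro = toupper(res$resname[r]) == "PRO"
    )
    bb[[r]]$complete <- !is.null(bb[[r]]$N) && !is.null(bb[[r]]$CA) &&
      !is.null(bb[[r]]$C) && !is.null(bb[[r]]$O)
  }
  # sequence continuity: same chain, consecutive in residue table, CA-CA <= 4.5
  contig <- logical(nr)  # contig[r]: residue r follows r-1 without a break
  for (r in 2:max(nr, 2)) {
    if (r > nr) break
    a <- bb[[r - 1]]; b <- bb[[r]]
    contig[r] <- a$chain == b$chain && a$complete && b$complete &&
      sqrt(sum((a$CA - b$CA)^2)) <= 4.5
  }
  # reconstruct amide H at 1.0 A from N along previous O -> C direction
  for (r in seq_len(nr)) {
    if (!bb[[r]]$complete || bb[[r]]$is_pro) next
    if (is.null(bb[[r]]$H) && r > 1L && contig[r]) {
      prev <- bb[[r - 1]]
      u <- prev$C - prev$O
      u <- u / sqrt(sum(u^2))
      bb[[r]]$H <- bb[[r]]$N + 1.0 * u
    }
  }
  list(bb = bb, contig = contig)
}

# Boolean H-bond matrix: hbmat[i, j] is TRUE when NH of residue i donates to
# CO of residue j.  Sequence-adjacent pairs are excluded.
dssp_hbond_matrix <- function(bbt) {
  bb <- bbt$bb
  nr <- length(bb)
  hb <- matrix(FALSE, nr, nr)
  energy <- matrix(NA_real_, nr, nr)
  # segment id: increments at each break, so "adjacent" respects breaks
  seg <- cumsum(c(1L, as.integer(!bbt$contig[-1])))
  for (i in seq_len(nr)) {
    di <- bb[[i]]
    if (!di$complete || di$is_pro || is.null(di$H)) next
    for (j in seq_len(nr)) {
      if (i == j) next
      if (seg[i] == seg[j] && abs(i - j) <= 1L) next
      aj <- bb[[j]]
      if (!aj$complete) next
      # cheap distance gate before the energy
      if (sum((di$N - aj$O)^2) > 49) next
      e <- ks_hbond_energy(aj$C, aj$O, di$N, di$H)
      energy[i, j] <- e
      hb[i, j] <- e < KS_CUTOFF
    }
  }
  list(hb = hb, energy = energy, seg = seg)
}

#' DSSP assignment for one frame
#'
#' @param traj a [trajectory()] (or a Topology when `frame` is a coordinate
#'   matrix).
#' @param frame frame index, or N x 3 coordinates.
#' @return Object of class `SSAssignment`: data.frame with chain, resid,
#'   resname and `ss` (one of H, G, I, E, B, T, S, C).
#' @export
assign_dssp <- function(traj, frame = 1L) {
  if (inherits(traj, "Trajectory")) {
    top <- traj$topology
    xyz <- frame_coords(traj, frame)
  } else {
    top <- traj
    xyz <- frame
  }
  bbt <- backbone_table(xyz, top)
  bb <- bbt$bb
  nr <- length(bb)
  hbm <- dssp_hbond_matrix(bbt)
  hb <- hbm$hb
  seg <- hbm$seg

  # n-turns: turn_n[i] when NH(i+n) -> CO(i), same segment
  turn <- list()
  for (n in c(3L, 4L, 5L)) {
    tn <- logical(nr)
    for (i in seq_len(nr - n)) {
      if (seg[i] == seg[i + n] && hb[i + n, i]) tn[i] <- TRUE
    }
    turn[[as.character(n)]] <- tn
  }

  ss <- rep("C", nr)
  set_if_lower <- function(idx, code) {
    for (i in idx) {
      if (i >= 1L && i <= nr && SS_PRIORITY[code] < SS_PRIORITY[ss[i]]) {
        ss[i] <<- code
      }
    }
  }

  # bridges (computed before helices so E can be decided, but H wins)
  partner <- vector("list", nr)
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (abs(i - j) < 3L && seg[i] == seg[j]) next
      para <- (i > 1L && i < nr && hb[i + 1L, j] && hb[j, i - 1L]) ||
        (j > 1L && j < nr && hb[j + 1L, i] && hb[i, j - 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i > 1L && i < nr && j > 1L && j < nr &&
           hb[i + 1L, j - 1L] && hb[j + 1L, i - 1L])
      if (para || anti) partner[[i]] <- c(partner[[i]], j)
    }
  }
  bridge <- which(vapply(partner, length, 1L) > 0L)
  in_ladder <- logical(nr)
  for (i in bridge) {
    for (j in partner[[i]]) {
      # ladder: neighbouring bridge (i+1, j+-1)
      ext <- (i + 1L) %in% bridge &&
        any(partner[[i + 1L]] %in% c(j - 1L, j + 1L))
      ext_prev <- (i - 1L) %in% bridge &&
        any(partner[[i - 1L]] %in% c(j - 1L, j + 1L))
      if (ext || ext_prev) in_ladder[i] <- TRUE
    }
  }

  # helices: two consecutive n-turns starting at i-1 and i
  helix_hits <- function(tn, n) {
    idx <- integer(0)
    for (i in 2:max(nr, 2)) {
      if (i > nr) break
      if (tn[i - 1L] && tn[i]) idx <- c(idx, i:(i + n - 1L))
    }
    unique(idx[idx <= nr])
  }
  set_if_lower(helix_hits(turn[["4"]], 4L), "H")
  set_if_lower(which(in_ladder), "E")
  set_if_lower(helix_hits(turn[["3"]], 3L), "G")
  set_if_lower(helix_hits(turn[["5"]], 5L), "I")
  set_if_lower(setdiff(bridge, which(in_ladder)), "B")

  # leftover turns: residues spanned by any single n-turn
  turn_span <- integer(0)
  for (n in c(3L, 4L, 5L)) {
    tn <- turn[[as.character(n)]]
    for (i in which(tn)) turn_span <- c(turn_span, (i + 1L):(i + n - 1L))
  }
  set_if_lower(unique(turn_span[turn_span <= nr]), "T")

  # bend: CA-chain curvature over i-2, i, i+2 > 70 degrees
  for (i in seq_len(nr)) {
    if (i <= 2L || i >= nr - 1L) next
    if (seg[i - 2L] != seg[i] || seg[i] != seg[i + 2L]) next
    a <- bb[[i - 2L]]; m <- bb[[i]]; b <- bb[[i + 2L]]
    if (!a$complete || !m$complete || !b$complete) next
    u <- m$CA - a$CA; v <- b$CA - m$CA
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(max(-1, min(1, cosang))) * 180 / pi > 70) set_if_lower(i, "S")
  }

  structure(
    data.frame(
      chain = vapply(bb, `[[`, "", "chain"),
      resid = vapply(bb, `[[`, 0L, "resid"),
      resname = vapply(bb, `[[`, "", "resname"),
      ss = ss, stringsAsFactors = FALSE
    ),
    class = c("SSAssignment", "data.frame")
  )
}

#' Per-residue secondary-structure fractions over a trajectory
#'
#' Fraction of analysed frames each residue spends in each DSSP class;
#' classes are reported both as raw codes and grouped
#' (helix_a = H, helix_310 = G, strand = E + B, turn_bend = T + S,
#' coil = C + I).
#'
#' @param traj a [trajectory()].
#' @param chain chain id to report.
#' @param window optional analysis window `list(from_ns=, to_ns=)`.
#' @return data.frame: chain, resid, resname, one fraction column per code
#'   (`frac_H` ... `frac_C`) plus grouped columns; rows sum to 1 over codes.
#' @export
ss_fraction <- function(traj, chain, window = NULL) {
  if (!chain %in% traj$topology$chains) stop("unknown chain: ", chain)
  idx <- window_frames(traj, window)
  codes <- c("H", "G", "I", "E", "B", "T", "S", "C")
  first <- assign_dssp(traj, idx[1])
  rows <- which(first$chain == chain)
  counts <- matrix(0L, length(rows), length(codes),
                   dimnames = list(NULL, codes))
  tally <- function(ass) {
    m <- match(ass$ss[rows], codes)
    for (k in seq_along(rows)) counts[k, m[k]] <<- counts[k, m[k]] + 1L
  }
  tally(first)
  for (f in idx[-1]) tally(assign_dssp(traj, f))
  fr <- counts / length(idx)
  out <- data.frame(
    chain = first$chain[rows], resid = first$resid[rows],
    resname = first$resname[rows], stringsAsFactors = FALSE
  )
  for (cd in codes) out[[paste0("frac_", cd)]] <- fr[, cd]
  out$helix_a <- fr[, "H"]
  out$helix_310 <- fr[, "G"]
  out$strand <- fr[, "E"] + fr[, "B"]
  out$turn_bend <- fr[, "T"] + fr[, "S"]
  out$coil <- fr[, "C"] + fr[, "I"]
  out
}

#' Compact per-frame DSSP strings
#'
#' @param traj a [trajectory()].
#' @param chain chain id.
#' @param window optional analysis window.
#' @return character vector, one string of per-residue codes per frame.
#' @export
dssp_strings <- function(traj, chain, window = NULL) {
  idx <- window_frames(traj, window)
  vapply(idx, function(f) {
    a <- assign_dssp(traj, f)
    paste(a$ss[a$chain == chain], collapse = "")
  }, "")
}
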