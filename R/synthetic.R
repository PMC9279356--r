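# Synthetic trimer trajectories with planted, machine-readable ground
# truth.  Geometry is schematic (poly-alanine-like backbone plus a few
# decorated pseudo-atoms), not chemically realistic: the generator's job is
# to exercise every analysis code path against a manifest oracle.
#
# Layout (lab frame, Angstrom):
#   chain A: residues 1..8  = "pocket" ring of CA pseudo-atoms around the
#            origin; residue 9 = icosahedral cage of 12 C atoms that buries
#            the probe atom when the exposure schedule says "buried";
#            acceptor pad residues for planted A-C contacts.
#   chain B: residues 1..4  = static CA pseudo-atoms (Cyclin stand-in);
#            acceptor pads for planted B-C contacts.
#   chain C: the inhibitor: an n-residue backbone segment built from ideal
#            dihedrals each frame (3-10 or alpha when the helix mask is on,
#            extended otherwise), a probe residue whose OH atom toggles
#            between the cage centre and an exposed slot, and donor pad
#            residues (N + H) for the planted contacts.
#
# Planted contacts are placed at 2.8 A / 170 deg when scheduled on and
# 5.0 A when off.  Thermal jitter ~ N(0, 0.1 A) is added to every atom;
# the three atoms of each contact pad receive one shared displacement per
# frame so the planted geometry is preserved exactly (margins to the
# 3.0 A / 135 deg criteria stay infinite rather than ~2 sigma).

# icosahedron vertices (unit radius)
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v / sqrt(1 + phi^2)
}

# exact-fraction schedule: one contiguous run (persistent) or scattered
# short runs (transient, every episode below the bound threshold)
make_schedule <- function(n_frames, fraction, style = c("block", "scattered"),
                          offset = 0L, run_len = 3L) {
  style <- match.arg(style)
  n_on <- round(fraction * n_frames)
  mask <- logical(n_frames)
  if (n_on == 0L) return(mask)
  if (style == "block") {
    start <- offset %% max(n_frames - n_on + 1L, 1L) + 1L
    mask[start:(start + n_on - 1L)] <- TRUE
  } else {
    n_runs <- ceiling(n_on / run_len)
    gap <- max((n_frames - n_on) %/% n_runs, 1L)
    pos <- 1L + (offset %% gap)
    left <- n_on
    while (left > 0L && pos <= n_frames) {
      len <- min(run_len, left, n_frames - pos + 1L)
      mask[pos:(pos + len - 1L)] <- TRUE
      left <- left - len
      pos <- pos + len + gap
    }
    # top up from the end if space ran out
    if (left > 0L) {
      off_idx <- rev(which(!mask))
      mask[off_idx[seq_len(left)]] <- TRUE
    }
  }
  mask
}

#' Default configuration for the toy trimer generator
#'
#' Contact fractions include the flagship intermolecular persistence values
#' (a 0.56-fraction Cyclin-Cdk contact among them) plus transient decoys;
#' the helix mask covers 60% of frames; the probe is exposed in 40%.
#'
#' @param n_frames number of frames (default 200).
#' @param frame_interval_ns ns per frame (default 0.1).
#' @param n_res inhibitor segment length (default 12).
#' @param helix_style `"310"` or `"alpha"`.
#' @param helix_fraction fraction of frames with the segment helical.
#' @param persistent_fractions lifetime fractions of planted persistent
#'   contacts (single contiguous episode each).
#' @param transient_fractions lifetime fractions of planted transient
#'   contacts (scattered sub-threshold episodes).
#' @param exposure_fraction fraction of frames with the probe exposed.
#' @param ejection_frame frame index at which the inhibitor segment is
#'   ejected (translated away from the pocket), or NA for none.
#' @param jitter_sd thermal jitter (A).
#' @return Named list of generator settings.
#' @export
toy_trimer_config <- function(n_frames = 200L, frame_interval_ns = 0.1,
                              n_res = 12L, helix_style = "310",
                              helix_fraction = 0.6,
                              persistent_fractions = c(0.9, 0.75, 0.56),
                              transient_fractions = c(0.3, 0.2, 0.15, 0.1, 0.05),
                              exposure_fraction = 0.4,
                              ejection_frame = NA_integer_,
                              jitter_sd = 0.1) {
  list(
    n_frames = as.integer(n_frames), frame_interval_ns = frame_interval_ns,
    n_res = as.integer(n_res), helix_style = helix_style,
    helix_fraction = helix_fraction,
    persistent_fractions = persistent_fractions,
    transient_fractions = transient_fractions,
    exposure_fraction = exposure_fraction,
    ejection_frame = ejection_frame,
    jitter_sd = jitter_sd
  )
}

#' Generate a toy trimer trajectory with planted ground truth
#'
#' @param config a [toy_trimer_config()].
#' @param seed RNG seed; the output is deterministic given (config, seed).
#' @return list: `trajectory` (a [trajectory()], parameters attached) and
#'   `manifest` (class `SyntheticManifest`) with every planted schedule,
#'   span, frame index and selection needed to verify the analyses.
#' @export
make_toy_trimer <- function(config = toy_trimer_config(), seed = 1L) {
  nf <- config$n_frames
  if (nf < 10L) stop("frame count must be >= 10")
  set.seed(seed)

  dih <- switch(config$helix_style,
    "310" = c(-49, -26),
    alpha = c(-57, -47),
    stop("helix_style must be '310' or 'alpha'")
  )
  ext <- c(-140, 135)

  # ---- schedules -----------------------------------------------------
  helix_mask <- make_schedule(nf, config$helix_fraction, "block", offset = 0L)
  exposure_mask <- make_schedule(nf, config$exposure_fraction, "block",
                                 offset = 17L)
  n_pers <- length(config$persistent_fractions)
  n_trans <- length(config$transient_fractions)
  contact_masks <- vector("list", n_pers + n_trans)
  for (i in seq_len(n_pers)) {
    contact_masks[[i]] <- make_schedule(nf, config$persistent_fractions[i],
                                        "block", offset = 13L * i)
  }
  for (i in seq_len(n_trans)) {
    contact_masks[[n_pers + i]] <- make_schedule(
      nf, config$transient_fractions[i], "scattered", offset = 7L * i
    )
  }

  # ---- static topology ----------------------------------------------
  atoms <- list()
  add_atom <- function(name, element, resname, resid, chain) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname,
      resid = resid, chain = chain, stringsAsFactors = FALSE
    )
    length(atoms)
  }
  base_coords <- list()  # idx -> function(frame) or constant position
  put <- function(idx, pos) base_coords[[idx]] <<- pos

  # chain A: pocket ring
  pocket_center <- c(0, 0, 0)
  for (r in 1:8) {
    ang <- 2 * pi * (r - 1) / 8
    i <- add_atom("CA", "C", "GLY", r, "A")
    put(i, pocket_center + 4 * c(cos(ang), sin(ang), 0))
  }
  # chain A: cage (residue 9)
  cage_center <- c(0, -18, 0)
  ico <- icosahedron_vertices()
  for (v in 1:12) {
    i <- add_atom(paste0("C", v), "C", "CAG", 9L, "A")
    put(i, cage_center + 3.0 * ico[v, ])
  }
  # chain B: static pseudo-Cyclin
  for (r in 1:4) {
    i <- add_atom("CA", "C", "GLY", r, "B")
    put(i, c(40, -16 - 5 * r, 0))
  }

  # chain C: inhibitor backbone segment (coordinates set per frame)
  seg_anchor <- c(14, 6, 0)
  bb_idx <- integer(0)
  bb_atoms <- build_backbone(rep(dih[1], config$n_res),
                             rep(dih[2], config$n_res))$atoms
  for (k in seq_len(nrow(bb_atoms))) {
    el <- substr(bb_atoms$name[k], 1, 1)
    i <- add_atom(bb_atoms$name[k], el, "ALA", bb_atoms$resid[k], "C")
    bb_idx <- c(bb_idx, i)
    put(i, c(0, 0, 0))
  }
  # probe residue: CA anchor plus a detached OH reporter atom
  probe_resid <- config$n_res + 1L
  probe_ca <- add_atom("CA", "C", "TYR", probe_resid, "C")
  put(probe_ca, cage_center + c(0, -9, 0))
  probe_oh <- add_atom("OH", "O", "TYR", probe_resid, "C")
  exposed_slot <- cage_center + c(0, -16, 0)
  put(probe_oh, cage_center)  # per-frame toggle

  # contact pads: donor (N + H) on chain C, acceptor O on chain A or B
  pad_info <- list()
  n_contacts <- n_pers + n_trans
  for (p in seq_len(n_contacts)) {
    d0 <- c(-14, 8 * p - 4 * n_contacts, 0)
    acc_chain <- if (p %% 2L == 1L) "A" else "B"
    acc_resid <- 100L + p
    don_resid <- probe_resid + p
    di <- add_atom("N", "N", "DNR", don_resid, "C")
    hi <- add_atom("H", "H", "DNR", don_resid, "C")
    ai <- add_atom("O", "O", "ACC", acc_resid, acc_chain)
    put(di, d0); put(hi, d0 + c(1, 0, 0)); put(ai, d0 + c(5, 0, 0))
    pad_info[[p]] <- list(
      donor = di, hydrogen = hi, acceptor = ai, origin = d0,
      chain_pair = paste(sort(c("C", acc_chain)), collapse = "-"),
      persistent = p <= n_pers,
      fraction = mean(contact_masks[[p]])
    )
  }

  atom_tab <- do.call(rbind, atoms)
  atom_tab$serial <- seq_len(nrow(atom_tab))
  # keep chains contiguous and ordered A, B, C for clean PDB output
  ord <- order(match(atom_tab$chain, c("A", "B", "C")), atom_tab$resid,
               atom_tab$serial)
  remap <- match(seq_len(nrow(atom_tab)), ord)  # old index -> new row
  atom_tab <- atom_tab[ord, , drop = FALSE]
  atom_tab$serial <- seq_len(nrow(atom_tab))
  rownames(atom_tab) <- NULL
  top <- topology(atom_tab)

  # ---- per-frame coordinates -----------------------------------------
  n_at <- nrow(atom_tab)
  coords <- array(0, dim = c(n_at, 3L, nf))
  base <- matrix(0, n_at, 3L)
  for (iold in seq_along(base_coords)) base[remap[iold], ] <- base_coords[[iold]]

  # on-geometry acceptor offset: 2.8 A from donor at 170 deg D-H-A
  c10 <- cos(10 * pi / 180); s10 <- sin(10 * pi / 180)
  t_on <- -c10 + sqrt(c10^2 + (2.8^2 - 1))
  acc_on <- c(1 + t_on * c10, t_on * s10, 0)
  acc_off <- c(5, 0, 0)

  helix_dih <- dih; ext_dih <- ext
  eject <- config$ejection_frame
  eject_shift <- c(0, 0, 22)

  pad_atoms_new <- lapply(pad_info, function(p) {
    c(remap[p$donor], remap[p$hydrogen], remap[p$acceptor])
  })
  probe_oh_new <- remap[probe_oh]
  bb_new <- remap[bb_idx]
  jitter_free <- unlist(pad_atoms_new)

  for (f in seq_len(nf)) {
    X <- base
    # inhibitor backbone for this frame
    use <- if (helix_mask[f]) helix_dih else ext_dih
    bb <- build_backbone(rep(use[1], config$n_res), rep(use[2], config$n_res))
    segc <- sweep(bb$coords, 2, -seg_anchor)
    if (!is.na(eject) && f >= eject) segc <- sweep(segc, 2, -eject_shift)
    X[bb_new, ] <- segc
    # probe toggle
    X[probe_oh_new, ] <- if (exposure_mask[f]) exposed_slot else cage_center
    # contacts
    for (p in seq_len(n_contacts)) {
      ids <- pad_atoms_new[[p]]
      o <- pad_info[[p]]$origin
      X[ids[1], ] <- o
      X[ids[2], ] <- o + c(1, 0, 0)
      X[ids[3], ] <- o + if (contact_masks[[p]][f]) acc_on else acc_off
    }
    # thermal jitter: i.i.d. everywhere except contact pads, which move
    # as rigid groups (one shared displacement per pad per frame)
    J <- matrix(stats::rnorm(3L * n_at, 0, config$jitter_sd), n_at, 3L)
    for (p in seq_len(n_contacts)) {
      ids <- pad_atoms_new[[p]]
      J[ids, ] <- matrix(J[ids[1], ], 3L, 3L, byrow = TRUE)
    }
    coords[, , f] <- X + J
  }

  traj <- trajectory(top, coords, frame_interval_ns = config$frame_interval_ns)

  # parameters: neutral default; charged pad atoms for the decomposition
  par_tab <- data.frame(
    residue_name = c("DNR", "DNR", "ACC", "*"),
    atom_name = c("N", "H", "O", "*"),
    charge = c(0.4, 0, -0.4, 0),
    lj_sigma = c(3.25, 0, 2.96, 3.4),
    lj_epsilon = c(0.17, 0, 0.21, 0),
    radius = c(1.65, 1.20, 1.60, 1.70),
    stringsAsFactors = FALSE
  )
  traj$topology <- suppressMessages(attach_parameters(traj$topology, par_tab))

  contacts_df <- data.frame(
    donor_atom = vapply(pad_atoms_new, `[`, 0L, 1L),
    acceptor_atom = vapply(pad_atoms_new, `[`, 0L, 3L),
    chain_pair = vapply(pad_info, `[[`, "", "chain_pair"),
    persistent = vapply(pad_info, `[[`, TRUE, "persistent"),
    fraction = vapply(pad_info, `[[`, 0, "fraction"),
    stringsAsFactors = FALSE
  )

  manifest <- structure(
    list(
      seed = seed, n_frames = nf,
      frame_interval_ns = config$frame_interval_ns,
      contacts = contacts_df,
      contact_schedules = contact_masks,
      helix = list(
        chain = "C", resid_from = 1L, resid_to = config$n_res,
        style = config$helix_style, mask = helix_mask,
        fraction = mean(helix_mask)
      ),
      ejection_frame = eject,
      exposure = list(
        chain = "C", resid = probe_resid, atom = "OH",
        mask = exposure_mask, fraction = mean(exposure_mask)
      ),
      selections = list(
        pocket = "chain A and resid 1-8",
        helix_segment = sprintf("chain C and resid 1-%d and name CA", config$n_res),
        probe = sprintf("chain C and resid %d", probe_resid)
      ),
      parameter_table = par_tab,
      config = config
    ),
    class = "SyntheticManifest"
  )
  list(trajectory = traj, manifest = manifest)
}

#' Write a generated fixture to disk
#'
#' Multi-model PDB + parameter TSV + manifest as structured text,
#' re-readable by [read_structure()]; byte-stable given the seed.
#'
#' @param traj a [trajectory()].
#' @param manifest its `SyntheticManifest`.
#' @param out_dir writable directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(traj, manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(out_dir, "trimer.pdb")
  par <- file.path(out_dir, "params.tsv")
  man <- file.path(out_dir, "manifest.txt")
  write_structure(traj, pdb)
  utils::write.table(manifest$parameter_table, par, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(man, "wt")
  writeLines(c(
    sprintf("seed: %d", manifest$seed),
    sprintf("n_frames: %d", manifest$n_frames),
    sprintf("frame_interval_ns: %g", manifest$frame_interval_ns),
    sprintf("ejection_frame: %s",
            ifelse(is.na(manifest$ejection_frame), "none",
                   manifest$ejection_frame)),
    sprintf("helix: chain %s resid %d-%d style %s fraction %g",
            manifest$helix$chain, manifest$helix$resid_from,
            manifest$helix$resid_to, manifest$helix$style,
            manifest$helix$fraction),
    sprintf("exposure: chain %s resid %d atom %s fraction %g",
            manifest$exposure$chain, manifest$exposure$resid,
            manifest$exposure$atom, manifest$exposure$fraction),
    "", "# contacts"
  ), con)
  utils::write.table(manifest$contacts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("", "# schedules (one row per contact, 0/1 per frame)"), con)
  for (i in seq_along(manifest$contact_schedules)) {
    writeLines(paste0("contact_", i, ": ",
                      paste(as.integer(manifest$contact_schedules[[i]]),
                            collapse = "")), con)
  }
  writeLines(paste0("helix_mask: ",
                    paste(as.integer(manifest$helix$mask), collapse = "")), con)
  writeLines(paste0("exposure_mask: ",
                    paste(as.integer(manifest$exposure$mask), collapse = "")), con)
  close(con)
  c(pdb = pdb, params = par, manifest = man)
}
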