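# Geometric hydrogen-bond detection and persistence statistics.
#
# Criteria: donor-acceptor heavy-atom distance <= 3.0 A and (when the donor
# carries hydrogens) best D-H...A angle >= 135 deg; heavy atoms are N, O, F.
# Contact identity is the (donor atom, acceptor atom) pair; bonds through
# different hydrogens of one donor are merged.  Lifetime fraction counts all
# frames in which the geometric criteria hold; the 1-ns episode rule governs
# only the bound/unbound label.

#' Hydrogen-bond criteria
#'
#' @param max_da_distance_A donor-acceptor heavy-atom cutoff (default 3.0).
#' @param min_dha_angle_deg minimum donor-hydrogen-acceptor angle
#'   (default 135).
#' @param heavy_elements element symbols eligible as donor/acceptor
#'   (default N, O, F).
#' @return Object of class `HBondCriteria`.
#' @export
hbond_criteria <- function(max_da_distance_A = 3.0, min_dha_angle_deg = 135,
                           heavy_elements = c("N", "O", "F")) {
  if (max_da_distance_A <= 0) stop("distance cutoff must be > 0")
  if (min_dha_angle_deg <= 0 || min_dha_angle_deg > 180) {
    stop("angle cutoff must be in (0, 180]")
  }
  structure(
    list(
      max_da_distance_A = max_da_distance_A,
      min_dha_angle_deg = min_dha_angle_deg,
      heavy_elements = toupper(heavy_elements)
    ),
    class = "HBondCriteria"
  )
}

# Map each heavy atom to the indices of its covalently bonded hydrogens
# (distance < 1.2 A in the given frame).
bonded_hydrogens <- function(xyz, top, covalent_cutoff = 1.2) {
  h_idx <- which(top$atoms$element == "H")
  heavy_idx <- which(top$atoms$element != "H")
  out <- vector("list", nrow(top$atoms))
  if (length(h_idx) == 0L) return(out)
  for (h in h_idx) {
    d2 <- rowSums(sweep(xyz[heavy_idx, , drop = FALSE], 2, xyz[h, ])^2)
    j <- which.min(d2)
    if (d2[j] < covalent_cutoff^2) {
      hv <- heavy_idx[j]
      out[[hv]] <- c(out[[hv]], h)
    }
  }
  out
}

angle_deg <- function(a, b, c) {
  # angle at vertex b
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' Donors are heavy atoms of the eligible elements with at least one bonded
#' hydrogen; acceptors are heavy atoms of the eligible elements.  When the
#' topology carries no hydrogens at all the detector falls back to a
#' distance-only criterion and flags the result (`no_h_mode`).
#'
#' @param traj a [trajectory()] (for topology) or a Topology plus `xyz`.
#' @param frame frame index, or an N x 3 matrix when `traj` is a Topology.
#' @param criteria an [hbond_criteria()].
#' @return data.frame with columns `donor`, `hydrogen` (NA in no-H mode),
#'   `acceptor` (atom indices) and attribute `no_h_mode`.
#' @export
detect_frame_hbonds <- function(traj, frame = 1L, criteria = hbond_criteria()) {
  if (inherits(traj, "Trajectory")) {
    top <- traj$topology
    xyz <- frame_coords(traj, frame)
  } else {
    top <- traj
    xyz <- frame
  }
  at <- top$atoms
  heavy <- which(at$element %in% criteria$heavy_elements)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0))
  if (length(heavy) < 2L) return(structure(empty, no_h_mode = FALSE))

  hmap <- bonded_hydrogens(xyz, top)
  no_h_mode <- !any(at$element == "H")
  donors <- if (no_h_mode) heavy else heavy[vapply(hmap[heavy], length, 1L) > 0L]

  res_of <- paste(at$chain, at$resid)
  recs <- list()
  for (d in donors) {
    dv <- sweep(xyz[heavy, , drop = FALSE], 2, xyz[d, ])
    dist <- sqrt(rowSums(dv^2))
    cand <- heavy[dist <= criteria$max_da_distance_A & heavy != d &
                    res_of[heavy] != res_of[d]]
    for (a in cand) {
      if (no_h_mode) {
        # donor/acceptor are indistinguishable without hydrogens; report
        # each unordered pair once
        if (d < a) recs[[length(recs) + 1L]] <- c(d, NA_integer_, a)
      } else {
        angs <- vapply(hmap[[d]], function(h) angle_deg(xyz[d, ], xyz[h, ], xyz[a, ]), 0)
        if (max(angs) >= criteria$min_dha_angle_deg) {
          recs[[length(recs) + 1L]] <- c(d, hmap[[d]][which.max(angs)], a)
        }
      }
    }
  }
  if (length(recs) == 0L) return(structure(empty, no_h_mode = no_h_mode))
  m <- do.call(rbind, recs)
  structure(
    data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3]),
    no_h_mode = no_h_mode
  )
}

#' Per-frame presence of a single donor/acceptor contact
#'
#' @param traj a [trajectory()].
#' @param donor,acceptor atom indices (rows of the atom table).
#' @param criteria an [hbond_criteria()].
#' @param window optional `list(from_ns=, to_ns=)` analysis window.
#' @return Object of class `ContactTimeSeries` with fields `donor`,
#'   `acceptor`, `mask` (logical per analysed frame), `times_ns`,
#'   `frame_interval_ns`.
#' @export
contact_series <- function(traj, donor, acceptor,
                           criteria = hbond_criteria(), window = NULL) {
  at <- traj$topology$atoms
  if (donor < 1L || donor > nrow(at) || acceptor < 1L || acceptor > nrow(at)) {
    stop("donor/acceptor atom index out of range")
  }
  idx <- window_frames(traj, window)
  no_h <- !any(at$element == "H")
  mask <- logical(length(idx))
  for (k in seq_along(idx)) {
    xyz <- frame_coords(traj, idx[k])
    d <- sqrt(sum((xyz[donor, ] - xyz[acceptor, ])^2))
    if (d > criteria$max_da_distance_A) next
    if (no_h) { mask[k] <- TRUE; next }
    hmap <- bonded_hydrogens(xyz, traj$topology)
    hs <- hmap[[donor]]
    if (length(hs) == 0L) next
    angs <- vapply(hs, function(h) angle_deg(xyz[donor, ], xyz[h, ], xyz[acceptor, ]), 0)
    mask[k] <- max(angs) >= criteria$min_dha_angle_deg
  }
  structure(
    list(
      donor = donor, acceptor = acceptor, mask = mask,
      times_ns = traj$times_ns[idx],
      frame_interval_ns = traj$frame_interval_ns
    ),
    class = "ContactTimeSeries"
  )
}

#' Lifetime fraction of a contact
#'
#' Fraction of analysed frames in which the contact satisfies the geometric
#' criteria.
#'
#' @param series a `ContactTimeSeries` or a logical mask.
#' @return Number in [0, 1].
#' @export
lifetime_fraction <- function(series) {
  mask <- if (is.logical(series)) series else series$mask
  if (length(mask) == 0L) stop("empty contact mask")
  mean(mask)
}

# Maximal runs of TRUE in a mask -> data.frame(start, end) of frame indices.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Classify a contact as bound or unbound
#'
#' A contact is bound when it persists for at least `min_episode_ns`
#' continuously at least once; shorter episodes are reported but flagged
#' transient.
#'
#' @param series a `ContactTimeSeries`.
#' @param min_episode_ns minimum continuous presence to call the contact
#'   bound (default 1.0 ns).
#' @return Object of class `PersistenceRecord` with `lifetime_fraction`,
#'   `episodes` (data.frame start_ns, end_ns, duration_ns, transient),
#'   `is_bound`.
#' @export
classify_bound <- function(series, min_episode_ns = 1.0) {
  if (!inherits(series, "ContactTimeSeries")) stop("need a ContactTimeSeries")
  runs <- true_runs(series$mask)
  dt <- series$frame_interval_ns
  # duration measured as (frames in run) * frame interval
  episodes <- data.frame(
    start_ns = series$times_ns[runs$start],
    end_ns = series$times_ns[runs$end],
    duration_ns = (runs$end - runs$start + 1L) * dt
  )
  episodes$transient <- episodes$duration_ns < min_episode_ns
  structure(
    list(
      donor = series$donor, acceptor = series$acceptor,
      lifetime_fraction = mean(series$mask),
      episodes = episodes,
      is_bound = nrow(episodes) > 0L && any(!episodes$transient),
      min_episode_ns = min_episode_ns
    ),
    class = "PersistenceRecord"
  )
}

#' Persistent intermolecular hydrogen-bond network
#'
#' Detects all hydrogen bonds per frame over the analysis window, merges
#' them by (donor, acceptor) identity, restricts to the requested chain
#' pairs, and retains contacts whose lifetime fraction exceeds `threshold`.
#'
#' @param traj a [trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param threshold lifetime-fraction cutoff (default 0.5).
#' @param chain_pairs list of 2-vectors of chain ids, e.g.
#'   `list(c("A","B"), c("A","C"), c("B","C"))`; NULL = all intermolecular.
#' @param window optional analysis window `list(from_ns=, to_ns=)`.
#' @param min_episode_ns bound-episode rule passed to [classify_bound()].
#' @return data.frame (one row per retained contact) sorted by lifetime
#'   fraction descending: donor/acceptor chain, resid, resname, atom name,
#'   `chain_pair`, `lifetime_fraction`, `n_episodes`, `longest_episode_ns`,
#'   `is_bound`.
#' @export
persistent_network <- function(traj, criteria = hbond_criteria(),
                               threshold = 0.5, chain_pairs = NULL,
                               window = NULL, min_episode_ns = 1.0) {
  at <- traj$topology$atoms
  idx <- window_frames(traj, window)
  nfr <- length(idx)
  masks <- new.env(parent = emptyenv())
  for (k in seq_along(idx)) {
    hb <- detect_frame_hbonds(traj, idx[k], criteria)
    if (nrow(hb) == 0L) next
    keys <- paste(hb$donor, hb$acceptor, sep = "_")
    for (r in seq_len(nrow(hb))) {
      key <- keys[r]
      if (is.null(masks[[key]])) masks[[key]] <- logical(nfr)
      masks[[key]][k] <- TRUE
    }
  }
  keys <- ls(masks)
  if (length(keys) == 0L) {
    return(empty_network_table())
  }
  rows <- list()
  dt <- traj$frame_interval_ns
  for (key in keys) {
    da <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    d <- da[1]; a <- da[2]
    cd <- at$chain[d]; ca <- at$chain[a]
    if (cd == ca) next  # intermolecular networks only
    if (!is.null(chain_pairs)) {
      ok <- any(vapply(chain_pairs, function(p) setequal(p, c(cd, ca)), TRUE))
      if (!ok) next
    }
    mask <- masks[[key]]
    frac <- mean(mask)
    if (frac <= threshold) next
    runs <- true_runs(mask)
    durations <- (runs$end - runs$start + 1L) * dt
    rows[[length(rows) + 1L]] <- data.frame(
      donor_chain = cd, donor_resid = at$resid[d],
      donor_resname = at$resname[d], donor_atom = at$name[d],
      acceptor_chain = ca, acceptor_resid = at$resid[a],
      acceptor_resname = at$resname[a], acceptor_atom = at$name[a],
      chain_pair = paste(sort(c(cd, ca)), collapse = "-"),
      lifetime_fraction = frac,
      n_episodes = nrow(runs),
      longest_episode_ns = max(durations),
      is_bound = any(durations >= min_episode_ns),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty_network_table())
  out <- do.call(rbind, rows)
  out <- out[order(-out$lifetime_fraction, out$donor_chain, out$donor_resid), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_network_table <- function() {
  data.frame(
    donor_chain = character(0), donor_resid = integer(0),
    donor_resname = character(0), donor_atom = character(0),
    acceptor_chain = character(0), acceptor_resid = integer(0),
    acceptor_resname = character(0), acceptor_atom = character(0),
    chain_pair = character(0), lifetime_fraction = numeric(0),
    n_episodes = integer(0), longest_episode_ns = numeric(0),
    is_bound = logical(0), stringsAsFactors = FALSE
  )
}
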