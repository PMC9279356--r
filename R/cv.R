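# Centre-of-mass collective variables, ejection-event detection,
# dissociation timing, Cdk4 activity inference, and k-means conformer
# clustering.

#' Centre-of-mass distance time series
#'
#' Euclidean distance between the (mass-weighted) centroids of two atom
#' selections, per frame.
#'
#' @param traj a [trajectory()].
#' @param selA,selB selections (objects or expressions).
#' @param mass_weighted use atomic masses (default TRUE); FALSE gives the
#'   geometric centroid.
#' @param window optional analysis window `list(from_ns=, to_ns=)`.
#' @param name series label.
#' @return Object of class `CVSeries` with `times_ns`, `values_A`.
#' @export
com_distance_series <- function(traj, selA, selB, mass_weighted = TRUE,
                                window = NULL, name = "com_distance") {
  top <- traj$topology
  ia <- resolve_selection(top, selA)
  ib <- resolve_selection(top, selB)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection for COM distance")
  wa <- if (mass_weighted) element_mass(top$atoms$element[ia]) else rep(1, length(ia))
  wb <- if (mass_weighted) element_mass(top$atoms$element[ib]) else rep(1, length(ib))
  idx <- window_frames(traj, window)
  vals <- vapply(idx, function(f) {
    xyz <- frame_coords(traj, f)
    ca <- colSums(xyz[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(xyz[ib, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, 0)
  structure(
    list(
      name = name, times_ns = traj$times_ns[idx], values_A = vals,
      selA = if (is.character(selA)) selA else selA$expression,
      selB = if (is.character(selB)) selB else selB$expression
    ),
    class = "CVSeries"
  )
}

#' Build a CVSeries from raw vectors
#'
#' @param times_ns,values_A numeric vectors of equal length.
#' @param name series label.
#' @return A `CVSeries`.
#' @export
cv_series <- function(times_ns, values_A, name = "cv") {
  if (length(times_ns) != length(values_A)) stop("length mismatch")
  if (any(values_A < 0)) stop("CV values must be >= 0")
  structure(list(name = name, times_ns = times_ns, values_A = values_A),
            class = "CVSeries")
}

#' Detect ejection events in a distance series
#'
#' The baseline is the series mean over `[start, start + baseline_window_ns]`.
#' An ejection onset is the first time the series exceeds
#' baseline + `delta_A` and stays above continuously for at least
#' `sustain_ns`; the event is flagged sustained when the excursion lasts to
#' the end of the series.  Baselines are always computed per system, never
#' shared: phosphorylation itself shifts the centre of mass of the tracked
#' group.
#'
#' @param series a `CVSeries`.
#' @param baseline_window_ns length of the baseline window at the start of
#'   the series.
#' @param delta_A required rise above baseline (default 5 A).
#' @param sustain_ns minimum continuous excursion (default 5 ns).
#' @return Object of class `EventSet`: data.frame `events` (type, onset_ns,
#'   sustained), `baseline_A`, `threshold_A`, `time_to_first_ns` (NA when
#'   no sustained excursion).
#' @export
detect_ejection <- function(series, baseline_window_ns, delta_A = 5,
                            sustain_ns = 5) {
  t <- series$times_ns
  v <- series$values_A
  base_idx <- which(t <= t[1] + baseline_window_ns)
  if (length(base_idx) == 0L) stop("baseline window empty")
  baseline <- mean(v[base_idx])
  thr <- baseline + delta_A
  above <- v > thr
  runs <- true_runs(above)
  events <- data.frame(type = character(0), onset_ns = numeric(0),
                       sustained = logical(0), stringsAsFactors = FALSE)
  if (nrow(runs) > 0L) {
    dur <- t[runs$end] - t[runs$start]
    # a run reaching the final frame counts its full remaining span
    keep <- dur >= sustain_ns |
      (runs$end == length(t) & (t[length(t)] - t[runs$start]) >= sustain_ns)
    if (any(keep)) {
      events <- data.frame(
        type = "ejection",
        onset_ns = t[runs$start[keep]],
        sustained = runs$end[keep] == length(t),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      events = events, baseline_A = baseline, threshold_A = thr,
      delta_A = delta_A, sustain_ns = sustain_ns,
      time_to_first_ns = if (nrow(events) > 0L) events$onset_ns[1] else NA_real_
    ),
    class = "EventSet"
  )
}

#' Time to first sustained dissociation event
#'
#' @param eventset an `EventSet` from [detect_ejection()].
#' @return list: `time_ns` (NA when no event) and `rate_per_ns`
#'   (1/time, the comparative dissociation rate; NA when no event).
#' @export
time_to_dissociation <- function(eventset) {
  tt <- eventset$time_to_first_ns
  list(time_ns = tt, rate_per_ns = if (is.na(tt) || tt <= 0) NA_real_ else 1 / tt)
}

#' Infer Cdk4 activity state from two distance series
#'
#' Decision table over the analysis window, with per-system thresholds:
#' residue-74 anchor bound = distance below `bound_threshold_A`
#' (default: its own baseline mean + 3 A); active site open = catalytic
#' Lys to C-helix distance above `open_threshold_A` (default: baseline
#' mean + 2 A).
#'
#' * anchor unbound throughout -> `active`
#' * anchor bound -> unbound transition -> `partially_active`
#' * anchor bound throughout, site open -> `partially_active`
#' * anchor bound throughout, site closed -> `inactive`
#'
#' @param dist_res74 `CVSeries`: inhibitor residue-74-equivalent to Cdk COM.
#' @param dist_lys_chelix `CVSeries`: catalytic lysine to C-helix COM.
#' @param bound_threshold_A,open_threshold_A explicit thresholds (A);
#'   NULL = baseline-derived defaults.
#' @param baseline_window_ns baseline span for the default thresholds.
#' @return Object of class `ActivityCall`: `state`, `evidence` (res74_bound,
#'   res74_transition, site_open), thresholds and window.
#' @export
cdk4_activity_call <- function(dist_res74, dist_lys_chelix,
                               bound_threshold_A = NULL,
                               open_threshold_A = NULL,
                               baseline_window_ns = 10) {
  if (length(dist_res74$times_ns) != length(dist_lys_chelix$times_ns) ||
      any(abs(dist_res74$times_ns - dist_lys_chelix$times_ns) > 1e-9)) {
    stop("window mismatch between the two distance series")
  }
  t <- dist_res74$times_ns
  base_idx <- which(t <= t[1] + baseline_window_ns)
  if (is.null(bound_threshold_A)) {
    bound_threshold_A <- mean(dist_res74$values_A[base_idx]) + 3
  }
  if (is.null(open_threshold_A)) {
    open_threshold_A <- mean(dist_lys_chelix$values_A[base_idx]) + 2
  }
  bound <- dist_res74$values_A < bound_threshold_A
  open_site <- dist_lys_chelix$values_A > open_threshold_A

  bound_throughout <- all(bound)
  unbound_throughout <- all(!bound)
  # transition: starts bound, ends unbound (sustained to the window end)
  transition <- bound[1] && !bound[length(bound)] && !bound_throughout
  site_open <- mean(open_site) > 0.5

  state <- if (unbound_throughout) {
    "active"
  } else if (transition) {
    "partially_active"
  } else if (bound_throughout && !site_open) {
    "inactive"
  } else if (bound_throughout && site_open) {
    "partially_active"
  } else {
    # intermittent unbinding without a lasting transition: treat like a
    # transition-capable (partially active) system
    "partially_active"
  }
  structure(
    list(
      state = state,
      evidence = list(
        res74_bound = bound_throughout,
        res74_transition = transition,
        site_open = site_open,
        fraction_bound = mean(bound)
      ),
      bound_threshold_A = bound_threshold_A,
      open_threshold_A = open_threshold_A,
      window_ns = range(t)
    ),
    class = "ActivityCall"
  )
}

#' @export
print.ActivityCall <- function(x, ...) {
  cat("state:", x$state, "\n")
  cat("res74_bound_throughout:", x$evidence$res74_bound, "\n")
  cat("res74_transition:", x$evidence$res74_transition, "\n")
  cat("site_open:", x$evidence$site_open, "\n")
  cat(sprintf("bound_threshold_A: %.3f\nopen_threshold_A: %.3f\n",
              x$bound_threshold_A, x$open_threshold_A))
  invisible(x)
}

# k-means++ seeding (deterministic given the RNG state)
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  if (k > 1L) {
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

#' Cluster trajectory frames by conformation
#'
#' Superposes every frame onto the first on the feature selection, flattens
#' the selected coordinates, and runs k-means (k-means++ initialisation,
#' Lloyd iterations, fixed seed).  The centroid frame of each cluster is
#' the frame closest to its cluster mean.
#'
#' @param traj a [trajectory()].
#' @param feature_selection atoms used as features (default all C-alpha).
#' @param k number of clusters (default 2).
#' @param seed RNG seed (default 1).
#' @return list: `labels` (per frame), `centroid_frames` (one per cluster),
#'   `sizes`, `withinss`.
#' @export
cluster_frames <- function(traj, feature_selection = "name CA", k = 2L,
                           seed = 1L) {
  nf <- n_frames(traj)
  if (k > nf) stop("k exceeds the number of frames")
  idx <- resolve_selection(traj$topology, feature_selection)
  if (length(idx) == 0L) stop("empty feature selection")
  ref <- frame_coords(traj, 1L)[idx, , drop = FALSE]
  X <- matrix(0, nf, 3L * length(idx))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)[idx, , drop = FALSE]
    fit <- kabsch_superpose(xyz, ref)
    moved <- sweep(xyz %*% fit$rotation, 2, fit$translation, `+`)
    X[f, ] <- as.numeric(t(moved))
  }
  set.seed(seed)
  init <- kmeanspp_centers(X, k)
  km <- suppressWarnings(
    stats::kmeans(X, centers = init, iter.max = 100L, algorithm = "Lloyd")
  )
  labels <- km$cluster
  centroid_frames <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(labels == cl)
    d2 <- rowSums(sweep(X[members, , drop = FALSE], 2, km$centers[cl, ])^2)
    centroid_frames[cl] <- members[which.min(d2)]
  }
  list(labels = labels, centroid_frames = centroid_frames,
       sizes = as.integer(km$size), withinss = km$withinss)
}
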