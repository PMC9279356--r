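# collective_variables: COM distances, ejection detection, activity calls,
# k-means conformer clustering.

two_group_traj <- function(posA, posB, elA = "C", elB = "C") {
  nA <- nrow(posA); nB <- nrow(posB)
  top <- topology(data.frame(
    serial = seq_len(nA + nB),
    name = paste0("X", seq_len(nA + nB)),
    element = c(rep(elA, nA), rep(elB, nB)),
    resname = "UNK", resid = c(rep(1L, nA), rep(2L, nB)),
    chain = c(rep("A", nA), rep("B", nB)), stringsAsFactors = FALSE
  ))
  trajectory(top, rbind(posA, posB), 0.1)
}

test_that("COM distances match hand-computed centroids, weighted and unweighted", {
  tr <- two_group_traj(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1))
  s <- com_distance_series(tr, "chain A", "chain B")
  expect_equal(s$values_A, 2.0)

  tr2 <- two_group_traj(rbind(c(0, 0, 0), c(2, 0, 0)), matrix(c(1, 0, 4), 1))
  expect_equal(com_distance_series(tr2, "chain A", "chain B")$values_A, 4.0)

  # masses 12 (C) and ~1 (H): COM near x = 1 for atoms at 0 and 13
  tr3 <- two_group_traj(rbind(c(0, 0, 0), c(13, 0, 0)),
                        matrix(c(0, 0, 0), 1), elA = "C")
  tr3$topology$atoms$element[2] <- "H"
  s3 <- com_distance_series(tr3, "chain A", "chain B", mass_weighted = TRUE)
  expect_equal(s3$values_A, 13 * 1.008 / (12.011 + 1.008), tolerance = 1e-9)

  expect_error(com_distance_series(tr, "chain Q", "chain B"), "empty selection")
})

test_that("COM distance is invariant under global rigid motion", {
  gen <- make_toy_trimer(toy_trimer_config(n_frames = 10), seed = 4)
  tr <- gen$trajectory
  ref <- com_distance_series(tr, "chain A", "chain C")$values_A
  rg <- random_rigid(6)
  coords <- tr$coords
  for (f in seq_len(n_frames(tr))) {
    coords[, , f] <- apply_rigid(coords[, , f], rg)
  }
  tr2 <- trajectory(tr$topology, coords, tr$frame_interval_ns)
  expect_equal(com_distance_series(tr2, "chain A", "chain C")$values_A,
               ref, tolerance = 1e-9)
})

test_that("ejection detection: flat series, clean step, planted frame, monotonicity", {
  flat <- cv_series(seq(0, 49.9, 0.1), rep(10, 500))
  ev0 <- detect_ejection(flat, baseline_window_ns = 10)
  expect_equal(nrow(ev0$events), 0L)
  expect_true(is.na(ev0$time_to_first_ns))
  expect_true(is.na(time_to_dissociation(ev0)$time_ns))

  t <- seq(0, 299.9, 0.1)
  step <- cv_series(t, ifelse(t < 150, 10, 18))
  ev1 <- detect_ejection(step, baseline_window_ns = 50)
  expect_equal(ev1$time_to_first_ns, 150)
  expect_true(ev1$events$sustained[1])
  expect_equal(time_to_dissociation(ev1)$rate_per_ns, 1 / 150)

  # planted ejection in the generator: onset within one frame
  gen <- make_toy_trimer(
    toy_trimer_config(n_frames = 120, helix_fraction = 1,
                      ejection_frame = 80L), seed = 11
  )
  man <- gen$manifest
  cv <- com_distance_series(gen$trajectory, man$selections$helix_segment,
                            man$selections$pocket)
  ev <- detect_ejection(cv, baseline_window_ns = 3, delta_A = 5,
                        sustain_ns = 2)
  onset_frame <- which(cv$times_ns == ev$time_to_first_ns)
  expect_lte(abs(onset_frame - man$ejection_frame), 1)

  # raising delta_A never yields an earlier onset
  onsets <- vapply(c(2, 4, 6, 8), function(d) {
    e <- detect_ejection(cv, baseline_window_ns = 3, delta_A = d,
                         sustain_ns = 2)
    if (is.na(e$time_to_first_ns)) Inf else e$time_to_first_ns
  }, 0)
  expect_true(all(diff(onsets) >= 0))

  # dissociation-rate ordering of two systems
  early <- detect_ejection(cv_series(t, ifelse(t < 50, 10, 18)), 10)
  late <- detect_ejection(cv_series(t, ifelse(t < 200, 10, 18)), 10)
  expect_gt(time_to_dissociation(early)$rate_per_ns,
            time_to_dissociation(late)$rate_per_ns)
})

test_that("activity decision table reproduces the published qualitative ordering", {
  t <- seq(25, 499.9, 0.1)
  closed <- cv_series(t, rep(8, length(t)))
  open <- cv_series(t, rep(14, length(t)))

  # anchor residue bound, site closed -> inactive (p21-like, p27-like)
  bound <- cv_series(t, rep(10, length(t)))
  call1 <- cdk4_activity_call(bound, closed, bound_threshold_A = 13,
                              open_threshold_A = 10)
  expect_equal(call1$state, "inactive")
  expect_true(call1$evidence$res74_bound)

  # bound -> unbound transition around 150 ns -> partially active
  trans <- cv_series(t, ifelse(t < 150, 10, 20))
  call2 <- cdk4_activity_call(trans, closed, bound_threshold_A = 13,
                              open_threshold_A = 10)
  expect_equal(call2$state, "partially_active")
  expect_true(call2$evidence$res74_transition)

  # unbound throughout -> active (p57-like)
  unb <- cv_series(t, rep(20, length(t)))
  call3 <- cdk4_activity_call(unb, open, bound_threshold_A = 13,
                              open_threshold_A = 10)
  expect_equal(call3$state, "active")

  # totality: every bound/site pattern maps to exactly one state
  patterns <- list(
    list(v = rep(10, length(t)), site = closed),
    list(v = rep(10, length(t)), site = open),
    list(v = ifelse(t < 150, 10, 20), site = open),
    list(v = ifelse(t < 150, 20, 10), site = closed),
    list(v = rep(20, length(t)), site = closed)
  )
  for (p in patterns) {
    cl <- cdk4_activity_call(cv_series(t, p$v), p$site,
                             bound_threshold_A = 13, open_threshold_A = 10)
    expect_true(cl$state %in% c("inactive", "partially_active", "active"))
  }
  expect_error(
    cdk4_activity_call(bound, cv_series(t[-1], rep(8, length(t) - 1)),
                       13, 10),
    "window mismatch"
  )
})

test_that("k-means recovers planted two-state conformations and centroids", {
  # alternate between two rigid conformations separated by a 5 A shift
  tr <- backbone_trajectory(-57, -47, 6)
  xyz <- frame_coords(tr, 1)
  nf <- 40
  coords <- array(0, dim = c(nrow(xyz), 3, nf))
  truth <- rep(c(1L, 2L), nf / 2)
  for (f in seq_len(nf)) {
    base <- if (truth[f] == 1L) xyz else {
      x2 <- xyz
      ca <- resolve_selection(tr$topology, "name CA")
      x2[ca[3:4], ] <- x2[ca[3:4], ] + c(5, 0, 0)
      x2
    }
    coords[, , f] <- base
  }
  tr2 <- trajectory(tr$topology, coords, 0.1)
  cl <- cluster_frames(tr2, "name CA", k = 2, seed = 1)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3L - truth))
  expect_equal(agree, 1)

  # identical frames, k = 1 -> centroid frame 1
  same <- trajectory(tr$topology, array(rep(xyz, 5), dim = c(nrow(xyz), 3, 5)), 0.1)
  c1 <- cluster_frames(same, "name CA", k = 1, seed = 1)
  expect_equal(c1$centroid_frames, 1L)

  # 70/30 split with 0.2 A noise: >= 95% label accuracy, deterministic
  set.seed(77)
  truth2 <- c(rep(1L, 28), rep(2L, 12))
  coords2 <- array(0, dim = c(nrow(xyz), 3, 40))
  moved_atoms <- which(tr$topology$atoms$resid >= 5)  # conformational change
  for (f in 1:40) {
    base <- xyz
    if (truth2[f] == 2L) {
      base[moved_atoms, ] <- base[moved_atoms, ] +
        matrix(c(3, 0, 0), length(moved_atoms), 3, byrow = TRUE)
    }
    coords2[, , f] <- base + matrix(rnorm(3 * nrow(xyz), sd = 0.2), nrow(xyz), 3)
  }
  tr3 <- trajectory(tr$topology, coords2, 0.1)
  cl3a <- cluster_frames(tr3, "name CA", k = 2, seed = 5)
  cl3b <- cluster_frames(tr3, "name CA", k = 2, seed = 5)
  expect_identical(cl3a$labels, cl3b$labels)
  acc <- max(mean(cl3a$labels == truth2), mean(cl3a$labels == 3L - truth2))
  expect_gte(acc, 0.95)

  expect_error(cluster_frames(tr2, "name CA", k = 100), "exceeds")
})
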