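# hbond_network: geometric detection, lifetime statistics, persistence.

test_that("detection honours the 3.0 A / 135 deg criteria on constructed geometries", {
  crit <- hbond_criteria()
  good <- hb_pair_frame(2.8, 170)
  expect_equal(nrow(detect_frame_hbonds(good$top, good$xyz, crit)), 1L)

  far <- hb_pair_frame(3.2, 180)
  expect_equal(nrow(detect_frame_hbonds(far$top, far$xyz, crit)), 0L)

  bent <- hb_pair_frame(2.8, 120)
  expect_equal(nrow(detect_frame_hbonds(bent$top, bent$xyz, crit)), 0L)

  # geometry just inside both thresholds passes (the exact boundary is
  # not representable after coordinate construction)
  edge <- hb_pair_frame(2.999, 135.5)
  expect_equal(nrow(detect_frame_hbonds(edge$top, edge$xyz, crit)), 1L)
})

test_that("detection is invariant under global rigid motion", {
  good <- hb_pair_frame(2.8, 170)
  for (s in 1:3) {
    moved <- apply_rigid(good$xyz, random_rigid(s))
    expect_equal(nrow(detect_frame_hbonds(good$top, moved)), 1L)
  }
})

test_that("hydrogen-free topologies fall back to distance-only mode with a flag", {
  top <- topology(data.frame(
    serial = 1:2, name = c("N", "O"), element = c("N", "O"),
    resname = c("GLY", "SER"), resid = 1:2, chain = c("A", "B"),
    stringsAsFactors = FALSE
  ))
  hb <- detect_frame_hbonds(top, rbind(c(0, 0, 0), c(2.8, 0, 0)))
  expect_equal(nrow(hb), 1L)
  expect_true(attr(hb, "no_h_mode"))
})

test_that("contact masks equal the planted schedules exactly", {
  gen <- make_toy_trimer(toy_trimer_config(n_frames = 100), seed = 5)
  man <- gen$manifest
  for (i in seq_len(nrow(man$contacts))) {
    cs <- contact_series(gen$trajectory, man$contacts$donor_atom[i],
                         man$contacts$acceptor_atom[i])
    expect_identical(cs$mask, man$contact_schedules[[i]])
    expect_equal(lifetime_fraction(cs), man$contacts$fraction[i])
  }
})

test_that("lifetime fraction is the plain frame fraction, with complement identity", {
  mask <- c(rep(TRUE, 300), rep(FALSE, 100))
  expect_equal(lifetime_fraction(mask), 0.75)
  # 2240 of 4000 frames on: the flagship Cyclin-Cdk persistence value
  m2 <- c(rep(TRUE, 2240), rep(FALSE, 1760))
  expect_equal(lifetime_fraction(m2), 0.56)
  expect_equal(lifetime_fraction(!m2), 1 - 0.56)
  expect_equal(lifetime_fraction(rep(FALSE, 10)), 0)
  expect_error(lifetime_fraction(logical(0)), "empty")
})

test_that("the 1 ns episode rule controls only the bound label", {
  mk_series <- function(mask) {
    structure(list(donor = 1L, acceptor = 2L, mask = mask,
                   times_ns = (seq_along(mask) - 1) * 0.1,
                   frame_interval_ns = 0.1),
              class = "ContactTimeSeries")
  }
  # 12 consecutive frames at 0.1 ns = 1.2 ns -> bound
  b <- classify_bound(mk_series(c(rep(FALSE, 5), rep(TRUE, 12), rep(FALSE, 5))))
  expect_true(b$is_bound)
  expect_equal(nrow(b$episodes), 1L)
  expect_equal(b$episodes$duration_ns, 1.2)

  # alternating frames: fraction 0.5 but never bound
  alt <- classify_bound(mk_series(rep(c(TRUE, FALSE), 20)))
  expect_false(alt$is_bound)
  expect_equal(alt$lifetime_fraction, 0.5)

  # one 0.5 ns transient + one 3 ns bound episode
  two <- classify_bound(mk_series(c(rep(TRUE, 5), rep(FALSE, 10),
                                    rep(TRUE, 30), rep(FALSE, 5))))
  expect_equal(nrow(two$episodes), 2L)
  expect_identical(two$episodes$transient, c(TRUE, FALSE))
  expect_true(two$is_bound)
})

test_that("persistence filtering keeps exactly the contacts above threshold", {
  gen <- make_toy_trimer(toy_trimer_config(n_frames = 100), seed = 5)
  man <- gen$manifest
  net <- persistent_network(gen$trajectory, threshold = 0.5)
  expect_equal(nrow(net), sum(man$contacts$persistent))
  expect_setequal(net$lifetime_fraction,
                  man$contacts$fraction[man$contacts$persistent])
  # sorted descending
  expect_identical(net$lifetime_fraction, sort(net$lifetime_fraction,
                                               decreasing = TRUE))
  # any threshold strictly between transient and persistent fractions
  # recovers the same set
  for (thr in c(0.35, 0.45, 0.5)) {
    n2 <- persistent_network(gen$trajectory, threshold = thr)
    expect_equal(nrow(n2), sum(man$contacts$persistent))
  }
  # threshold ~0 returns every planted contact
  n0 <- persistent_network(gen$trajectory, threshold = 0.01)
  expect_equal(nrow(n0), nrow(man$contacts))
  # chain-pair restriction
  nac <- persistent_network(gen$trajectory, threshold = 0.01,
                            chain_pairs = list(c("A", "C")))
  expect_true(all(nac$chain_pair == "A-C"))
})

test_that("the example fraction set {0.69, 0.57, 0.39} filters at 0.5 as published", {
  fractions <- c(0.69, 0.57, 0.39)
  kept <- fractions[fractions > 0.5]
  expect_equal(sort(kept, decreasing = TRUE), c(0.69, 0.57))
})
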