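# energy_decomposition: pair energies, per-residue shares, ranking.

toy_interface <- function(n_res_each = 1, seed = 1) {
  # one atom per residue, receptor chain A / ligand chain C, random charges
  set.seed(seed)
  n <- 2 * n_res_each
  top <- topology(data.frame(
    serial = seq_len(n), name = "X1", element = "C", resname = "UNK",
    resid = rep(seq_len(n_res_each), 2),
    chain = rep(c("A", "C"), each = n_res_each), stringsAsFactors = FALSE
  ))
  top$atoms$charge <- round(runif(n, -1, 1), 3)
  top$atoms$lj_sigma <- 3.4
  top$atoms$lj_epsilon <- 0
  top$atoms$radius <- 1.7
  xyz <- rbind(
    cbind(0, 4 * seq_len(n_res_each), 0),
    cbind(6, 4 * seq_len(n_res_each) + runif(n_res_each), 0)
  )
  trajectory(top, xyz, 0.1)
}

test_that("pair energies match closed forms", {
  vac <- energy_model("vacuum", lj = FALSE)
  # opposite unit charges at k/100 Angstrom -> exactly -100 kcal/mol
  expect_equal(pair_energy(1, -1, c(0, 0, 0), c(3.320637, 0, 0), model = vac),
               -100.0, tolerance = 1e-9)
  expect_equal(pair_energy(0, -1, c(0, 0, 0), c(3, 0, 0), model = vac), 0)

  # LJ root at r = sigma
  ljm <- energy_model("vacuum", lj = TRUE)
  expect_equal(pair_energy(0, 0, c(0, 0, 0), c(3.4, 0, 0),
                           si = 3.4, sj = 3.4, ei = 0.2, ej = 0.2,
                           model = ljm), 0, tolerance = 1e-12)
  # symmetry
  e1 <- pair_energy(0.3, -0.7, c(0, 0, 0), c(4, 1, 0), si = 3.2, sj = 3.6,
                    ei = 0.1, ej = 0.2, model = ljm)
  e2 <- pair_energy(-0.7, 0.3, c(4, 1, 0), c(0, 0, 0), si = 3.6, sj = 3.2,
                    ei = 0.2, ej = 0.1, model = ljm)
  expect_equal(e1, e2, tolerance = 1e-12)

  expect_error(pair_energy(1, 1, c(0, 0, 0), c(0, 0, 0), model = vac),
               "coincident")
  expect_error(pair_energy(NA, 1, c(0, 0, 0), c(1, 0, 0), model = vac),
               "charge")
})

test_that("two-residue toy: symmetric split gives each side half the pair energy", {
  tr <- toy_interface(1, seed = 2)
  for (dm in c("vacuum", "distance_dependent", "debye")) {
    dec <- per_residue_binding_decomposition(
      tr, "chain A", "chain C", model = energy_model(dm, lj = FALSE)
    )
    tot <- attr(dec, "dE_total_mean")
    expect_equal(dec$dE_mean_kcal_mol, rep(tot / 2, 2), tolerance = 1e-12)
  }
})

test_that("shares sum to dE_total and equal a brute-force double loop", {
  tr <- toy_interface(5, seed = 3)
  model <- energy_model("distance_dependent", lj = FALSE)
  dec <- per_residue_binding_decomposition(tr, "chain A", "chain C",
                                           model = model)
  shares <- attr(dec, "shares_per_frame")
  totals <- attr(dec, "dE_total_per_frame")
  expect_lt(max(abs(rowSums(shares) - totals)), 1e-8)

  # brute force: loop over all cross pairs
  at <- tr$topology$atoms
  xyz <- frame_coords(tr, 1)
  rec <- which(at$chain == "A"); lig <- which(at$chain == "C")
  brute_tot <- 0
  brute_share <- stats::setNames(
    numeric(nrow(dec)), paste(dec$chain, dec$resid)
  )
  for (i in rec) {
    for (j in lig) {
      e <- pair_energy(at$charge[i], at$charge[j], xyz[i, ], xyz[j, ],
                       model = model)
      brute_tot <- brute_tot + e
      brute_share[paste(at$chain[i], at$resid[i])] <-
        brute_share[paste(at$chain[i], at$resid[i])] + e / 2
      brute_share[paste(at$chain[j], at$resid[j])] <-
        brute_share[paste(at$chain[j], at$resid[j])] + e / 2
    }
  }
  expect_equal(attr(dec, "dE_total_mean"), brute_tot, tolerance = 1e-10)
  expect_equal(dec$dE_mean_kcal_mol,
               unname(brute_share[paste(dec$chain, dec$resid)]),
               tolerance = 1e-10)
})

test_that("separated ligand gives ~zero everywhere; swap symmetry holds", {
  tr <- toy_interface(3, seed = 4)
  far <- tr
  lig <- which(tr$topology$atoms$chain == "C")
  far$coords[lig, 1, 1] <- far$coords[lig, 1, 1] + 1e4
  dec_far <- per_residue_binding_decomposition(
    far, "chain A", "chain C",
    model = energy_model("distance_dependent", lj = FALSE)
  )
  expect_lt(max(abs(dec_far$dE_mean_kcal_mol)), 1e-6)

  dec_ab <- per_residue_binding_decomposition(
    tr, "chain A", "chain C", model = energy_model("vacuum", lj = FALSE)
  )
  dec_ba <- per_residue_binding_decomposition(
    tr, "chain C", "chain A", model = energy_model("vacuum", lj = FALSE)
  )
  expect_equal(attr(dec_ab, "dE_total_mean"), attr(dec_ba, "dE_total_mean"),
               tolerance = 1e-12)
  expect_equal(dec_ab$dE_mean_kcal_mol, dec_ba$dE_mean_kcal_mol,
               tolerance = 1e-12)

  expect_error(
    per_residue_binding_decomposition(tr, "chain A", "chain A or chain C"),
    "overlap"
  )
})

test_that("rank_contributors applies the +/-2 kcal/mol filter with deterministic ties", {
  df <- data.frame(
    chain = c("C", "B", "C", "A", "A"), resid = c(88L, 268L, 30L, 5L, 2L),
    resname = c("Y2P", "GLU", "ARG", "ALA", "ALA"),
    dE_mean_kcal_mol = c(26, -8, 1.5, 3, -3),
    dE_stderr = 0.1, flag_minor = abs(c(26, -8, 1.5, 3, -3)) < 2,
    stringsAsFactors = FALSE
  )
  class(df) <- c("DecompositionTable", "data.frame")
  rk <- rank_contributors(df, cutoff = 2)
  expect_equal(rk$destabilizing$dE_mean_kcal_mol, c(26, 3))
  expect_equal(rk$stabilizing$dE_mean_kcal_mol, c(-8, -3))
  expect_false(1.5 %in% c(rk$destabilizing$dE_mean_kcal_mol,
                          rk$stabilizing$dE_mean_kcal_mol))

  # all-zero table -> both lists empty
  zero <- df; zero$dE_mean_kcal_mol <- 0
  rz <- rank_contributors(zero)
  expect_equal(nrow(rz$destabilizing), 0L)
  expect_equal(nrow(rz$stabilizing), 0L)

  # ties at equal |dE| sort by (chain, resid)
  tie <- df; tie$dE_mean_kcal_mol <- c(5, 5, 5, 5, 5)
  rt <- rank_contributors(tie)
  expect_equal(rt$destabilizing$chain, c("A", "A", "B", "C", "C"))
  expect_equal(rt$destabilizing$resid, c(2L, 5L, 268L, 30L, 88L))
})

test_that("decomposition TSV carries the model-provenance header", {
  tr <- toy_interface(2, seed = 5)
  dec <- per_residue_binding_decomposition(tr, "chain A", "chain C")
  f <- tempfile(fileext = ".tsv")
  write_decomposition_tsv(dec, f)
  head2 <- readLines(f, n = 2)
  expect_match(head2[1], "NOT an MM-PBSA")
  expect_match(head2[2], "dE_total_mean")
})
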