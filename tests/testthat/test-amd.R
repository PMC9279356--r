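# amd_toy: boost closed forms, Langevin sampling, reweighting, estimation.

test_that("boost closed forms: boundary, V = E - alpha, numerical derivative", {
  p <- amd_params(E = 10, alpha = 2)
  at_e <- amd_boost(10, p)
  expect_equal(at_e$deltaV, 0)
  expect_equal(at_e$force_scale, 1)
  above <- amd_boost(12, p)
  expect_equal(above$deltaV, 0)

  half <- amd_boost(10 - 2, p)
  expect_equal(half$deltaV, 2 / 2)
  expect_equal(half$force_scale, 1 / 4)

  # force_scale == d(V + deltaV)/dV by central difference
  set.seed(21)
  for (k in 1:50) {
    E <- runif(1, -5, 5); a <- runif(1, 0.5, 3)
    V <- E - runif(1, 0.01, 6)
    pp <- amd_params(E, a)
    h <- 1e-6
    mod <- function(v) v + amd_boost(v, pp)$deltaV
    num <- (mod(V + h) - mod(V - h)) / (2 * h)
    expect_equal(amd_boost(V, pp)$force_scale, num, tolerance = 1e-5)
  }
})

test_that("deltaV >= 0 and the modified surface is C1 at V = E", {
  p <- amd_params(E = 3, alpha = 1.5)
  V <- seq(-10, 10, by = 0.01)
  b <- amd_boost(V, p)
  expect_true(all(b$deltaV >= 0))
  expect_true(all(b$force_scale > 0 & b$force_scale <= 1))
  # continuity of value and derivative across the threshold
  eps <- 1e-7
  expect_equal(amd_boost(3 - eps, p)$deltaV, 0, tolerance = 1e-10)
  expect_equal(amd_boost(3 - eps, p)$force_scale, 1, tolerance = 1e-5)
})

test_that("harmonic equipartition: position variance matches kT/k within 5%", {
  s <- langevin_settings(n_steps = 2e5, dt = 0.05, friction = 1, seed = 12,
                         reduced_units = TRUE, sample_stride = 5)
  tr <- run_langevin(toy_potential("harmonic", k = 1), s, x0 = 0)
  expect_equal(stats::var(tr$x), 1.0, tolerance = 0.05)
})

test_that("zero-temperature start at the minimum stays there", {
  s <- langevin_settings(temperature_K = 1e-12, n_steps = 2000, dt = 0.01,
                         seed = 1, sample_stride = 10)
  tr <- run_langevin(toy_potential("double_well", h = 6), s, x0 = -1)
  expect_true(all(abs(tr$x + 1) < 1e-4))
})

test_that("boosted sampling crosses the 6 kT barrier more often (paired seeds)", {
  pot <- toy_potential("double_well", h = 6)
  s <- langevin_settings(n_steps = 2e5, dt = 0.01, seed = 31,
                         reduced_units = TRUE, sample_stride = 5)
  un <- run_langevin(pot, s)
  bo <- run_langevin(pot, s, amd = amd_params(E = 7, alpha = 2))
  expect_gte(count_transitions(bo$x), count_transitions(un$x))
  expect_gt(count_transitions(bo$x), 5)
  # determinism given the seed
  un2 <- run_langevin(pot, s)
  expect_identical(un$x, un2$x)
})

test_that("reweighting identities and the quadrature cross-check", {
  expect_equal(reweight(c(1, 2, 3, 4), rep(0, 4), kT = 1), 2.5)
  # two samples with deltaV = {0, kT ln 2} weight 1:2
  expect_equal(reweight(c(0, 1), c(0, log(2)), kT = 1), 2 / 3, tolerance = 1e-12)
  expect_error(reweight(1:3, 1:2), "length mismatch")
  expect_error(reweight(1:3, c(0, -1, 0)), ">= 0")

  # asymmetric double well: reweighted occupancy ratio within 20% of the
  # Boltzmann ratio from direct quadrature
  pot <- toy_potential("tilted_double_well", h = 3, s = 0.5)
  st <- langevin_settings(n_steps = 5e5, dt = 0.01, seed = 5,
                          reduced_units = TRUE, sample_stride = 10)
  bo <- run_langevin(pot, st, amd = amd_params(E = 4, alpha = 1.5))
  w_left <- reweight(as.numeric(bo$x < 0), bo$deltaV, kT = 1)
  ratio <- w_left / (1 - w_left)
  exact <- stats::integrate(function(x) exp(-pot$V(x)), -4, 0)$value /
    stats::integrate(function(x) exp(-pot$V(x)), 0, 4)$value
  expect_equal(ratio, exact, tolerance = 0.2)
})

test_that("parameter estimation from an unbiased energy series", {
  set.seed(8)
  V <- rnorm(5000, mean = 20, sd = 3)
  p <- estimate_amd_params(V)
  expect_equal(p$E - mean(V), 4 * stats::sd(V), tolerance = 1e-12)
  expect_equal(p$alpha, stats::sd(V), tolerance = 1e-12)
  expect_gt(p$E, mean(V))

  # c1 = 0: boost active for roughly half of a symmetric distribution
  p0 <- estimate_amd_params(V, c1 = 0)
  expect_equal(mean(V < p0$E), 0.5, tolerance = 0.1)

  expect_error(estimate_amd_params(rep(5, 200)), "zero-variance")
  expect_error(estimate_amd_params(rnorm(50)), "100")
})

test_that("toy potentials: gradient matches central differences", {
  pots <- list(
    toy_potential("harmonic", k = 2),
    toy_potential("double_well", h = 6),
    toy_potential("tilted_double_well", h = 3, s = 0.5)
  )
  xs <- seq(-2, 2, by = 0.37)
  h <- 1e-6
  for (p in pots) {
    num <- (p$V(xs + h) - p$V(xs - h)) / (2 * h)
    expect_equal(p$grad(xs), num, tolerance = 1e-5)
  }
  expect_error(toy_potential("custom"), "needs V and grad")
})
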