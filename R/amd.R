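# Toy accelerated-MD: boost potential, Langevin (BAOAB) dynamics on toy
# potentials, exponential reweighting, boost-parameter estimation, and
# transition counting.
#
# Boost: for V < E, dV = (E - V)^2 / (alpha + E - V) and the force on the
# modified surface is the unbiased force scaled by
# alpha^2 / (alpha + E - V)^2; for V >= E the surface is untouched.  The
# modified potential is C1-continuous at V = E.

KB_KCAL <- 0.0019872041  # kcal/mol/K

#' Define a toy potential
#'
#' Presets: `"harmonic"` (V = 0.5 k x^2), `"double_well"`
#' (V = h (x^2 - 1)^2, barrier height h at x = 0), `"tilted_double_well"`
#' (double well plus s * x).  Custom potentials pass `V` and `grad`.
#'
#' @param preset preset name, or `"custom"`.
#' @param h barrier height (kcal/mol or kT in reduced units).
#' @param k harmonic spring constant.
#' @param s linear tilt of the tilted double well.
#' @param V,grad functions of position (custom only).
#' @return Object of class `ToyPotential` with `V(x)` and `grad(x)`.
#' @export
toy_potential <- function(preset = c("double_well", "harmonic",
                                     "tilted_double_well", "custom"),
                          h = 6, k = 1, s = 0.5, V = NULL, grad = NULL) {
  preset <- match.arg(preset)
  pot <- switch(preset,
    harmonic = list(
      V = function(x) 0.5 * k * x^2,
      grad = function(x) k * x
    ),
    double_well = list(
      V = function(x) h * (x^2 - 1)^2,
      grad = function(x) 4 * h * x * (x^2 - 1)
    ),
    tilted_double_well = list(
      V = function(x) h * (x^2 - 1)^2 + s * x,
      grad = function(x) 4 * h * x * (x^2 - 1) + s
    ),
    custom = {
      if (is.null(V) || is.null(grad)) stop("custom potential needs V and grad")
      list(V = V, grad = grad)
    }
  )
  structure(c(pot, list(preset = preset, h = h, k = k, s = s)),
            class = "ToyPotential")
}

#' Accelerated-MD boost
#'
#' @param V_value potential energy (scalar or vector).
#' @param params list/`AMDParams` with `E` (threshold) and `alpha` (> 0).
#' @return list: `deltaV` (>= 0) and `force_scale` in (0, 1].
#' @export
amd_boost <- function(V_value, params) {
  if (params$alpha <= 0) stop("alpha must be > 0")
  u <- params$E - V_value
  below <- u > 0
  deltaV <- ifelse(below, u^2 / (params$alpha + u), 0)
  force_scale <- ifelse(below, params$alpha^2 / (params$alpha + u)^2, 1)
  list(deltaV = deltaV, force_scale = force_scale)
}

#' AMD parameters
#'
#' @param E boost threshold energy.
#' @param alpha boost smoothing parameter (> 0).
#' @return Object of class `AMDParams`.
#' @export
amd_params <- function(E, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(E = E, alpha = alpha), class = "AMDParams")
}

#' Langevin settings
#'
#' @param temperature_K temperature (default 300 K); ignored when
#'   `reduced_units` (then kT = 1).
#' @param dt time step (default 0.002, a 2 fs analog in model time units).
#' @param friction friction coefficient (1/time, default 1).
#' @param mass particle mass (default 1).
#' @param n_steps number of integration steps.
#' @param seed RNG seed.
#' @param reduced_units when TRUE, kT = 1 (cleaner analytic checks).
#' @param sample_stride record every n-th step (default 10).
#' @return Object of class `LangevinSettings`.
#' @export
langevin_settings <- function(temperature_K = 300, dt = 0.002, friction = 1,
                              mass = 1, n_steps = 10000L, seed = 1L,
                              reduced_units = FALSE, sample_stride = 10L) {
  if (dt <= 0) stop("dt must be > 0")
  if (temperature_K <= 0) stop("temperature must be > 0")
  structure(
    list(temperature_K = temperature_K, dt = dt, friction = friction,
         mass = mass, n_steps = as.integer(n_steps), seed = as.integer(seed),
         reduced_units = reduced_units,
         sample_stride = as.integer(sample_stride)),
    class = "LangevinSettings"
  )
}

kT_of <- function(settings) {
  if (settings$reduced_units) 1 else KB_KCAL * settings$temperature_K
}

#' Run Langevin dynamics on a toy potential
#'
#' BAOAB discretisation; initial velocity drawn from the Maxwell-Boltzmann
#' distribution at the target temperature; deterministic given the seed.
#' With `amd` set, forces are scaled by the boost force scale each step and
#' the boost deltaV is recorded for reweighting.
#'
#' @param potential a [toy_potential()].
#' @param settings a [langevin_settings()].
#' @param amd an [amd_params()] or NULL (unbiased).
#' @param x0 initial position (default -1, the left well of the presets).
#' @return data.frame: `step`, `x`, `V`, `deltaV` (sampled every
#'   `sample_stride` steps).
#' @export
run_langevin <- function(potential, settings, amd = NULL, x0 = -1) {
  set.seed(settings$seed)
  kT <- kT_of(settings)
  m <- settings$mass
  dt <- settings$dt
  c1 <- exp(-settings$friction * dt)
  c2 <- sqrt((1 - c1^2) * kT / m)
  x <- x0
  v <- stats::rnorm(1L, 0, sqrt(kT / m))
  n <- settings$n_steps
  stride <- settings$sample_stride
  n_out <- n %/% stride
  out_x <- numeric(n_out); out_V <- numeric(n_out); out_dV <- numeric(n_out)
  out_step <- integer(n_out)
  Vfun <- potential$V; Gfun <- potential$grad
  force_at <- function(x) {
    g <- Gfun(x)
    if (is.null(amd)) return(list(f = -g, dV = 0))
    u <- amd$E - Vfun(x)
    if (u <= 0) return(list(f = -g, dV = 0))
    sc <- amd$alpha^2 / (amd$alpha + u)^2
    list(f = -g * sc, dV = u^2 / (amd$alpha + u))
  }
  fa <- force_at(x)
  noise <- stats::rnorm(n)
  j <- 0L
  for (i in seq_len(n)) {
    v <- v + 0.5 * dt * fa$f / m
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * noise[i]
    x <- x + 0.5 * dt * v
    fa <- force_at(x)
    v <- v + 0.5 * dt * fa$f / m
    if (!is.finite(x) || abs(x) > 1e6) {
      stop("trajectory diverged; use a smaller dt")
    }
    if (i %% stride == 0L) {
      j <- j + 1L
      out_step[j] <- i; out_x[j] <- x
      out_V[j] <- Vfun(x); out_dV[j] <- fa$dV
    }
  }
  data.frame(step = out_step, x = out_x, V = out_V, deltaV = out_dV)
}

#' Exponential reweighting of boosted samples
#'
#' Canonical average <A> = sum(A_i w_i) / sum(w_i) with
#' w_i = exp(deltaV_i / kT), max-shifted against overflow.  Unbiased input
#' (all deltaV zero) returns the plain mean.
#'
#' @param observable numeric vector.
#' @param deltaV boost energies (>= 0), same length.
#' @param kT thermal energy (use 1 in reduced units, or
#'   0.0019872041 * T in kcal/mol).
#' @return Weighted average.
#' @export
reweight <- function(observable, deltaV, kT = 1) {
  if (length(observable) != length(deltaV)) stop("length mismatch")
  if (any(deltaV < -1e-12)) stop("deltaV must be >= 0")
  w <- exp((deltaV - max(deltaV)) / kT)
  sum(observable * w) / sum(w)
}

#' Estimate boost parameters from an unbiased potential-energy series
#'
#' E = <V> + c1 * sd(V), alpha = c2 * sd(V); defaults c1 = 4, c2 = 1.
#'
#' @param V_series unbiased potential-energy samples (length >= 100).
#' @param c1,c2 estimator constants.
#' @return An [amd_params()].
#' @export
estimate_amd_params <- function(V_series, c1 = 4, c2 = 1) {
  if (length(V_series) < 100L) stop("need at least 100 samples")
  s <- stats::sd(V_series)
  if (s < 1e-12) stop("zero-variance potential-energy series")
  amd_params(E = mean(V_series) + c1 * s, alpha = c2 * s)
}

#' Count well-to-well transitions of a 1-D trajectory
#'
#' Hysteresis counter: a transition is recorded each time the position
#' crosses from below `lo` to above `hi` or vice versa.
#'
#' @param x positions.
#' @param lo,hi hysteresis bounds (defaults -0.5, 0.5 for the +/-1 wells).
#' @return Integer transition count.
#' @export
count_transitions <- function(x, lo = -0.5, hi = 0.5) {
  state <- 0L  # -1 left, +1 right, 0 undecided
  n_trans <- 0L
  for (xi in x) {
    s <- if (xi < lo) -1L else if (xi > hi) 1L else 0L
    if (s != 0L) {
      if (state != 0L && s != state) n_trans <- n_trans + 1L
      state <- s
    }
  }
  n_trans
}
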