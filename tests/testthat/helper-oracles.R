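# Independent oracles used across the suite.  These stay deliberately
# separate from the package implementations they check.

# ---- Shrake-Rupley numerical SASA (golden-spiral quadrature) -------------
sr_sasa <- function(xyz, radii, probe = 1.4, n_pts = 1000) {
  R <- radii + probe
  n <- nrow(xyz)
  k <- seq_len(n_pts)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * k - 1) / n_pts
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * k
  pts <- cbind(r * cos(th), r * sin(th), z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    P <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_pts)
    for (j in seq_len(n)) {
      if (j == i) next
      free <- free & rowSums(sweep(P, 2, xyz[j, ])^2) > R[j]^2
    }
    out[i] <- mean(free) * 4 * pi * R[i]^2
  }
  out
}

# radii the package's LCPO classes assign (needed so the oracle integrates
# the same spheres)
lcpo_class_radii <- function(xyz, top) {
  cls <- ckitraj:::lcpo_atom_classes(xyz, top, lcpo_params())
  list(heavy = cls$heavy, radii = lcpo_params()$table$radius[cls$rows])
}

# ---- brute-force rigid-body RMSD via quaternion parametrisation ----------
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

brute_force_rmsd <- function(mobile, reference, n_starts = 12) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    rot <- quat_to_rot(q)
    sqrt(mean(rowSums((M %*% t(rot) - R)^2)))
  }
  best <- Inf
  set.seed(1234)
  starts <- rbind(diag(4), matrix(rnorm(4 * n_starts), ncol = 4))
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 500))
    best <- min(best, o$value)
  }
  best
}

# ---- frozen reference DSSP (MDAnalysis 2.10 / pydssp, 3-state) -----------
# Structures are rebuilt deterministically by build_dssp_testset(); the
# strings below were produced by running the reference implementation on
# the identical PDB files and are frozen here.  Codes: H (any helix),
# E (strand), '-' (everything else).
build_dssp_testset <- function() {
  list(
    alpha12 = backbone_trajectory(-57, -47, 12),
    g310_12 = backbone_trajectory(-49, -26, 12),
    mixed20 = backbone_trajectory(c(rep(-57, 8), -80, 80, rep(-57, 10)),
                                  c(rep(-47, 8), 100, 30, rep(-47, 10)), 20),
    pp_ext = backbone_trajectory(-140, 135, 12),
    hairpin = backbone_trajectory(c(rep(-130, 6), 60, 90, rep(-130, 6)),
                                  c(rep(135, 6), 30, 0, rep(135, 6)), 14)
  )
}

dssp_reference_3state <- c(
  alpha12 = "-HHHHHHHHHH-",
  g310_12 = "-HHHHHHHHHH-",
  mixed20 = "-HHHHHHH--HHHHHHHHH-",
  pp_ext = "------------",
  hairpin = "----EE--EE----"
)

dssp_to_3state <- function(ss) {
  out <- rep("-", length(ss))
  out[ss %in% c("H", "G", "I")] <- "H"
  out[ss %in% c("E", "B")] <- "E"
  paste(out, collapse = "")
}

# ---- misc ---------------------------------------------------------------
# random rigid transform
random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  list(rot = quat_to_rot(q), trans = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, rigid) {
  sweep(xyz %*% t(rigid$rot), 2, rigid$trans, `+`)
}

# clash-free random tetrapeptide cluster (20 heavy atoms) for SASA checks
random_peptide_cluster <- function(seed) {
  set.seed(seed)
  for (k in 1:200) {
    phi <- runif(4, -170, -40)
    psi <- runif(4, -70, 170)
    tr <- backbone_trajectory(phi, psi, 4, with_h = FALSE, with_cb = TRUE)
    xyz <- frame_coords(tr, 1)
    res <- tr$topology$atoms$resid
    D <- as.matrix(stats::dist(xyz))
    sep <- abs(outer(res, res, "-")) >= 2
    if (min(D[sep]) >= 3.0) return(tr)
  }
  stop("no clash-free conformation found")
}
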