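# Shared fixture builders (used by unit and acceptance tests alike).

# one donor (N + H) and one acceptor (O): N at the origin, H at (1,0,0),
# acceptor placed so that |N-A| = dist and the D-H-A angle is `ang` deg
hb_pair_frame <- function(dist, ang) {
  top <- topology(data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    resname = c("GLY", "GLY", "SER"), resid = c(1L, 1L, 2L),
    chain = c("A", "A", "B"), stringsAsFactors = FALSE
  ))
  u <- c(-cos(ang * pi / 180), sin(ang * pi / 180), 0)
  tpos <- -u[1] + sqrt(u[1]^2 - 1 + dist^2)
  A <- c(1, 0, 0) + tpos * u
  stopifnot(abs(sqrt(sum(A^2)) - dist) < 1e-9)
  list(top = top, xyz = rbind(c(0, 0, 0), c(1, 0, 0), A))
}

# generated fixture + matching JSON config for pipeline runs
write_run_inputs <- function(n_frames = 60, eject = 45L, seed = 9,
                             dir = tempfile()) {
  gen <- make_toy_trimer(
    toy_trimer_config(n_frames = n_frames, helix_fraction = 1,
                      ejection_frame = eject),
    seed = seed
  )
  files <- write_fixture(gen$trajectory, gen$manifest, dir)
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    input = files[["pdb"]], params = files[["params"]],
    equilibration_drop_ns = 1,
    cv = list(helix_selection = gen$manifest$selections$helix_segment,
              pocket_selection = gen$manifest$selections$pocket,
              delta_A = 5, sustain_ns = 1, baseline_window_ns = 2)
  ), cfg, auto_unbox = TRUE)
  list(gen = gen, files = files, cfg = cfg)
}

# lifetime fractions the analysis window should see, from the manifest
manifest_window_fractions <- function(gen, drop_ns) {
  keep <- gen$trajectory$times_ns >= drop_ns
  vapply(gen$manifest$contact_schedules, function(m) mean(m[keep]), 0)
}
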