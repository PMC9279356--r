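# PDB reading/writing (ATOM/HETATM/MODEL/ENDMDL/TER) and parameter tables.
#
# Multi-model files become multi-frame trajectories sharing one Topology.
# The time mapping comes from the caller (PDB has no time field).  Alternate
# locations other than 'A'/blank are dropped; PTR/TPO residue names are
# aliased to Y2P/T2P.

guess_element <- function(name, resname) {
  # PDB element column may be absent; fall back on the atom-name convention.
  nm <- gsub("[0-9' ]", "", name)
  first2 <- toupper(substr(nm, 1, 2))
  if (first2 %in% c("CL", "BR", "MG", "ZN", "FE", "SE", "NA", "CA")) {
    # two-letter elements only when the residue is an ion of the same name
    if (toupper(resname) == first2) return(first2)
  }
  toupper(substr(nm, 1, 1))
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' A single-model file yields a one-frame trajectory; a file with n
#' MODEL/ENDMDL blocks yields n frames sharing one topology, with frame i
#' mapped to time (i - 1) * `frame_interval_ns`.  Atom order must be
#' identical across models.
#'
#' @param path PDB file path.
#' @param frame_interval_ns nanoseconds between successive models.  The save
#'   interval of a production run is not recorded in PDB, so it must be
#'   supplied; 0.1 ns/frame is the package default elsewhere.
#' @return A [trajectory()].
#' @export
read_structure <- function(path, frame_interval_ns = 0.1) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")

  n_models <- sum(is_model)
  # assign a model index to every line
  model_of <- cumsum(is_model)
  if (n_models == 0L) model_of <- rep(1L, length(lines))

  parse_block <- function(lidx, model_label) {
    n <- length(lidx)
    serial <- integer(n); name <- character(n); altloc <- character(n)
    resname <- character(n); chain <- character(n); resid <- integer(n)
    x <- numeric(n); y <- numeric(n); z <- numeric(n); element <- character(n)
    keep <- logical(n)
    for (k in seq_len(n)) {
      ln <- lines[lidx[k]]
      if (nchar(ln) < 54) {
        stop(sprintf("unparseable ATOM record at line %d (too short)", lidx[k]))
      }
      xs <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      ys <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      zs <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      sn <- suppressWarnings(as.integer(substr(ln, 7, 11)))
      rs <- suppressWarnings(as.integer(substr(ln, 23, 26)))
      if (is.na(xs) || is.na(ys) || is.na(zs) || is.na(sn) || is.na(rs)) {
        stop(sprintf("unparseable ATOM record at line %d", lidx[k]))
      }
      al <- substr(ln, 17, 17)
      keep[k] <- al %in% c(" ", "A", "")
      serial[k] <- sn
      name[k] <- trimws(substr(ln, 13, 16))
      altloc[k] <- al
      rn <- trimws(substr(ln, 18, 20))
      if (rn %in% names(PHOSPHO_ALIASES)) rn <- PHOSPHO_ALIASES[[rn]]
      resname[k] <- rn
      chain[k] <- substr(ln, 22, 22)
      resid[k] <- rs
      x[k] <- xs; y[k] <- ys; z[k] <- zs
      el <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
      element[k] <- if (nzchar(el)) toupper(el) else guess_element(name[k], resname[k])
    }
    n_drop <- sum(!keep)
    if (n_drop > 0L) {
      message(sprintf("read_structure: dropped %d altloc record(s) in model %s",
                      n_drop, model_label))
    }
    list(
      atoms = data.frame(
        serial = serial[keep], name = name[keep], element = element[keep],
        resname = resname[keep], resid = resid[keep], chain = chain[keep],
        stringsAsFactors = FALSE
      ),
      coords = cbind(x[keep], y[keep], z[keep])
    )
  }

  model_ids <- sort(unique(model_of[is_atom]))
  blocks <- lapply(model_ids, function(m) {
    parse_block(which(is_atom & model_of == m), as.character(m))
  })
  if (length(blocks) == 0L) stop("no ATOM/HETATM records in ", path)

  na0 <- nrow(blocks[[1]]$atoms)
  for (b in seq_along(blocks)) {
    if (nrow(blocks[[b]]$atoms) != na0) {
      stop(sprintf(
        "inconsistent atom count in model %d: %d atoms, expected %d",
        b, nrow(blocks[[b]]$atoms), na0
      ))
    }
  }
  top <- topology(blocks[[1]]$atoms)
  coords <- array(0, dim = c(na0, 3L, length(blocks)))
  for (b in seq_along(blocks)) coords[, , b] <- blocks[[b]]$coords
  trajectory(top, coords, frame_interval_ns = frame_interval_ns)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' One MODEL/ENDMDL block per frame, TER records between chains;
#' coordinates at PDB precision (1e-3 Angstrom).  Output is byte-stable for
#' identical input.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path) {
  top <- traj$topology
  at <- top$atoms
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- nf > 1L
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    out <- character(nrow(at) + length(top$chains))
    j <- 0L
    for (i in seq_len(nrow(at))) {
      j <- j + 1L
      nm <- at$name[i]
      # PDB atom-name alignment: 1-3 char names start in column 14
      nm_fmt <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      out[j] <- sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        at$serial[i] %% 100000L, nm_fmt, substr(at$resname[i], 1, 3),
        at$chain[i], at$resid[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
        1.0, 0.0, substr(at$element[i], 1, 2)
      )
      last_of_chain <- i == nrow(at) || at$chain[i + 1L] != at$chain[i]
      if (last_of_chain) {
        j <- j + 1L
        out[j] <- sprintf("TER   %5d      %-3s %1s%4d",
                          (at$serial[i] + 1L) %% 100000L,
                          substr(at$resname[i], 1, 3), at$chain[i], at$resid[i])
      }
    }
    writeLines(out[seq_len(j)], con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a per-atom parameter table
#'
#' Header-bearing TSV with columns `residue_name`, `atom_name`, `charge`,
#' `lj_sigma`, `lj_epsilon`, `radius`.  A row with residue_name `*` and
#' atom_name `*` is the default row for unmatched atoms.
#'
#' @param path TSV file path.
#' @return data.frame of parameter rows.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("residue_name", "atom_name", "charge", "lj_sigma", "lj_epsilon", "radius")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) stop("parameter table lacks columns: ", paste(miss, collapse = ", "))
  tab
}

#' Attach per-atom parameters to a topology
#'
#' Stands in for force-field assignment: each atom is matched on
#' (residue_name, atom_name); unmatched atoms receive the default row
#' (`*`/`*`) when present, otherwise an error lists the offenders.
#'
#' @param top a [topology()].
#' @param table data.frame from [read_parameter_table()] or built in code.
#' @return The topology with `charge`, `lj_sigma`, `lj_epsilon`, `radius`
#'   populated.
#' @export
attach_parameters <- function(top, table) {
  at <- top$atoms
  key_tab <- paste(table$residue_name, table$atom_name, sep = "/")
  key_atoms <- paste(at$resname, at$name, sep = "/")
  hit <- match(key_atoms, key_tab)
  default_row <- which(table$residue_name == "*" & table$atom_name == "*")
  unmatched <- which(is.na(hit))
  if (length(unmatched) > 0L) {
    if (length(default_row) == 0L) {
      stop("no parameters and no default row for atoms: ",
           paste(unique(key_atoms[unmatched]), collapse = ", "))
    }
    message(sprintf("attach_parameters: %d atom(s) received default parameters",
                    length(unmatched)))
    hit[unmatched] <- default_row[1]
  }
  at$charge <- as.numeric(table$charge[hit])
  at$lj_sigma <- as.numeric(table$lj_sigma[hit])
  at$lj_epsilon <- as.numeric(table$lj_epsilon[hit])
  at$radius <- as.numeric(table$radius[hit])
  top$atoms <- at
  top
}
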