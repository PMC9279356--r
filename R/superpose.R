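# Kabsch best-fit superposition, C-alpha RMSD time series, and
# equilibration trimming.

#' Kabsch best-fit superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` (uniform weights).  The sign of the smallest
#' singular value is corrected so the rotation has determinant +1 and
#' chirality is preserved.
#'
#' @param mobile N x 3 coordinate matrix (Angstrom).
#' @param reference N x 3 coordinate matrix, same N.
#' @return list with `rotation` (3 x 3, applied on the right of centred row
#'   vectors), `translation` (3-vector), `rmsd` (Angstrom).  The aligned
#'   mobile is `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be N x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  # collinear point sets leave the rotation about the axis undetermined
  sv_m <- svd(M, nu = 0, nv = 0)$d
  if (sv_m[2] <= 1e-8 * max(sv_m[1], 1e-12)) {
    stop("degenerate configuration: point set is rank-deficient (collinear)")
  }
  C <- crossprod(M, R)                      # 3x3 covariance
  sv <- svd(C)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  D <- diag(c(1, 1, s))
  rot <- sv$u %*% D %*% t(sv$v)             # M %*% rot ~ R
  aligned <- M %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - R)^2)))
  list(
    rotation = rot,
    translation = as.numeric(cr - cm %*% rot),
    rmsd = rmsd
  )
}

#' Best-fit RMSD time series
#'
#' Computes the best-fit RMSD of each frame to a reference frame, after
#' Kabsch superposition.  Fitting and reporting selections may differ: the
#' rigid transform is found on `fit_sel` and the RMSD reported on `sel`
#' (default: fit = report, i.e. the selection is superposed on itself).
#'
#' @param traj a [trajectory()].
#' @param sel selection whose RMSD is reported (default all C-alpha atoms).
#' @param reference_frame 1-based frame index of the reference
#'   (default 1, the starting structure).
#' @param fit_sel selection used to find the superposition
#'   (default: same as `sel`).
#' @return Object of class `RMSDSeries`: data.frame-like list with
#'   `times_ns`, `values_A`, plus the selections and reference index.
#' @export
rmsd_series <- function(traj, sel = "name CA", reference_frame = 1L,
                        fit_sel = NULL) {
  top <- traj$topology
  idx <- resolve_selection(top, sel)
  if (length(idx) == 0L) stop("empty selection for RMSD")
  fit_idx <- if (is.null(fit_sel)) idx else resolve_selection(top, fit_sel)
  if (length(fit_idx) == 0L) stop("empty fit selection for RMSD")
  if (reference_frame < 1L || reference_frame > n_frames(traj)) {
    stop("reference_frame out of range")
  }
  ref <- frame_coords(traj, reference_frame)
  ref_fit <- ref[fit_idx, , drop = FALSE]
  ref_rep <- ref[idx, , drop = FALSE]
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(xyz[fit_idx, , drop = FALSE], ref_fit)
    moved <- xyz[idx, , drop = FALSE] %*% fit$rotation
    moved <- sweep(moved, 2, fit$translation, `+`)
    vals[f] <- sqrt(mean(rowSums((moved - ref_rep)^2)))
  }
  structure(
    list(
      times_ns = traj$times_ns, values_A = vals,
      selection = if (is.character(sel)) sel else sel$expression,
      reference_frame = as.integer(reference_frame)
    ),
    class = "RMSDSeries"
  )
}

#' Drop the equilibration phase of a time series
#'
#' Retains samples with time >= `drop_ns`.  All time-averaged statistics in
#' the pipeline consume trimmed series; the default 25 ns mirrors the
#' conservative equilibration period used for trimer production runs.
#'
#' @param x an `RMSDSeries`, `CVSeries`, `SASASeries`, or a data.frame with
#'   a `time_ns` (or `times_ns`) column.
#' @param drop_ns nanoseconds to drop from the start (default 25).
#' @return The same type of object, trimmed.
#' @export
trim_equilibration <- function(x, drop_ns = 25) {
  if (drop_ns < 0) stop("drop_ns must be >= 0")
  UseMethod("trim_equilibration")
}

trim_series_fields <- function(x, drop_ns, time_field = "times_ns") {
  keep <- x[[time_field]] >= drop_ns
  if (!any(keep)) stop("empty analysis window: drop_ns >= series span")
  len <- length(x[[time_field]])
  for (fld in names(x)) {
    if (is.atomic(x[[fld]]) && length(x[[fld]]) == len && fld != "selection") {
      x[[fld]] <- x[[fld]][keep]
    }
  }
  x
}

#' @export
trim_equilibration.RMSDSeries <- function(x, drop_ns = 25) {
  trim_series_fields(x, drop_ns)
}

#' @export
trim_equilibration.CVSeries <- function(x, drop_ns = 25) {
  trim_series_fields(x, drop_ns)
}

#' @export
trim_equilibration.SASASeries <- function(x, drop_ns = 25) {
  trim_series_fields(x, drop_ns)
}

#' @export
trim_equilibration.data.frame <- function(x, drop_ns = 25) {
  tf <- intersect(c("time_ns", "times_ns"), names(x))
  if (length(tf) == 0L) stop("data.frame needs a time_ns column")
  keep <- x[[tf[1]]] >= drop_ns
  if (!any(keep)) stop("empty analysis window: drop_ns >= series span")
  x[keep, , drop = FALSE]
}

#' @export
trim_equilibration.default <- function(x, drop_ns = 25) {
  stop("no trim_equilibration method for class ", paste(class(x), collapse = "/"))
}

#' Write a time series as TSV
#'
#' @param x an object with `times_ns` and `values_A` fields.
#' @param path output path.
#' @param value_name column name for the values (default `rmsd_A`).
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(x, path, value_name = "rmsd_A") {
  df <- data.frame(time_ns = x$times_ns, value = x$values_A)
  names(df)[2] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
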