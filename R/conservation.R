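# Alignment-based conservation of phospho-site-equivalent positions and
# S/T-P motif scanning across Cip/Kip orthologs.  Alignments are consumed,
# never computed: the module reads a pre-built aligned FASTA (optionally
# with a clade-label TSV) and reports presence/absence of a residue at the
# column mapped from a reference position.

#' Read an aligned FASTA as an AlignedSet
#'
#' @param path aligned FASTA (all rows equal length, '-' gaps).
#' @return Object of class `AlignedSet`: named character vector of gapped
#'   sequences.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  aligned_set(stats::setNames(as.character(ss), names(ss)))
}

#' Construct an AlignedSet from named sequences
#'
#' @param sequences named character vector of gapped sequences.
#' @return Object of class `AlignedSet`.
#' @export
aligned_set <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(sequences))) stop("sequence ids must be unique")
  w <- nchar(sequences)
  if (length(unique(w)) != 1L) stop("aligned sequences must have equal length")
  structure(toupper(sequences), class = "AlignedSet")
}

#' Map an ungapped reference position to an alignment column
#'
#' @param aln an `AlignedSet`.
#' @param ref_id id of the reference row.
#' @param ref_pos 1-based position in the ungapped reference sequence.
#' @return 1-based alignment column index.
#' @export
map_reference_position <- function(aln, ref_id, ref_pos) {
  if (!ref_id %in% names(aln)) stop("unknown reference id: ", ref_id)
  row <- strsplit(unclass(aln)[[ref_id]], "")[[1]]
  ungapped <- cumsum(row != "-")
  if (ref_pos < 1L || ref_pos > max(ungapped)) {
    stop(sprintf("position %d beyond ungapped length %d", ref_pos, max(ungapped)))
  }
  which(ungapped == ref_pos & row != "-")[1]
}

#' Residue presence at an alignment column
#'
#' @param aln an `AlignedSet`.
#' @param column 1-based alignment column.
#' @param residue single-letter residue to test (default "Y"); gaps count
#'   as absent.
#' @return list: `present` (named logical per sequence), `fraction`.
#' @export
site_presence <- function(aln, column, residue = "Y") {
  w <- nchar(unclass(aln)[[1]])
  if (column < 1L || column > w) stop("column out of range")
  obs <- substr(unclass(aln), column, column)
  present <- stats::setNames(obs == toupper(residue), names(aln))
  list(present = present, observed = stats::setNames(obs, names(aln)),
       fraction = mean(present))
}

#' Scan a sequence for S/T-P motifs
#'
#' Reports every position i (1-based) where the residue is S or T and the
#' next residue is P -- the minimal proline-directed kinase consensus.
#'
#' @param sequence ungapped amino-acid sequence.
#' @return Integer vector of 1-based S/T positions (possibly empty).
#' @export
stp_motif_scan <- function(sequence) {
  s <- toupper(gsub("-", "", sequence))
  hits <- gregexpr("(?=[ST]P)", s, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

#' Site-conservation report across an alignment
#'
#' Maps reference positions to columns, tests residue presence per
#' sequence, and merges optional clade labels.
#'
#' @param aln an `AlignedSet`.
#' @param ref_id reference sequence id.
#' @param sites data.frame with `label`, `ref_pos`, `residue`.
#' @param clades optional data.frame with `seq_id`, `clade`.
#' @return data.frame: seq_id, clade, site_label, column,
#'   residue_expected, residue_observed, present.
#' @export
conservation_report <- function(aln, ref_id, sites, clades = NULL) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    col <- map_reference_position(aln, ref_id, sites$ref_pos[i])
    sp <- site_presence(aln, col, sites$residue[i])
    rows[[i]] <- data.frame(
      seq_id = names(aln),
      site_label = sites$label[i],
      column = col,
      residue_expected = sites$residue[i],
      residue_observed = unname(sp$observed),
      present = as.integer(unname(sp$present)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$clade <- if (is.null(clades)) NA_character_ else {
    clades$clade[match(out$seq_id, clades$seq_id)]
  }
  out[, c("seq_id", "clade", "site_label", "column", "residue_expected",
          "residue_observed", "present")]
}
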