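#' In silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to K or R, except when the
#' following residue is proline, and returns every peptide containing up
#' to \code{max_missed_cleavages} internal missed cleavage sites, within
#' the requested length window.  Duplicate peptide sequences (possible
#' when a protein contains sequence repeats) are removed.
#'
#' @param sequence single uppercase amino-acid string.
#' @param max_missed_cleavages maximum internal missed cleavage sites.
#' @param min_len,max_len peptide length window (inclusive).
#' @param alphabet allowed residue characters; residues outside it are
#'   rejected.  Defaults to the 20 standard amino acids.
#' @return character vector of unique peptides, in order of first
#'   occurrence along the sequence.
#' @examples
#' tryptic_digest("MKWVTFISLLFR", 0, min_len = 1, max_len = 30)
#' @export
tryptic_digest <- function(sequence, max_missed_cleavages = DIGEST_MISSED,
                           min_len = DIGEST_MIN_LEN,
                           max_len = DIGEST_MAX_LEN,
                           alphabet = "ACDEFGHIKLMNPQRSTVWY") {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (max_missed_cleavages < 0L) stopf("max_missed_cleavages must be >= 0")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(res) == 0L) return(character())
  ok <- strsplit(alphabet, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), ok)
  if (length(bad))
    stopf("invalid residue character(s): %s", paste(bad, collapse = ", "))
  n <- length(res)
  # cleavage after position i: K/R at i, not followed by P, not terminal
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  # fully cleaved fragments delimited by the cut sites
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nfrag <- length(starts)
  peps <- character(0)
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      len <- ends[j] - starts[i] + 1L
      if (len >= min_len && len <= max_len)
        peps <- c(peps, substr(sequence, starts[i], ends[j]))
    }
  }
  unique(peps)
}

#' Build a peptide-to-protein lookup over a protein database
#'
#' Digests every database sequence (targets, decoys and host alike) and
#' indexes which accessions yield each tryptic peptide.  The index is the
#' ground truth for "which proteins could this peptide have come from",
#' used both by the synthetic PSM sampler and by per-rank peptide
#' uniqueness.
#'
#' @param database a \code{protein_db} data.frame (see
#'   \code{\link{read_database}}).
#' @param max_missed_cleavages,min_len,max_len digestion parameters.
#' @return an environment mapping peptide -> character vector of
#'   accessions, with the digestion parameters stored as attributes.
#' @export
build_peptide_index <- function(database,
                                max_missed_cleavages = DIGEST_MISSED,
                                min_len = DIGEST_MIN_LEN,
                                max_len = DIGEST_MAX_LEN) {
  idx <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(29L, nrow(database) * 32L))
  for (i in seq_len(nrow(database))) {
    acc <- database$accession[i]
    for (p in tryptic_digest(database$sequence[i], max_missed_cleavages,
                             min_len, max_len)) {
      idx[[p]] <- c(idx[[p]], acc)
    }
  }
  attr(idx, "max_missed_cleavages") <- max_missed_cleavages
  attr(idx, "min_len") <- min_len
  attr(idx, "max_len") <- max_len
  idx
}

# accessions matching a peptide, or character(0)
index_lookup <- function(index, peptide) {
  v <- index[[peptide]]
  if (is.null(v)) character(0) else v
}
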