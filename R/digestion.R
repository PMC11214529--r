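#' @keywords internal
"_PACKAGE"

## The 20 standard amino-acid one-letter codes. Ambiguity codes (B, Z, X) and
## the rare translated residues (U, O) are rejected at load so that peptide
## indexing stays deterministic.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

TAXONOMIC_RANKS <- c(
  "kingdom", "phylum", "class", "order", "family", "genus", "species"
)

#' Validate a protein sequence
#'
#' Checks that a residue string uses only the 20 standard amino acids.
#'
#' @param sequence Character scalar, a protein sequence.
#' @return The sequence, invisibly, if valid.
#' @keywords internal
validate_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty character string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad) > 0L) {
    stop(
      "invalid residue(s) in sequence: ", paste(bad, collapse = ", "),
      " (only the 20 standard amino acids are accepted)",
      call. = FALSE
    )
  }
  invisible(sequence)
}

#' Collapse isoleucine and leucine to a common symbol
#'
#' I and L are isobaric and indistinguishable by de novo sequencing; for de
#' novo peptide matching both are mapped to "J".
#'
#' @param peptides Character vector of peptide sequences.
#' @return Character vector with every I and L replaced by J.
#' @export
collapse_il <- function(peptides) {
  chartr("IL", "JJ", peptides)
}

#' In-silico tryptic digestion of a protein
#'
#' Cleaves C-terminal to lysine (K) or arginine (R). Under the classic
#' `"trypsin"` rule no cleavage occurs when the following residue is proline;
#' the `"trypsin/p"` rule cleaves regardless. Products carrying up to
#' `missed_cleavages` internal cleavage sites are emitted, filtered to the
#' observable tryptic length range.
#'
#' @param sequence Protein sequence (standard residues only).
#' @param missed_cleavages Maximum number of missed cleavage sites per
#'   peptide. Default 1, the value used for the database searches this
#'   workflow consumes.
#' @param min_length Minimum peptide length retained (default 7 residues).
#' @param max_length Maximum peptide length retained (default 40).
#' @param rule Cleavage rule, `"trypsin"` (no cleavage before proline,
#'   default) or `"trypsin/p"`.
#' @return Character vector of peptides ordered by position in the protein
#'   (start position, then number of missed cleavages).
#' @examples
#' tryptic_digest("AAAAAAKGGGGGGR", missed_cleavages = 0)
#' tryptic_digest("AAKPGGGGR", missed_cleavages = 0, min_length = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 1L, min_length = 7L,
                           max_length = 40L, rule = c("trypsin", "trypsin/p")) {
  rule <- match.arg(rule)
  validate_residues(sequence)
  if (missed_cleavages < 0L || min_length < 1L || max_length < min_length) {
    stop("invalid digestion parameters", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  ## cleavage sites: after position i when chars[i] is K/R (and chars[i+1]
  ## is not P under the classic rule); position n never needs a cut
  is_kr <- chars %in% c("K", "R")
  if (rule == "trypsin") {
    next_is_p <- c(chars[-1L] == "P", FALSE)
    cut_after <- is_kr & !next_is_p
  } else {
    cut_after <- is_kr
  }
  sites <- which(cut_after[-n])  # internal cut positions

  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  n_frag <- length(starts)

  out <- character(0L)
  for (i in seq_len(n_frag)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n_frag) break
      len <- ends[j] - starts[i] + 1L
      if (len >= min_length && len <= max_length) {
        out <- c(out, substr(sequence, starts[i], ends[j]))
      }
    }
  }
  out
}
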