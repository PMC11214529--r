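## Independent brute-force oracles: these re-derive expected results by
## exhaustive enumeration, never by calling the implementation under test.

## Enumerate every substring window of `sequence` and accept it as a tryptic
## product iff its boundaries are valid cleavage points and it contains at
## most `mc` internal cleavage sites. Independent of tryptic_digest().
brute_digest <- function(sequence, mc = 1L, min_len = 7L, max_len = 40L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_site <- function(i) {
    # a cleavage point AFTER position i (classic rule: K/R not before P)
    i >= 1L && i < n && chars[i] %in% c("K", "R") && chars[i + 1L] != "P"
  }
  out <- character(0L)
  for (start in seq_len(n)) {
    if (!(start == 1L || is_site(start - 1L))) next
    for (end in start:n) {
      if (!(end == n || is_site(end))) next
      len <- end - start + 1L
      if (len < min_len || len > max_len) next
      internal <- sum(vapply(start:(end - 1L), is_site, logical(1L)))
      if (end == start) internal <- 0L
      if (internal <= mc) out <- c(out, substr(sequence, start, end))
    }
  }
  out
}

## Nested scan over all proteomes, proteins and digestion windows; returns
## the peptide -> (taxon, protein) occurrence set as a sorted data frame.
brute_index <- function(proteomes, mc = 1L, min_len = 7L, max_len = 40L,
                        il = FALSE) {
  rows <- list()
  for (p in proteomes) {
    for (pid in names(p$proteins)) {
      peps <- unique(brute_digest(p$proteins[[pid]], mc, min_len, max_len))
      if (il) peps <- chartr("IL", "JJ", peps)
      for (pep in unique(peps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, taxon_id = p$taxon_id, protein_id = pid,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- unique(do.call(rbind, rows))
  df[order(df$peptide, df$taxon_id, df$protein_id), , drop = FALSE]
}

## A tiny fixed proteome collection for deterministic unit fixtures.
toy_proteomes <- function() {
  lin <- function(g, s) c(
    kingdom = "Bacteria", phylum = "P1", class = "C1", order = "O1",
    family = "F1", genus = g, species = s
  )
  list(
    A = taxon_proteome("A", lin("GenX", "GenX alpha"),
                       c(pA1 = "AAAAAAKGGGGGGR", pA2 = "CCCCCCCKDDDDDDDR")),
    B = taxon_proteome("B", lin("GenX", "GenX beta"),
                       c(pB1 = "EEEEEEEKFFFFFFFR", pB2 = "CCCCCCCKDDDDDDDR")),
    C = taxon_proteome("C", lin("GenY", "GenY gamma"),
                       c(pC1 = "HHHHHHHKMMMMMMMR"))
  )
}

## Random proteome fixtures for oracle-equivalence sweeps.
random_fixture <- function(seed) {
  set.seed(seed)
  n_taxa <- sample(1:6, 1L)
  generate_taxon_proteomes(
    n_taxa = n_taxa,
    n_proteins_per_taxon = sample(3:10, 1L),
    length_distribution = list(mean = 120, sd = 30, min = 40),
    shared_fraction = sample(c(0, 0.2, 0.4), 1L),
    seed = seed
  )
}
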