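#' Construct a taxon-labeled proteome
#'
#' The unit of the reference database: a set of protein sequences carrying a
#' full ranked lineage (kingdom down to species).
#'
#' @param taxon_id Character scalar, a unique taxon identifier.
#' @param lineage Named character vector with entries for all seven ranks
#'   (`kingdom`, `phylum`, `class`, `order`, `family`, `genus`, `species`),
#'   each non-empty.
#' @param proteins Named character vector of protein sequences; names are
#'   protein ids. Sequences must use only the 20 standard residues.
#' @return An object of class `taxon_proteome`.
#' @export
taxon_proteome <- function(taxon_id, lineage, proteins) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L, nzchar(taxon_id))
  if (!all(TAXONOMIC_RANKS %in% names(lineage))) {
    stop("lineage must name all ranks: ",
         paste(TAXONOMIC_RANKS, collapse = ", "), call. = FALSE)
  }
  lineage <- lineage[TAXONOMIC_RANKS]
  if (any(is.na(lineage)) || any(!nzchar(lineage))) {
    stop("lineage ranks must be non-empty down to species", call. = FALSE)
  }
  if (length(proteins) == 0L || is.null(names(proteins)) ||
      any(!nzchar(names(proteins)))) {
    stop("`proteins` must be a named character vector of sequences",
         call. = FALSE)
  }
  for (s in proteins) validate_residues(s)
  structure(
    list(taxon_id = taxon_id, lineage = lineage, proteins = proteins),
    class = "taxon_proteome"
  )
}

#' @export
print.taxon_proteome <- function(x, ...) {
  cat("<taxon_proteome> ", x$taxon_id, " (", x$lineage[["species"]], "): ",
      length(x$proteins), " proteins\n", sep = "")
  invisible(x)
}

#' Lineage table of a proteome collection
#'
#' @param proteomes List of [taxon_proteome()] objects.
#' @return Tibble with one row per taxon and one column per rank.
#' @export
lineage_table <- function(proteomes) {
  stopifnot(length(proteomes) >= 1L)
  rows <- lapply(proteomes, function(p) {
    tibble::tibble(taxon_id = p$taxon_id, !!!as.list(p$lineage))
  })
  dplyr::bind_rows(rows)
}

#' Write taxon proteomes as FASTA
#'
#' One file per taxon, records headed `>taxonid|proteinid lineage=k;p;c;o;f;g;s`.
#'
#' @param proteomes List of [taxon_proteome()] objects.
#' @param dir Output directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
write_proteome_fasta <- function(proteomes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(proteomes, function(p) {
    path <- file.path(dir, paste0(p$taxon_id, ".fasta"))
    seqs <- Biostrings::AAStringSet(p$proteins)
    names(seqs) <- paste0(
      p$taxon_id, "|", names(p$proteins),
      " lineage=", paste(p$lineage, collapse = ";")
    )
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    path
  }, character(1L))
  invisible(paths)
}

#' Read taxon proteomes from FASTA
#'
#' Accepts the header dialect written by [write_proteome_fasta()]
#' (`>taxonid|proteinid lineage=k;p;c;o;f;g;s`), or arbitrary FASTA plus a
#' taxon map giving each file's taxon id and lineage.
#'
#' @param files Character vector of FASTA paths.
#' @param taxon_map Optional tibble with columns `file`, `taxon_id` and the
#'   seven rank columns; required when headers do not carry a lineage.
#' @return Named list of [taxon_proteome()] objects keyed by taxon id.
#' @export
read_proteome_fasta <- function(files, taxon_map = NULL) {
  out <- list()
  for (f in files) {
    seqs <- Biostrings::readAAStringSet(f)
    headers <- names(seqs)
    if (is.null(taxon_map)) {
      id_part <- sub("\\s.*$", "", headers)
      taxon_ids <- sub("\\|.*$", "", id_part)
      protein_ids <- sub("^[^|]*\\|", "", id_part)
      lin_part <- sub("^.*lineage=", "", headers)
      if (any(lin_part == headers)) {
        stop("FASTA headers in ", f, " carry no lineage=; supply `taxon_map`",
             call. = FALSE)
      }
      for (tid in unique(taxon_ids)) {
        sel <- taxon_ids == tid
        lin <- strsplit(lin_part[sel][1L], ";", fixed = TRUE)[[1L]]
        names(lin) <- TAXONOMIC_RANKS
        prot <- as.character(seqs[sel])
        names(prot) <- protein_ids[sel]
        out[[tid]] <- taxon_proteome(tid, lin, prot)
      }
    } else {
      row <- taxon_map[taxon_map$file == basename(f) | taxon_map$file == f, ]
      if (nrow(row) != 1L) {
        stop("`taxon_map` must have exactly one row for file ", f,
             call. = FALSE)
      }
      lin <- unlist(row[TAXONOMIC_RANKS])
      prot <- as.character(seqs)
      names(prot) <- sub("\\s.*$", "", headers)
      out[[row$taxon_id]] <- taxon_proteome(row$taxon_id, lin, prot)
    }
  }
  out
}
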