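#' Build the peptide-to-taxa index
#'
#' Digests every protein of every proteome in silico and records, for each
#' distinct peptide, all (taxon, protein) pairs producing it. The index is
#' the backbone of peptide uniqueness and of unique-peptide quantification.
#' Digestion parameters are frozen into the index and reused by every
#' consumer so that classification is always consistent with construction.
#'
#' @param proteomes List of [taxon_proteome()] objects (at least one);
#'   duplicate taxon ids are rejected.
#' @param missed_cleavages,min_length,max_length,rule Digestion parameters,
#'   see [tryptic_digest()].
#' @param il_collapse Logical; collapse I/L to a common symbol before
#'   indexing (appropriate for matching de novo peptides, where the two are
#'   indistinguishable). Default `FALSE` for closed-search quantification.
#' @return An object of class `peptide_index`: a list with `peptides` (tibble
#'   `peptide`, `taxon_id`, `protein_id`), `lineages` (tibble from
#'   [lineage_table()]) and `params`.
#' @export
build_peptide_index <- function(proteomes, missed_cleavages = 1L,
                                min_length = 7L, max_length = 40L,
                                rule = "trypsin", il_collapse = FALSE) {
  stopifnot(length(proteomes) >= 1L)
  ids <- vapply(proteomes, function(p) p$taxon_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate taxon ids in proteome collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", length(proteomes))
  for (i in seq_along(proteomes)) {
    p <- proteomes[[i]]
    per_prot <- lapply(names(p$proteins), function(pid) {
      peps <- tryptic_digest(p$proteins[[pid]], missed_cleavages,
                             min_length, max_length, rule)
      if (length(peps) == 0L) return(NULL)
      tibble::tibble(peptide = unique(peps), taxon_id = p$taxon_id,
                     protein_id = pid)
    })
    rows[[i]] <- dplyr::bind_rows(per_prot)
  }
  peptides <- dplyr::bind_rows(rows)
  if (nrow(peptides) > 0L && il_collapse) {
    peptides$peptide <- collapse_il(peptides$peptide)
    peptides <- dplyr::distinct(peptides)
  }
  structure(
    list(
      peptides = peptides,
      lineages = lineage_table(proteomes),
      params = list(missed_cleavages = missed_cleavages,
                    min_length = min_length, max_length = max_length,
                    rule = rule, il_collapse = il_collapse)
    ),
    class = "peptide_index"
  )
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("<peptide_index> ", dplyr::n_distinct(x$peptides$peptide),
      " distinct peptides over ", nrow(x$lineages), " taxa",
      " (missed cleavages ", x$params$missed_cleavages,
      ", length ", x$params$min_length, "-", x$params$max_length,
      ", I/L collapse ", x$params$il_collapse, ")\n", sep = "")
  invisible(x)
}

## map query peptides onto the index convention (I/L collapse if indexed so)
index_key <- function(index, peptides) {
  if (isTRUE(index$params$il_collapse)) collapse_il(peptides) else peptides
}

#' Classify peptide specificity at a taxonomic rank
#'
#' A peptide is *unique* at rank r when all its occurrences in the index
#' collapse to a single taxon label at that rank, *shared* when they span
#' several, and *unmatched* when it is absent from every digest.
#'
#' @param peptides Character vector of peptide sequences (collapsed
#'   automatically when the index was built with I/L collapse).
#' @param index A [build_peptide_index()] object.
#' @param rank Taxonomic rank, one of kingdom...species (default
#'   `"species"`, the rank used for community composition).
#' @return Tibble with columns `peptide`, `status`
#'   (`unique`/`shared`/`unmatched`) and `taxon` (the owning label at `rank`
#'   when unique, otherwise `NA`).
#' @export
classify_peptide_specificity <- function(peptides, index, rank = "species") {
  stopifnot(inherits(index, "peptide_index"))
  if (!rank %in% TAXONOMIC_RANKS) {
    stop("unknown rank: ", rank, " (expected one of ",
         paste(TAXONOMIC_RANKS, collapse = ", "), ")", call. = FALSE)
  }
  query <- tibble::tibble(
    peptide = peptides,
    .key = index_key(index, peptides)
  )
  lab <- index$lineages[, c("taxon_id", rank)]
  names(lab)[2L] <- ".label"
  occ <- dplyr::left_join(index$peptides, lab, by = "taxon_id")
  per_pep <- dplyr::summarise(
    dplyr::group_by(occ, .data$peptide),
    .n_labels = dplyr::n_distinct(.data$.label),
    .label = .data$.label[1L],
    .groups = "drop"
  )
  res <- dplyr::left_join(query, per_pep, by = c(".key" = "peptide"))
  tibble::tibble(
    peptide = res$peptide,
    status = dplyr::case_when(
      is.na(res$.n_labels) ~ "unmatched",
      res$.n_labels == 1L ~ "unique",
      TRUE ~ "shared"
    ),
    taxon = ifelse(!is.na(res$.n_labels) & res$.n_labels == 1L,
                   res$.label, NA_character_)
  )
}

#' Serialize / restore a peptide index as TSV
#'
#' The occurrence table, lineage table and parameter block are written to a
#' single TSV artifact with a commented parameter header, so an index can be
#' archived alongside pipeline outputs and rebuilt losslessly.
#'
#' @param index A `peptide_index`.
#' @param path Output file.
#' @return `path`, invisibly (`write_peptide_index`); a `peptide_index`
#'   (`read_peptide_index`).
#' @export
write_peptide_index <- function(index, path) {
  stopifnot(inherits(index, "peptide_index"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  p <- index$params
  writeLines(sprintf(
    "# peptide_index missed_cleavages=%d min_length=%d max_length=%d rule=%s il_collapse=%s",
    p$missed_cleavages, p$min_length, p$max_length, p$rule, p$il_collapse
  ), con)
  writeLines(paste0("# lineage\t", apply(index$lineages, 1L, paste, collapse = ";")), con)
  utils::write.table(index$peptides, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_peptide_index
#' @export
read_peptide_index <- function(path) {
  lines <- readLines(path)
  header <- lines[1L]
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1L]]
  params <- stats::setNames(
    lapply(strsplit(kv, "=", fixed = TRUE), `[[`, 2L),
    vapply(strsplit(kv, "=", fixed = TRUE), `[[`, 1L, FUN.VALUE = character(1L))
  )
  lin_lines <- sub("^# lineage\t", "", grep("^# lineage\t", lines, value = TRUE))
  lin <- do.call(rbind, strsplit(lin_lines, ";", fixed = TRUE))
  lineages <- tibble::as_tibble(as.data.frame(lin, stringsAsFactors = FALSE))
  names(lineages) <- c("taxon_id", TAXONOMIC_RANKS)
  body <- lines[!startsWith(lines, "#")]
  peptides <- readr::read_tsv(I(paste(body, collapse = "\n")),
                              col_types = "ccc", progress = FALSE)
  structure(
    list(
      peptides = peptides,
      lineages = lineages,
      params = list(
        missed_cleavages = as.integer(params$missed_cleavages),
        min_length = as.integer(params$min_length),
        max_length = as.integer(params$max_length),
        rule = params$rule,
        il_collapse = identical(params$il_collapse, "TRUE")
      )
    ),
    class = "peptide_index"
  )
}
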