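#' Filter de novo peptides by ALC score
#'
#' Retains rows whose average local confidence meets the threshold
#' (inclusive: ALC equal to the threshold is kept).
#'
#' @param denovo Tibble with at least columns `peptide` and `alc`.
#' @param threshold ALC threshold in percent (default 80).
#' @return The retained rows; the number removed is reported via `message()`.
#' @export
filter_denovo_by_alc <- function(denovo, threshold = 80) {
  if (!"alc" %in% names(denovo)) {
    stop("de novo table lacks an `alc` column", call. = FALSE)
  }
  if (threshold < 0 || threshold > 100) {
    stop("`threshold` must be in [0, 100]", call. = FALSE)
  }
  keep <- denovo$alc >= threshold
  message(sum(!keep), " de novo peptides removed at ALC < ", threshold)
  denovo[keep, , drop = FALSE]
}

#' Tally taxon-specific de novo evidence per sample
#'
#' Matches filtered de novo peptides against the peptide index and counts,
#' per (taxon, sample), the distinct peptides that are species-unique to
#' that taxon. A taxon is "identified in a sample" when its count reaches
#' `min_specific_peptides`. Peptides shared between taxa contribute to no
#' taxon's tally.
#'
#' @param denovo Filtered de novo tibble (`sample_id`, `peptide`).
#' @param index A [build_peptide_index()] object; for de novo evidence it
#'   should be built with `il_collapse = TRUE`.
#' @param min_specific_peptides Identification threshold (default 1).
#' @return Tibble `taxon_id`, `sample_id`, `n_specific_peptides`,
#'   `identified`.
#' @export
tally_taxon_evidence <- function(denovo, index, min_specific_peptides = 1L) {
  stopifnot(inherits(index, "peptide_index"), min_specific_peptides >= 1L)
  rows <- dplyr::distinct(denovo[, c("sample_id", "peptide")])
  cls <- classify_peptide_specificity(rows$peptide, index, rank = "species")
  ## species-unique peptides only; map species label back to taxon id
  sp_map <- index$lineages[, c("taxon_id", "species")]
  hit <- cls$status == "unique"
  ev <- tibble::tibble(sample_id = rows$sample_id[hit],
                       species = cls$taxon[hit],
                       peptide = index_key(index, rows$peptide[hit]))
  ev <- dplyr::left_join(ev, sp_map, by = "species")
  tally <- dplyr::summarise(
    dplyr::group_by(ev, .data$taxon_id, .data$sample_id),
    n_specific_peptides = dplyr::n_distinct(.data$peptide),
    .groups = "drop"
  )
  tally$identified <- tally$n_specific_peptides >= min_specific_peptides
  tally
}

#' Apply the taxon retention rules to an evidence table
#'
#' The database-refinement rule set: (i) keep only taxa of kingdom
#' Bacteria; (ii) remove taxa not identified in at least
#' `min_samples_per_group` samples of some substrate group (the `"any"`
#' rule; set `group_rule = "all"` to require every group to qualify);
#' (iii) add back taxa reported by 16S rRNA sequencing. Host taxa are
#' appended as fixed background entries. Each retained taxon carries a
#' provenance flag.
#'
#' @param evidence Tibble from [tally_taxon_evidence()].
#' @param design Tibble from [sample_design()].
#' @param lineages Lineage tibble (from [lineage_table()] or a
#'   `peptide_index`), used for the kingdom rule.
#' @param min_samples_per_group Identification count needed within a group
#'   (default 3, i.e. all of a triplicate).
#' @param taxa_16s Character vector of taxon ids (or species names) to add
#'   regardless of proteomic evidence.
#' @param group_rule `"any"` (default): retained if any group reaches the
#'   threshold; `"all"`: every group must.
#' @param host_taxa Host taxon ids always appended (default human, pig).
#' @return Tibble `taxon_id`, `provenance` (proteomic/16S/both/host). 16S
#'   taxa with no lineage available are kept, flagged in the `unresolved`
#'   attribute, and a warning is raised.
#' @export
refine_taxon_set <- function(evidence, design, lineages,
                             min_samples_per_group = 3L,
                             taxa_16s = character(),
                             group_rule = c("any", "all"),
                             host_taxa = c("human", "pig")) {
  group_rule <- match.arg(group_rule)
  stopifnot(min_samples_per_group >= 1L)

  ev <- dplyr::left_join(evidence[evidence$identified, , drop = FALSE],
                         design[, c("sample_id", "group")], by = "sample_id")
  per_group <- dplyr::summarise(
    dplyr::group_by(ev, .data$taxon_id, .data$group),
    n_samples = dplyr::n_distinct(.data$sample_id),
    .groups = "drop"
  )
  qual <- dplyr::summarise(
    dplyr::group_by(per_group, .data$taxon_id),
    ok = if (group_rule == "any") {
      any(.data$n_samples >= min_samples_per_group)
    } else {
      ## groups with zero identifications are absent from per_group, so the
      ## "all" rule additionally requires presence in every group
      all(.data$n_samples >= min_samples_per_group) &&
        dplyr::n_distinct(.data$group) == dplyr::n_distinct(design$group)
    },
    .groups = "drop"
  )
  proteomic <- qual$taxon_id[qual$ok]

  ## kingdom rule
  kingdoms <- stats::setNames(lineages$kingdom, lineages$taxon_id)
  proteomic <- proteomic[!is.na(kingdoms[proteomic]) &
                           kingdoms[proteomic] == "Bacteria"]

  ## 16S union: accept taxon ids or species names
  sixteen <- taxa_16s
  by_species <- stats::setNames(lineages$taxon_id, lineages$species)
  resolved_16s <- ifelse(sixteen %in% lineages$taxon_id, sixteen,
                         by_species[sixteen])
  unresolved <- sixteen[is.na(resolved_16s)]
  resolved_16s <- resolved_16s[!is.na(resolved_16s)]
  if (length(unresolved) > 0L) {
    warning("16S taxa with no available proteome/lineage: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }

  all_ids <- union(proteomic, resolved_16s)
  out <- tibble::tibble(
    taxon_id = sort(all_ids),
    provenance = dplyr::case_when(
      sort(all_ids) %in% proteomic & sort(all_ids) %in% resolved_16s ~ "both",
      sort(all_ids) %in% proteomic ~ "proteomic",
      TRUE ~ "16S"
    )
  )
  out <- dplyr::bind_rows(
    out, tibble::tibble(taxon_id = host_taxa, provenance = "host")
  )
  attr(out, "unresolved") <- unresolved
  out
}

#' Export the refined protein database
#'
#' Writes the retained taxa's proteomes to a single FASTA with
#' provenance-preserving headers, in deterministic order (taxon id, then
#' protein id), plus a manifest TSV. Taxa with no resolvable proteome are
#' listed in the manifest and excluded from the FASTA.
#'
#' @param retained Tibble from [refine_taxon_set()].
#' @param proteomes Named list of [taxon_proteome()] (bacteria and hosts).
#' @param fasta_path,manifest_path Output files.
#' @return The manifest tibble (`taxon_id`, `n_proteins`, `provenance`),
#'   invisibly.
#' @export
export_refined_database <- function(retained, proteomes, fasta_path,
                                    manifest_path) {
  ord <- order(retained$taxon_id)
  retained <- retained[ord, , drop = FALSE]
  records <- character(0L)
  seqs <- character(0L)
  n_prot <- integer(nrow(retained))
  for (i in seq_len(nrow(retained))) {
    tid <- retained$taxon_id[i]
    p <- proteomes[[tid]]
    if (is.null(p)) {
      n_prot[i] <- NA_integer_
      next
    }
    pid_ord <- order(names(p$proteins))
    prot <- p$proteins[pid_ord]
    records <- c(records, paste0(
      tid, "|", names(prot),
      " lineage=", paste(p$lineage, collapse = ";"),
      " provenance=", retained$provenance[i]
    ))
    seqs <- c(seqs, unname(prot))
    n_prot[i] <- length(prot)
  }
  fa <- Biostrings::AAStringSet(seqs)
  names(fa) <- records
  Biostrings::writeXStringSet(fa, fasta_path, width = 60L)
  manifest <- tibble::tibble(taxon_id = retained$taxon_id,
                             n_proteins = n_prot,
                             provenance = retained$provenance)
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  invisible(manifest)
}
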