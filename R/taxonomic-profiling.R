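#' Community profile from unique-peptide intensities
#'
#' Per sample, a taxon's abundance is the summed intensity of peptides
#' unique to it at the requested rank, divided by the sample's total
#' unique-peptide intensity over bacterial taxa. Shared and unmatched
#' peptides are excluded from quantification (they are counted in the QC
#' attributes); host-assigned intensity is reported separately and never
#' enters the bacterial simplex. Repeated rows for the same peptide in a
#' sample (technical injections) are summed.
#'
#' @param observations Tibble `sample_id`, `peptide`, `intensity`.
#' @param index A [build_peptide_index()] object.
#' @param rank Taxonomic rank for uniqueness (default `"species"`).
#' @return A `community_profile`: tibble `sample_id`, `taxon`, `rank`,
#'   `abundance`, `n_unique_peptides`, `valid`. Attributes: `rank`,
#'   `lineages`, `host` (tibble `sample_id`, `host_share` relative to all
#'   matched intensity), `qc` (per-sample matched/shared/unmatched counts).
#'   Samples with zero bacterial unique-peptide intensity are flagged
#'   `valid = FALSE` rather than silently zero-filled.
#' @export
quantify_unique_peptide_profile <- function(observations, index,
                                            rank = "species") {
  stopifnot(inherits(index, "peptide_index"))
  if (nrow(observations) == 0L) {
    stop("`observations` is empty", call. = FALSE)
  }
  obs <- dplyr::summarise(
    dplyr::group_by(observations, .data$sample_id, .data$peptide),
    intensity = sum(.data$intensity),
    .groups = "drop"
  )
  cls <- classify_peptide_specificity(obs$peptide, index, rank = rank)
  obs$status <- cls$status
  obs$taxon <- cls$taxon

  ## bacterial vs host at the chosen rank
  lin <- index$lineages
  rank_kingdom <- dplyr::distinct(lin[, c(rank, "kingdom")])
  names(rank_kingdom) <- c("taxon", "kingdom")
  dup <- rank_kingdom$taxon[duplicated(rank_kingdom$taxon)]
  if (length(dup) > 0L) {
    stop("rank label(s) span kingdoms: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  obs <- dplyr::left_join(obs, rank_kingdom, by = "taxon")
  uniq <- obs[obs$status == "unique", , drop = FALSE]
  is_bact <- uniq$kingdom == "Bacteria"

  qc <- dplyr::summarise(
    dplyr::group_by(obs, .data$sample_id),
    n_matched = sum(.data$status != "unmatched"),
    n_shared = sum(.data$status == "shared"),
    n_unmatched = sum(.data$status == "unmatched"),
    .groups = "drop"
  )

  matched_total <- dplyr::summarise(
    dplyr::group_by(obs[obs$status != "unmatched", , drop = FALSE],
                    .data$sample_id),
    total = sum(.data$intensity), .groups = "drop"
  )
  host_int <- dplyr::summarise(
    dplyr::group_by(uniq[!is_bact, , drop = FALSE], .data$sample_id),
    host_intensity = sum(.data$intensity), .groups = "drop"
  )
  host <- dplyr::left_join(matched_total, host_int, by = "sample_id")
  host$host_intensity[is.na(host$host_intensity)] <- 0
  host <- tibble::tibble(sample_id = host$sample_id,
                         host_share = host$host_intensity / host$total)

  bact <- uniq[is_bact, , drop = FALSE]
  per_taxon <- dplyr::summarise(
    dplyr::group_by(bact, .data$sample_id, .data$taxon),
    intensity = sum(.data$intensity),
    n_unique_peptides = dplyr::n(),
    .groups = "drop"
  )
  totals <- dplyr::summarise(
    dplyr::group_by(per_taxon, .data$sample_id),
    total = sum(.data$intensity), .groups = "drop"
  )
  samples <- unique(observations$sample_id)
  invalid <- setdiff(samples, totals$sample_id[totals$total > 0])
  if (length(invalid) > 0L) {
    warning("sample(s) with zero bacterial unique-peptide intensity ",
            "flagged invalid: ", paste(invalid, collapse = ", "),
            call. = FALSE)
  }
  per_taxon <- dplyr::left_join(per_taxon, totals, by = "sample_id")
  profile <- tibble::tibble(
    sample_id = per_taxon$sample_id,
    taxon = per_taxon$taxon,
    rank = rank,
    abundance = per_taxon$intensity / per_taxon$total,
    n_unique_peptides = per_taxon$n_unique_peptides,
    valid = TRUE
  )
  if (length(invalid) > 0L) {
    profile <- dplyr::bind_rows(profile, tibble::tibble(
      sample_id = invalid, taxon = NA_character_, rank = rank,
      abundance = NA_real_, n_unique_peptides = 0L, valid = FALSE
    ))
  }
  structure(profile, class = c("community_profile", class(profile)),
            rank = rank, lineages = lin, host = host, qc = qc)
}

rank_index <- function(rank) match(rank, TAXONOMIC_RANKS)

#' Aggregate a community profile to a coarser rank
#'
#' Sums abundances of taxa sharing the same label at the target rank; the
#' per-sample simplex is preserved.
#'
#' @param profile A `community_profile`.
#' @param rank Target rank; must be the profile's rank or coarser.
#' @return A `community_profile` at the target rank.
#' @export
aggregate_to_rank <- function(profile, rank) {
  stopifnot(inherits(profile, "community_profile"))
  from <- attr(profile, "rank")
  if (rank_index(rank) > rank_index(from)) {
    stop("target rank (", rank, ") is finer than the profile rank (", from,
         ")", call. = FALSE)
  }
  if (rank == from) return(profile)
  lin <- attr(profile, "lineages")
  map <- dplyr::distinct(lin[, c(from, rank)])
  names(map) <- c("taxon", ".target")
  valid <- profile[profile$valid, , drop = FALSE]
  joined <- dplyr::left_join(valid, map, by = "taxon")
  agg <- dplyr::summarise(
    dplyr::group_by(joined, .data$sample_id, .data$.target),
    abundance = sum(.data$abundance),
    n_unique_peptides = sum(.data$n_unique_peptides),
    .groups = "drop"
  )
  out <- tibble::tibble(
    sample_id = agg$sample_id, taxon = agg$.target, rank = rank,
    abundance = agg$abundance, n_unique_peptides = agg$n_unique_peptides,
    valid = TRUE
  )
  invalid <- profile[!profile$valid, , drop = FALSE]
  if (nrow(invalid) > 0L) {
    invalid$rank <- rank
    out <- dplyr::bind_rows(out, invalid)
  }
  structure(out, class = c("community_profile", class(out)),
            rank = rank, lineages = lin, host = attr(profile, "host"),
            qc = attr(profile, "qc"))
}

#' Replicate-averaged group profile with a top-N "other" bucket
#'
#' Means abundances across the valid replicates of each substrate group,
#' ranks taxa by their grand mean across groups, and pools everything
#' beyond the top `top_n` into an `"other"` bucket so the output rows still
#' sum to 1 per group.
#'
#' @param profile A `community_profile`.
#' @param design Tibble from [sample_design()].
#' @param top_n Number of taxa reported individually (default 14, the
#'   number shown in genus-level community figures).
#' @return Tibble `group`, `taxon`, `mean_abundance`. Groups with no valid
#'   samples are omitted with a warning.
#' @export
summarize_replicates <- function(profile, design, top_n = 14L) {
  stopifnot(inherits(profile, "community_profile"), top_n >= 1L)
  valid <- profile[profile$valid, , drop = FALSE]
  joined <- dplyr::left_join(valid, design[, c("sample_id", "group")],
                             by = "sample_id")
  dropped <- setdiff(design$group, joined$group)
  if (length(dropped) > 0L) {
    warning("group(s) with no valid samples omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  ## per-sample rows lack zero-abundance taxa; group means must divide by
  ## the number of valid samples, not the number of non-zero rows
  n_valid <- dplyr::summarise(
    dplyr::group_by(joined, .data$group),
    .n = dplyr::n_distinct(.data$sample_id), .groups = "drop"
  )
  sums <- dplyr::summarise(
    dplyr::group_by(joined, .data$group, .data$taxon),
    .sum = sum(.data$abundance), .groups = "drop"
  )
  means <- dplyr::left_join(sums, n_valid, by = "group")
  means$mean_abundance <- means$.sum / means$.n

  grand <- dplyr::summarise(
    dplyr::group_by(means, .data$taxon),
    grand_mean = mean(.data$mean_abundance), .groups = "drop"
  )
  grand <- grand[order(-grand$grand_mean, grand$taxon), , drop = FALSE]
  top <- utils::head(grand$taxon, top_n)

  means$taxon <- ifelse(means$taxon %in% top, means$taxon, "other")
  out <- dplyr::summarise(
    dplyr::group_by(means, .data$group, .data$taxon),
    mean_abundance = sum(.data$mean_abundance), .groups = "drop"
  )
  ## keep an explicit zero "other" row when nothing was pooled
  have_other <- unique(out$group[out$taxon == "other"])
  missing_other <- setdiff(unique(out$group), have_other)
  if (length(missing_other) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      group = missing_other, taxon = "other", mean_abundance = 0
    ))
  }
  dplyr::arrange(out, .data$group, dplyr::desc(.data$mean_abundance))
}
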