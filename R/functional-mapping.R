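CAZYME_TOOLS <- c("hmm", "diamond", "peptide-pattern")

METABOLIC_GROUPS <- c("Butyric", "Akkermansia", "Bifido", "Bacteroides",
                      "Enterobacteria", "Lachnoclostridium",
                      "Asaccharolytic", "Succinivorans")

#' Consensus filter for CAZyme annotations
#'
#' A (protein, family) annotation is retained when at least `min_tools`
#' distinct annotation tools report that exact family for that protein;
#' duplicate reports by one tool count once. Sulfatase annotations come from
#' a single catalog, so hits whose tool is `"sulfatase"` are passed through
#' the same machinery with an effective threshold of one tool and flagged
#' `source = "sulfatase"` in the output.
#'
#' @param hits Tibble with columns `protein_id`, `family`, `tool`; `tool`
#'   must be one of `r paste(c(CAZYME_TOOLS, "sulfatase"), collapse = ", ")`.
#' @param min_tools Distinct tools required (default 2).
#' @return Tibble `protein_id`, `family`, `n_tools`, `source`
#'   (`"cazy-consensus"` or `"sulfatase"`).
#' @export
consensus_cazyme_filter <- function(hits, min_tools = 2L) {
  stopifnot(min_tools >= 1L)
  needed <- c("protein_id", "family", "tool")
  if (!all(needed %in% names(hits))) {
    stop("hit table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(hits$tool), c(CAZYME_TOOLS, "sulfatase"))
  if (length(bad) > 0L) {
    stop("unknown annotation tool(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(hits$family) | is.na(hits$family))) {
    stop("empty CAZy family label in hit table", call. = FALSE)
  }
  cazy <- hits[hits$tool != "sulfatase", , drop = FALSE]
  sulf <- hits[hits$tool == "sulfatase", , drop = FALSE]
  agg <- dplyr::summarise(
    dplyr::group_by(cazy, .data$protein_id, .data$family),
    n_tools = dplyr::n_distinct(.data$tool), .groups = "drop"
  )
  out <- agg[agg$n_tools >= min_tools, , drop = FALSE]
  out$source <- "cazy-consensus"
  if (nrow(sulf) > 0L) {
    sagg <- dplyr::summarise(
      dplyr::group_by(sulf, .data$protein_id, .data$family),
      n_tools = 1L, .groups = "drop"
    )
    sagg$source <- "sulfatase"
    out <- dplyr::bind_rows(out, sagg)
  }
  dplyr::arrange(out, .data$protein_id, .data$family)
}

#' Build a reaction catalog of reference enzyme sequences
#'
#' @param reactions Tibble with columns `reaction`, `taxon_id`,
#'   `enzyme_id`, `sequence` (residues, standard alphabet), and optionally
#'   `pathway` (metabolite/pathway tag).
#' @return The validated catalog tibble with class `reaction_catalog`.
#' @export
reaction_catalog <- function(reactions) {
  needed <- c("reaction", "taxon_id", "enzyme_id", "sequence")
  if (!all(needed %in% names(reactions)) || nrow(reactions) == 0L) {
    stop("catalog needs >= 1 row with columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  for (s in reactions$sequence) validate_residues(s)
  structure(reactions, class = c("reaction_catalog", class(reactions)))
}

#' Match observed peptides to reference enzyme digests
#'
#' A peptide matches a reference enzyme when it is among the enzyme's
#' tryptic digestion products under the same parameters used for the
#' community index (`mode = "tryptic"`, the default); `mode = "substring"`
#' accepts any exact substring, for sensitivity checks. Each
#' (sample, peptide, taxon, reaction) combination is emitted once, however
#' many enzymes of that taxon and reaction the peptide hits.
#'
#' @param observations Tibble `sample_id`, `peptide`, `intensity`.
#' @param catalog A [reaction_catalog()].
#' @param missed_cleavages,min_length,max_length,rule Digestion parameters
#'   (defaults match [build_peptide_index()]).
#' @param il_collapse Collapse I/L before matching (default `FALSE`).
#' @param mode `"tryptic"` (membership in the digest) or `"substring"`.
#' @return Tibble `sample_id`, `peptide`, `taxon_id`, `reaction`.
#' @export
match_peptides_to_reference_enzymes <- function(observations, catalog,
                                                missed_cleavages = 1L,
                                                min_length = 7L,
                                                max_length = 40L,
                                                rule = "trypsin",
                                                il_collapse = FALSE,
                                                mode = c("tryptic", "substring")) {
  mode <- match.arg(mode)
  stopifnot(inherits(catalog, "reaction_catalog"))
  obs <- dplyr::distinct(observations[, c("sample_id", "peptide")])
  key <- if (il_collapse) collapse_il(obs$peptide) else obs$peptide

  out <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    if (mode == "tryptic") {
      prods <- tryptic_digest(catalog$sequence[i], missed_cleavages,
                              min_length, max_length, rule)
      if (il_collapse) prods <- collapse_il(prods)
      hit <- key %in% prods
    } else {
      target <- if (il_collapse) collapse_il(catalog$sequence[i]) else catalog$sequence[i]
      hit <- vapply(key, grepl, logical(1L), x = target, fixed = TRUE)
    }
    if (!any(hit)) next
    out[[i]] <- tibble::tibble(
      sample_id = obs$sample_id[hit], peptide = obs$peptide[hit],
      taxon_id = catalog$taxon_id[i], reaction = catalog$reaction[i]
    )
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Assign taxa to metabolic groups
#'
#' Maps taxa onto the eight fermentation guilds used to roll up enzyme copy
#' numbers: Butyric (butyrate and 1,2-propanediol producers), Akkermansia
#' (the mucolytic *A. muciniphila*), Bifido (lactate/acetate producers),
#' Bacteroides (propionate/succinate and acetate producers), Enterobacteria
#' (lactate, succinate and acetate producers), Lachnoclostridium (mucolytic
#' formate/1,2-propanediol consumers), Asaccharolytic (lactate and amino
#' acid degraders) and Succinivorans (succinate consumers).
#'
#' @param taxa Character vector of taxon ids.
#' @param group_map Tibble `taxon_id`, `group` with groups drawn from the
#'   eight labels above.
#' @return Character vector of group labels; unmapped taxa return
#'   `"unassigned"` with a warning, never a silent default.
#' @export
assign_metabolic_group <- function(taxa, group_map) {
  stopifnot(all(c("taxon_id", "group") %in% names(group_map)))
  bad <- setdiff(unique(group_map$group), METABOLIC_GROUPS)
  if (length(bad) > 0L) {
    stop("unknown metabolic group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lookup <- stats::setNames(group_map$group, group_map$taxon_id)
  out <- unname(lookup[taxa])
  if (anyNA(out)) {
    warning("unmapped taxa assigned 'unassigned': ",
            paste(unique(taxa[is.na(out)]), collapse = ", "), call. = FALSE)
    out[is.na(out)] <- "unassigned"
  }
  out
}

#' Default metabolic-group map for synthetic taxa
#'
#' Assigns taxa cyclically over the eight guild labels — a synthetic
#' stand-in for curated genome-based assignments, sufficient to exercise
#' group-level additivity on generated communities. Real analyses should
#' load a curated map with [read_group_map()].
#'
#' @param taxa Character vector of taxon ids.
#' @return Tibble `taxon_id`, `group`.
#' @export
default_metabolic_group_map <- function(taxa) {
  tibble::tibble(
    taxon_id = taxa,
    group = METABOLIC_GROUPS[(seq_along(taxa) - 1L) %% 8L + 1L]
  )
}

#' @rdname default_metabolic_group_map
#' @param path TSV file with columns `taxon_id`, `group`.
#' @export
read_group_map <- function(path) {
  map <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  bad <- setdiff(unique(map$group), METABOLIC_GROUPS)
  if (length(bad) > 0L) {
    stop("unknown metabolic group label(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map
}

#' Enzyme copy numbers per taxon or metabolic group
#'
#' The count of distinct peptide sequences matching a taxon's reference
#' enzymes for a reaction, per sample — the workflow's "protein copy
#' number". Group scope sums member taxa. When a design is supplied, the
#' per-condition mean and SD across replicates are computed as well.
#'
#' @param matches Tibble from [match_peptides_to_reference_enzymes()].
#' @param scope `"taxon"` or `"group"`.
#' @param group_map Required when `scope = "group"`; must cover every taxon
#'   in `matches`.
#' @param design Optional [sample_design()] tibble for condition summaries.
#' @param reactions Optional character vector fixing the full reaction set
#'   (so empty match tables still yield a complete zero matrix).
#' @return List of class `enzyme_copy_matrix`: `counts` (tibble `unit`,
#'   `reaction`, `sample_id`, `n_peptides`, complete over the unit x
#'   reaction x sample grid) and `condition_summary` (tibble `unit`,
#'   `reaction`, `group`, `mean`, `sd`; `NULL` without a design).
#' @export
enzyme_copy_numbers <- function(matches, scope = c("taxon", "group"),
                                group_map = NULL, design = NULL,
                                reactions = NULL) {
  scope <- match.arg(scope)
  m <- dplyr::distinct(matches)
  if (scope == "group") {
    if (is.null(group_map)) {
      stop("`group_map` required when scope = \"group\"", call. = FALSE)
    }
    missing <- setdiff(unique(m$taxon_id), group_map$taxon_id)
    if (length(missing) > 0L) {
      stop("taxa missing from group map: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m$unit <- assign_metabolic_group(m$taxon_id, group_map)
    units <- unique(group_map$group)
  } else {
    m$unit <- m$taxon_id
    units <- unique(m$taxon_id)
  }
  reactions <- unique(c(reactions, m$reaction))
  samples <- if (!is.null(design)) design$sample_id else unique(m$sample_id)

  counts <- dplyr::summarise(
    dplyr::group_by(m, .data$unit, .data$reaction, .data$sample_id),
    n_peptides = dplyr::n_distinct(.data$peptide), .groups = "drop"
  )
  grid <- tidyr::expand_grid(unit = units, reaction = reactions,
                             sample_id = samples)
  counts <- dplyr::left_join(grid, counts,
                             by = c("unit", "reaction", "sample_id"))
  counts$n_peptides[is.na(counts$n_peptides)] <- 0L

  condition_summary <- NULL
  if (!is.null(design)) {
    joined <- dplyr::left_join(counts, design[, c("sample_id", "group")],
                               by = "sample_id")
    condition_summary <- dplyr::summarise(
      dplyr::group_by(joined, .data$unit, .data$reaction, .data$group),
      mean = mean(.data$n_peptides),
      sd = stats::sd(.data$n_peptides),
      .groups = "drop"
    )
  }
  structure(list(counts = counts, condition_summary = condition_summary,
                 scope = scope),
            class = "enzyme_copy_matrix")
}
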