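pipeline_defaults <- function() {
  list(
    seed = 7L,
    ## synthetic community
    n_taxa = 12L, n_proteins_per_taxon = 30L, shared_fraction = 0.3,
    groups = c("InuHP", "B-gluc", "PecA", "Xyl", "InuHP+PCM", "B-gluc+PCM",
               "PecA+PCM", "Xyl+PCM", "Xyl+PGM", "PGM", "PCM"),
    replicates = 3L,
    depth = 2000L, intensity_noise = 0.3, background_fraction = 0.03,
    substitution_rate = 0.02, alc_mean = 88, alc_sd = 8,
    ## digestion / refinement / annotation
    missed_cleavages = 1L, min_length = 7L, max_length = 40L,
    rule = "trypsin",
    alc_threshold = 80, min_specific_peptides = 1L,
    min_samples_per_group = 3L, min_tools = 2L,
    ## profiling / physiology / stats
    rank = "species", top_n = 14L,
    heat_yield = 4000, working_volume_L = 2e-3
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills documented defaults, rejects unknown keys and
#' reports all validation problems at once. An empty or absent file yields
#' the full default configuration.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL) {
  defaults <- pipeline_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  problems <- character(0L)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    problems <- c(problems,
                  paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in intersect(names(user), names(defaults))) {
    want <- defaults[[key]]
    got <- user[[key]]
    if (is.numeric(want) && !is.numeric(got)) {
      problems <- c(problems, paste0("`", key, "` must be numeric, got ",
                                     class(got)[1L]))
    } else if (is.character(want) && !is.character(got)) {
      problems <- c(problems, paste0("`", key, "` must be character, got ",
                                     class(got)[1L]))
    } else {
      defaults[[key]] <- if (is.integer(want) && is.numeric(got)) {
        as.integer(got)
      } else got
    }
  }
  if (length(problems) > 0L) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(defaults, class = "pipeline_config")
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

## small built-in reaction catalog for demo runs: one reference enzyme per
## taxon for each of eight reactions, sampled from the synthetic proteomes
demo_reaction_catalog <- function(proteomes) {
  reactions <- c("butyryl-CoA transferase", "proline dehydrogenase",
                 "glutamate decarboxylase", "methylmalonyl-CoA decarboxylase",
                 "lactate dehydrogenase", "pyruvate:ferredoxin oxidoreductase",
                 "acetate kinase", "fumarate reductase")
  rows <- list()
  taxa <- names(proteomes)
  for (j in seq_along(reactions)) {
    for (tid in taxa) {
      prot <- proteomes[[tid]]$proteins
      pick <- (j - 1L) %% length(prot) + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction = reactions[j], taxon_id = tid,
        enzyme_id = paste0(tid, "_", names(prot)[pick]),
        sequence = unname(prot[pick])
      )
    }
  }
  reaction_catalog(dplyr::bind_rows(rows))
}

#' Run the full synthetic-community pipeline
#'
#' Orchestrates simulate -> index -> refine -> profile -> metabolism ->
#' physiology -> stats, with every stage interface persisted as a TSV (or
#' FASTA) under `outdir`. A failing stage is recorded in the manifest and
#' its downstream stages are skipped. The resolved configuration is written
#' alongside the outputs, and the whole run is deterministic under a fixed
#' seed.
#'
#' @param config A [load_pipeline_config()] object (or `NULL` for
#'   defaults).
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the configured seed.
#' @return Manifest tibble (`stage`, `output`, `rows`, `md5`, `status`),
#'   invisibly; also written to `manifest.tsv`.
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL) {
  if (is.null(config)) config <- load_pipeline_config()
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(outdir, "resolved-config.yaml"))

  manifest <- tibble::tibble(stage = character(), output = character(),
                             rows = integer(), md5 = character(),
                             status = character())
  note <- function(stage, path, rows, status = "ok") {
    manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
      stage = stage, output = basename(path), rows = as.integer(rows),
      md5 = unname(tools::md5sum(path)), status = status
    ))
  }
  failed <- FALSE
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fn) {
    if (failed) {
      manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
        stage = stage, output = NA_character_, rows = NA_integer_,
        md5 = NA_character_, status = "skipped"
      ))
      return(invisible(NULL))
    }
    tryCatch(fn(), error = function(e) {
      failed <<- TRUE
      manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
        stage = stage, output = NA_character_, rows = NA_integer_,
        md5 = NA_character_, status = paste0("failed: ", conditionMessage(e))
      ))
    })
  }

  run_stage("simulate", function() {
    cfg <- config
    design <- sample_design(cfg$groups, cfg$replicates)
    proteomes <- generate_taxon_proteomes(
      cfg$n_taxa, cfg$n_proteins_per_taxon,
      shared_fraction = cfg$shared_fraction, seed = cfg$seed
    )
    hosts <- generate_host_proteomes(seed = cfg$seed)
    set.seed(cfg$seed + 1L)
    w <- stats::rgamma(cfg$n_taxa, shape = 2)
    truth <- community_truth(design, stats::setNames(w, names(proteomes)),
                             seed = cfg$seed)
    obs <- simulate_peptide_observations(
      proteomes, truth, depth = cfg$depth,
      intensity_noise = cfg$intensity_noise,
      background_fraction = cfg$background_fraction, hosts = hosts,
      seed = cfg$seed + 2L
    )
    denovo <- simulate_denovo_peptides(
      obs, alc_mean = cfg$alc_mean, alc_sd = cfg$alc_sd,
      substitution_rate = cfg$substitution_rate, seed = cfg$seed + 3L
    )
    chem <- simulate_culture_chemistry(
      design,
      effects = list(propionate = c("PCM" = 4, "InuHP+PCM" = 2,
                                    "B-gluc+PCM" = 2, "PecA+PCM" = 2,
                                    "Xyl+PCM" = 2)),
      seed = cfg$seed + 4L
    )
    cal <- simulate_calorimetry_series(seed = cfg$seed + 5L)

    fasta_dir <- file.path(outdir, "proteomes")
    write_proteome_fasta(c(proteomes, hosts), fasta_dir)
    note("simulate", file.path(fasta_dir, paste0(names(proteomes)[1L], ".fasta")),
         length(proteomes) + length(hosts))
    note("simulate", write_stage_tsv(design, file.path(outdir, "design.tsv")),
         nrow(design))
    note("simulate", write_stage_tsv(obs, file.path(outdir, "observations.tsv")),
         nrow(obs))
    note("simulate", write_stage_tsv(denovo, file.path(outdir, "denovo.tsv")),
         nrow(denovo))
    note("simulate", write_stage_tsv(chem$metabolites,
                                     file.path(outdir, "metabolites.tsv")),
         nrow(chem$metabolites))
    note("simulate", write_stage_tsv(chem$gases, file.path(outdir, "gases.tsv")),
         nrow(chem$gases))
    note("simulate", write_stage_tsv(chem$ph, file.path(outdir, "ph.tsv")),
         nrow(chem$ph))
    note("simulate", write_stage_tsv(tibble::as_tibble(cal),
                                     file.path(outdir, "calorimetry.tsv")),
         nrow(cal))
    state$design <- design
    state$proteomes <- proteomes
    state$hosts <- hosts
    state$truth <- truth
    state$obs <- obs
    state$denovo <- denovo
    state$chem <- chem
    state$cal <- cal
  })

  run_stage("index", function() {
    cfg <- config
    all_prot <- c(state$proteomes, state$hosts)
    state$index <- build_peptide_index(
      all_prot, cfg$missed_cleavages, cfg$min_length, cfg$max_length,
      cfg$rule, il_collapse = FALSE
    )
    state$index_il <- build_peptide_index(
      all_prot, cfg$missed_cleavages, cfg$min_length, cfg$max_length,
      cfg$rule, il_collapse = TRUE
    )
    path <- file.path(outdir, "peptide-index.tsv")
    write_peptide_index(state$index, path)
    note("index", path, nrow(state$index$peptides))
  })

  run_stage("refine", function() {
    cfg <- config
    kept <- filter_denovo_by_alc(state$denovo, cfg$alc_threshold)
    evidence <- tally_taxon_evidence(kept, state$index_il,
                                     cfg$min_specific_peptides)
    retained <- refine_taxon_set(
      evidence, state$design, state$index$lineages,
      min_samples_per_group = cfg$min_samples_per_group
    )
    fasta <- file.path(outdir, "refined-database.fasta")
    man <- file.path(outdir, "refined-manifest.tsv")
    export_refined_database(retained, c(state$proteomes, state$hosts),
                            fasta, man)
    note("refine", write_stage_tsv(evidence, file.path(outdir, "evidence.tsv")),
         nrow(evidence))
    note("refine", fasta, nrow(retained))
    note("refine", man, nrow(retained))
    state$retained <- retained
  })

  run_stage("profile", function() {
    cfg <- config
    profile <- quantify_unique_peptide_profile(state$obs, state$index,
                                               rank = cfg$rank)
    genus <- aggregate_to_rank(profile, "genus")
    summary <- summarize_replicates(genus, state$design, top_n = cfg$top_n)
    note("profile", write_stage_tsv(tibble::as_tibble(profile),
                                    file.path(outdir, "profile.tsv")),
         nrow(profile))
    note("profile", write_stage_tsv(summary,
                                    file.path(outdir, "group-summary.tsv")),
         nrow(summary))
    note("profile", write_stage_tsv(attr(profile, "host"),
                                    file.path(outdir, "host-share.tsv")),
         nrow(attr(profile, "host")))
    state$profile <- profile
  })

  run_stage("metabolism", function() {
    catalog <- demo_reaction_catalog(state$proteomes)
    matches <- match_peptides_to_reference_enzymes(
      state$obs, catalog, config$missed_cleavages, config$min_length,
      config$max_length, config$rule
    )
    group_map <- default_metabolic_group_map(names(state$proteomes))
    copies <- enzyme_copy_numbers(matches, scope = "group",
                                  group_map = group_map,
                                  design = state$design,
                                  reactions = unique(catalog$reaction))
    note("metabolism", write_stage_tsv(matches,
                                       file.path(outdir, "enzyme-matches.tsv")),
         nrow(matches))
    note("metabolism", write_stage_tsv(copies$counts,
                                       file.path(outdir, "enzyme-copies.tsv")),
         nrow(copies$counts))
    note("metabolism",
         write_stage_tsv(copies$condition_summary,
                         file.path(outdir, "enzyme-copies-summary.tsv")),
         nrow(copies$condition_summary))
  })

  run_stage("physiology", function() {
    cfg <- config
    cal_q <- integrate_heat(state$cal)
    q_final <- cal_q$Q_J[nrow(cal_q)]
    biomass <- biomass_from_heat(q_final, cfg$heat_yield,
                                 cfg$working_volume_L)
    gases <- dplyr::left_join(state$chem$gases, state$chem$ph,
                              by = "sample_id")
    dissolved <- dplyr::bind_cols(
      gases["sample_id"],
      dissolved_gas_concentration(gases$species, gases$p_atm, gases$pH)
    )
    met <- state$chem$metabolites
    met$mmol_per_gDW <- normalize_to_dry_weight(met$conc_mM, biomass$dw_g,
                                                cfg$working_volume_L)
    physiology <- tibble::tibble(
      Q_J = q_final, dw_g = biomass$dw_g, dw_g_per_L = biomass$dw_g_per_L,
      propionate_bound_mM = mucin_propionate_bound(0.5, 0.10)
    )
    note("physiology", write_stage_tsv(physiology,
                                       file.path(outdir, "physiology.tsv")),
         nrow(physiology))
    note("physiology", write_stage_tsv(dissolved,
                                       file.path(outdir, "dissolved-gases.tsv")),
         nrow(dissolved))
    note("physiology",
         write_stage_tsv(met, file.path(outdir, "metabolites-normalized.tsv")),
         nrow(met))
    state$metabolites_norm <- met
  })

  run_stage("stats", function() {
    prof <- state$profile
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(prof[prof$valid, c("sample_id", "taxon", "abundance")]),
      names_from = "taxon", values_from = "abundance", values_fill = 0
    )
    m <- as.matrix(wide[, -1L, drop = FALSE])
    rownames(m) <- wide$sample_id
    diversity <- tibble::tibble(
      sample_id = rownames(m),
      gini_simpson = apply(m, 1L, gini_simpson)
    )
    bc <- bray_curtis_matrix(m)
    ord <- pcoa_ordination(bc, k = 2L)
    coords <- tibble::tibble(
      sample_id = rownames(ord$coordinates),
      axis1 = ord$coordinates[, 1L],
      axis2 = if (ncol(ord$coordinates) >= 2L) ord$coordinates[, 2L] else 0
    )
    met <- dplyr::left_join(state$chem$metabolites,
                            state$design[, c("sample_id", "group")],
                            by = "sample_id")
    tests <- dplyr::bind_rows(lapply(split(met, met$metabolite), function(d) {
      kw <- kruskal_wallis_test(d$conc_mM, d$group)
      kw$metabolite <- d$metabolite[1L]
      kw
    }))
    dunn <- dplyr::bind_rows(lapply(split(met, met$metabolite), function(d) {
      dn <- dunn_posthoc(d$conc_mM, d$group)
      dn$metabolite <- d$metabolite[1L]
      dn
    }))
    note("stats", write_stage_tsv(diversity,
                                  file.path(outdir, "alpha-diversity.tsv")),
         nrow(diversity))
    bc_tbl <- tibble::as_tibble(bc, rownames = "sample_id")
    note("stats", write_stage_tsv(bc_tbl,
                                  file.path(outdir, "bray-curtis.tsv")),
         nrow(bc_tbl))
    note("stats", write_stage_tsv(coords,
                                  file.path(outdir, "ordination.tsv")),
         nrow(coords))
    note("stats", write_stage_tsv(tests,
                                  file.path(outdir, "kruskal-wallis.tsv")),
         nrow(tests))
    note("stats", write_stage_tsv(dunn, file.path(outdir, "dunn.tsv")),
         nrow(dunn))
  })

  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}
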