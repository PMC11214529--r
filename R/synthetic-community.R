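#' Default substrate-group sample design
#'
#' A fermentation screen of four dietary fibers alone and with porcine
#' colonic mucin (PCM), one fiber with porcine gastric mucin (PGM), and the
#' two mucins alone: 11 substrate groups, each cultivated in replicate vials
#' (default triplicates).
#'
#' @param groups Character vector of substrate-group labels.
#' @param replicates Replicates per group (default 3).
#' @return Tibble with columns `sample_id`, `group`, `replicate`.
#' @export
sample_design <- function(groups = c("InuHP", "B-gluc", "PecA", "Xyl",
                                     "InuHP+PCM", "B-gluc+PCM", "PecA+PCM",
                                     "Xyl+PCM", "Xyl+PGM", "PGM", "PCM"),
                          replicates = 3L) {
  stopifnot(length(groups) >= 1L, !anyDuplicated(groups), replicates >= 1L)
  tibble::tibble(
    group = rep(groups, each = replicates),
    replicate = rep(seq_len(replicates), times = length(groups)),
    sample_id = sprintf("%s_r%d", rep(groups, each = replicates),
                        rep(seq_len(replicates), times = length(groups)))
  )[, c("sample_id", "group", "replicate")]
}

## residue sampling probabilities with a controllable combined K+R frequency;
## the remaining mass is spread uniformly over the other 18 residues
residue_probs <- function(kr_freq = 0.1) {
  stopifnot(kr_freq > 0, kr_freq < 1)
  p <- rep((1 - kr_freq) / 18, 20L)
  names(p) <- AA_STANDARD
  p[c("K", "R")] <- kr_freq / 2
  p
}

random_protein <- function(len, probs) {
  paste(sample(AA_STANDARD, len, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic multi-taxon proteome collection
#'
#' Protein sequences are drawn i.i.d. over the 20 residues with a
#' configurable combined K/R frequency, so tryptic peptide counts follow a
#' known geometric fragment-length law. Cross-taxon peptide sharing is
#' created by copying proteins between taxa on a ring: each taxon donates
#' and receives exactly `s = round(shared_fraction / (1 + shared_fraction) *
#' n_proteins_per_taxon)` proteins from its ring neighbour, which makes the
#' fraction of distinct proteins (hence, to close approximation, distinct
#' peptides) present in more than one taxon equal to `shared_fraction`, and
#' gives every taxon the same expected unique-peptide fraction. Taxa are
#' assigned to genera in consecutive pairs, so ring sharing produces both
#' within- and cross-genus shared peptides.
#'
#' @param n_taxa Number of bacterial taxa (>= 1).
#' @param n_proteins_per_taxon Proteins per taxon (default 30).
#' @param length_distribution List with `mean`, `sd`, `min` for protein
#'   lengths (normal, truncated below at `min`).
#' @param shared_fraction Target fraction of digested peptides occurring in
#'   more than one taxon, in [0, 1).
#' @param kr_freq Combined K+R residue frequency (default 0.1, i.e. a mean
#'   tryptic fragment of ~10 residues).
#' @param seed Integer seed; identical arguments give byte-identical output.
#' @return Named list of [taxon_proteome()] objects.
#' @export
generate_taxon_proteomes <- function(n_taxa, n_proteins_per_taxon = 30L,
                                     length_distribution = list(mean = 300, sd = 60, min = 60),
                                     shared_fraction = 0, kr_freq = 0.1,
                                     seed = 1L) {
  if (n_taxa < 1L || n_proteins_per_taxon < 1L) {
    stop("`n_taxa` and `n_proteins_per_taxon` must be >= 1", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction >= 1) {
    stop("`shared_fraction` must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  probs <- residue_probs(kr_freq)
  P <- as.integer(n_proteins_per_taxon)
  s <- as.integer(round(shared_fraction / (1 + shared_fraction) * P))
  if (n_taxa == 1L) s <- 0L
  n_private <- P - s

  ## private proteins first; shared slots are filled by copying from the
  ## next taxon on the ring afterwards
  privates <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    lens <- pmax(length_distribution$min,
                 round(stats::rnorm(n_private, length_distribution$mean,
                                    length_distribution$sd)))
    privates[[i]] <- stats::setNames(
      vapply(lens, random_protein, character(1L), probs = probs),
      sprintf("p%03d", seq_len(n_private))
    )
  }
  donated <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    donor <- if (i == n_taxa) 1L else i + 1L
    pick <- if (s > 0L) sample(seq_len(n_private), s) else integer(0L)
    donated[[i]] <- privates[[donor]][pick]
  }

  out <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    taxon_id <- sprintf("t%02d", i)
    genus <- sprintf("Genus_%02d", ceiling(i / 2))
    lineage <- c(
      kingdom = "Bacteria",
      phylum = sprintf("Phylum_%02d", ceiling(i / 8)),
      class = sprintf("Class_%02d", ceiling(i / 6)),
      order = sprintf("Order_%02d", ceiling(i / 4)),
      family = sprintf("Family_%02d", ceiling(i / 3)),
      genus = genus,
      species = sprintf("%s species_%02d", genus, i)
    )
    shared <- donated[[i]]
    if (length(shared) > 0L) {
      donor <- if (i == n_taxa) 1L else i + 1L
      names(shared) <- sprintf("shared_t%02d_%s", donor, names(shared))
    }
    proteins <- c(privates[[i]], shared)
    out[[i]] <- taxon_proteome(taxon_id, lineage, proteins)
  }
  stats::setNames(out, vapply(out, function(p) p$taxon_id, character(1L)))
}

#' Generate host background proteomes
#'
#' Two non-bacterial "taxa" (human and pig) standing in for host proteins
#' that contaminate fecal fermentation samples. They are excluded from
#' community normalization and reported separately.
#'
#' @param n_proteins Proteins per host proteome (default 20).
#' @param length_distribution As in [generate_taxon_proteomes()].
#' @param seed Integer seed.
#' @return Named list of two [taxon_proteome()] objects (`human`, `pig`).
#' @export
generate_host_proteomes <- function(n_proteins = 20L,
                                    length_distribution = list(mean = 300, sd = 60, min = 60),
                                    seed = 1L) {
  set.seed(seed + 104729L)  # offset stream from the bacterial generator
  probs <- residue_probs(0.1)
  make <- function(id, genus, species) {
    lens <- pmax(length_distribution$min,
                 round(stats::rnorm(n_proteins, length_distribution$mean,
                                    length_distribution$sd)))
    proteins <- stats::setNames(
      vapply(lens, random_protein, character(1L), probs = probs),
      sprintf("h%03d", seq_len(n_proteins))
    )
    taxon_proteome(id, c(
      kingdom = "Eukaryota", phylum = "Chordata", class = "Mammalia",
      order = if (id == "human") "Primates" else "Artiodactyla",
      family = if (id == "human") "Hominidae" else "Suidae",
      genus = genus, species = species
    ), proteins)
  }
  list(human = make("human", "Homo", "Homo sapiens"),
       pig = make("pig", "Sus", "Sus scrofa"))
}

#' Ground truth for a synthetic community
#'
#' Fixes, per sample, the relative weight of each bacterial taxon together
#' with the peptide-class detectability used by the observation simulator.
#'
#' @param design Tibble from [sample_design()].
#' @param weights Either a named numeric vector over taxon ids (used for
#'   every sample) or a samples x taxa matrix with rownames matching
#'   `design$sample_id`. Weights are normalized to sum to 1 per sample.
#' @param detectability Named numeric vector with entries `unique` and
#'   `shared` in (0, 1]: relative sampling weight of peptides by class.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `community_truth`.
#' @export
community_truth <- function(design, weights,
                            detectability = c(unique = 1, shared = 1),
                            seed = 1L) {
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  if (is.matrix(weights)) {
    W <- weights
    if (is.null(rownames(W)) || !setequal(rownames(W), design$sample_id)) {
      stop("weight matrix rownames must match design sample ids", call. = FALSE)
    }
    W <- W[design$sample_id, , drop = FALSE]
  } else {
    if (is.null(names(weights))) stop("`weights` must be named", call. = FALSE)
    W <- matrix(rep(weights, each = nrow(design)), nrow = nrow(design),
                dimnames = list(design$sample_id, names(weights)))
  }
  if (any(W < 0)) stop("weights must be >= 0", call. = FALSE)
  rs <- rowSums(W)
  if (any(rs <= 0)) stop("every sample needs positive total weight", call. = FALSE)
  W <- W / rs
  stopifnot(all(c("unique", "shared") %in% names(detectability)),
            all(detectability > 0), all(detectability <= 1))
  structure(list(design = design, weights = W,
                 detectability = detectability[c("unique", "shared")],
                 seed = seed),
            class = "community_truth")
}

#' Simulate a peptide observation table
#'
#' Stands in for search-engine evidence output: rows of (sample, peptide,
#' intensity). For each sample, `depth` peptide observations are drawn; each
#' is a host peptide with probability `background_fraction` (split evenly
#' between the host proteomes), otherwise a bacterial peptide from a taxon
#' chosen by its ground-truth weight. Within a taxon, peptides are drawn
#' uniformly from its digest (weighted by class detectability). Intensities
#' are lognormal with mean `base_intensity` and coefficient of variation
#' `intensity_noise`; `intensity_noise = 0` gives constant intensities, the
#' noiseless condition used for recovery checks.
#'
#' @param proteomes Bacterial proteomes (named list of [taxon_proteome()]).
#' @param truth A [community_truth()] object; all its taxa must be present
#'   in `proteomes`.
#' @param depth Observations per sample (>= 0).
#' @param intensity_noise Lognormal coefficient of variation (default 0.3).
#' @param background_fraction Probability an observation is host-derived
#'   (default 0.03; host proteins average a few percent of identifications
#'   in fecal metaproteomes).
#' @param hosts Host proteomes from [generate_host_proteomes()]; required
#'   when `background_fraction > 0`.
#' @param base_intensity Mean intensity (arbitrary units, default 1e6).
#' @param index Optional prebuilt default-parameter [build_peptide_index()]
#'   over `proteomes` (built internally when absent; used for peptide class
#'   detectability weighting).
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `peptide`, `intensity`, plus a `taxon_id`
#'   column recording the true generating taxon (ground truth for tests;
#'   downstream consumers ignore it).
#' @export
simulate_peptide_observations <- function(proteomes, truth, depth = 2000L,
                                          intensity_noise = 0.3,
                                          background_fraction = 0.03,
                                          hosts = NULL,
                                          base_intensity = 1e6,
                                          index = NULL, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"), depth >= 0L,
            intensity_noise >= 0, background_fraction >= 0,
            background_fraction < 1)
  taxa <- colnames(truth$weights)
  missing <- setdiff(taxa, names(proteomes))
  if (length(missing) > 0L) {
    stop("taxa in truth absent from proteomes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (background_fraction > 0 && is.null(hosts)) {
    stop("`hosts` required when background_fraction > 0", call. = FALSE)
  }
  empty <- tibble::tibble(sample_id = character(), peptide = character(),
                          intensity = numeric(), taxon_id = character())
  if (depth == 0L || nrow(truth$design) == 0L) return(empty)

  if (is.null(index)) index <- build_peptide_index(proteomes)
  ## per-taxon digest with class-detectability sampling weights
  occ <- index$peptides
  n_taxa_per_pep <- table(unique(occ[, c("peptide", "taxon_id")])$peptide)
  pools <- lapply(taxa, function(tid) {
    peps <- unique(occ$peptide[occ$taxon_id == tid])
    if (length(peps) == 0L) stop("taxon ", tid, " digests to no peptides",
                                 call. = FALSE)
    cls <- ifelse(n_taxa_per_pep[peps] > 1L, "shared", "unique")
    list(peptides = peps, w = unname(truth$detectability[cls]))
  })
  names(pools) <- taxa
  host_pools <- if (!is.null(hosts)) {
    lapply(hosts, function(h) {
      unique(unlist(lapply(h$proteins, tryptic_digest), use.names = FALSE))
    })
  } else list()

  set.seed(seed)
  sdlog <- sqrt(log(1 + intensity_noise^2))
  out <- vector("list", nrow(truth$design))
  for (i in seq_len(nrow(truth$design))) {
    sid <- truth$design$sample_id[i]
    w <- truth$weights[sid, ]
    is_host <- stats::runif(depth) < background_fraction
    n_bact <- sum(!is_host)
    pick <- sample(taxa, n_bact, replace = TRUE, prob = w)
    peptide <- character(depth)
    origin <- character(depth)
    bact_idx <- which(!is_host)
    for (tid in unique(pick)) {
      rows <- bact_idx[pick == tid]
      pool <- pools[[tid]]
      peptide[rows] <- sample(pool$peptides, length(rows), replace = TRUE,
                              prob = pool$w)
      origin[rows] <- tid
    }
    if (any(is_host)) {
      hnames <- names(host_pools)
      hpick <- sample(hnames, sum(is_host), replace = TRUE)
      hidx <- which(is_host)
      for (hn in unique(hpick)) {
        rows <- hidx[hpick == hn]
        peptide[rows] <- sample(host_pools[[hn]], length(rows), replace = TRUE)
        origin[rows] <- hn
      }
    }
    intensity <- if (intensity_noise == 0) {
      rep(base_intensity, depth)
    } else {
      ## meanlog chosen so the lognormal mean equals base_intensity
      stats::rlnorm(depth, log(base_intensity) - sdlog^2 / 2, sdlog)
    }
    out[[i]] <- tibble::tibble(sample_id = sid, peptide = peptide,
                               intensity = intensity, taxon_id = origin)
  }
  dplyr::bind_rows(out)
}

## truncated-normal sampler via inverse CDF on [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(hi, max(lo, mean)), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate de novo peptide calls with ALC scores
#'
#' Copies the distinct (sample, peptide) pairs of an observation table,
#' injects single-residue substitutions at the stated per-peptide rate
#' (replacements are drawn uniformly from the other 19 residues, so I/L
#' swaps are always possible), and attaches average local confidence (ALC)
#' scores from a truncated normal on [0, 100].
#'
#' @param observations Tibble from [simulate_peptide_observations()].
#' @param alc_mean,alc_sd Parameters of the truncated-normal ALC
#'   distribution (defaults 88 and 8).
#' @param substitution_rate Probability a peptide carries one substituted
#'   residue, in [0, 1].
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `peptide`, `alc`.
#' @export
simulate_denovo_peptides <- function(observations, alc_mean = 88,
                                     alc_sd = 8, substitution_rate = 0,
                                     seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("`substitution_rate` must be in [0, 1]", call. = FALSE)
  }
  base <- dplyr::distinct(observations[, c("sample_id", "peptide")])
  set.seed(seed)
  n <- nrow(base)
  peptide <- base$peptide
  if (n > 0L && substitution_rate > 0) {
    mutate_rows <- which(stats::runif(n) < substitution_rate)
    for (r in mutate_rows) {
      chars <- strsplit(peptide[r], "", fixed = TRUE)[[1L]]
      pos <- sample.int(length(chars), 1L)
      chars[pos] <- sample(setdiff(AA_STANDARD, chars[pos]), 1L)
      peptide[r] <- paste(chars, collapse = "")
    }
  }
  tibble::tibble(
    sample_id = base$sample_id,
    peptide = peptide,
    alc = rtruncnorm(n, alc_mean, alc_sd, 0, 100)
  )
}

#' Simulate an isothermal microcalorimetry series
#'
#' Heat flow is proportional to the growth rate of a logistic biomass curve:
#' a culture producing `biomass_yield` grams of dry biomass releases
#' `heat_yield` joules per gram, so the closed-form accumulated heat is
#' `Q(t) = heat_yield * (X(t) - X0)` with final value
#' `heat_yield * biomass_yield`. Optional additive Gaussian noise on the
#' heat-flow channel.
#'
#' @param growth_rate Logistic rate r (per hour, default 0.35).
#' @param biomass_yield Total dry biomass produced over the run (g, default
#'   1.5e-3 for a 2 mL vial).
#' @param x0_fraction Initial biomass as a fraction of the carrying capacity
#'   (default 0.01).
#' @param duration_h Run length in hours (default 64, the incubation used
#'   for fecal fermentations).
#' @param step_min Sampling interval in minutes (default 5).
#' @param noise_uw SD of additive heat-flow noise in uW (default 0).
#' @param heat_yield Heat released per gram of biomass (J/g, default 4000).
#' @param seed Integer seed (used only when `noise_uw > 0`).
#' @return An object of class `calorimetry_series`: tibble `time_h`,
#'   `heatflow_uW` with the generating parameters stored as attributes,
#'   including `q_final_J`, the closed-form final accumulated heat.
#' @export
simulate_calorimetry_series <- function(growth_rate = 0.35,
                                        biomass_yield = 1.5e-3,
                                        x0_fraction = 0.01,
                                        duration_h = 64, step_min = 5,
                                        noise_uw = 0, heat_yield = 4000,
                                        seed = 1L) {
  stopifnot(duration_h > 0, step_min > 0, biomass_yield >= 0,
            x0_fraction > 0, x0_fraction < 1)
  time_h <- seq(0, duration_h, by = step_min / 60)
  if (growth_rate <= 0 || biomass_yield == 0) {
    p_uw <- rep(0, length(time_h))
    q_final <- 0
  } else {
    ## X(t) = K / (1 + A exp(-r t)); total produced = K - X0 = biomass_yield
    K <- biomass_yield / (1 - x0_fraction)
    x0 <- K * x0_fraction
    A <- (K - x0) / x0
    x <- K / (1 + A * exp(-growth_rate * time_h))
    dxdt <- growth_rate * x * (1 - x / K)                # g/h
    p_uw <- heat_yield * dxdt * 1e6 / 3600               # J/h -> uW
    q_final <- heat_yield * (x[length(x)] - x0)
  }
  if (noise_uw > 0) {
    set.seed(seed)
    p_uw <- p_uw + stats::rnorm(length(p_uw), 0, noise_uw)
  }
  out <- tibble::tibble(time_h = time_h, heatflow_uW = p_uw)
  structure(out, class = c("calorimetry_series", class(out)),
            growth_rate = growth_rate, biomass_yield = biomass_yield,
            heat_yield = heat_yield, q_final_J = q_final)
}

#' Simulate per-sample culture chemistry tables
#'
#' Generates short-chain fatty acid concentrations (mM), headspace gas
#' partial pressures (atm) and pH per sample, with additive group-level
#' effects injected on chosen metabolites so downstream nonparametric tests
#' have a known signal (set all effects to zero for null calibration).
#'
#' @param design Tibble from [sample_design()].
#' @param effects Named list: metabolite -> named numeric vector of additive
#'   group shifts (mM). Default: no injected effects.
#' @param baseline Named numeric of baseline SCFA concentrations (mM).
#' @param noise_sd SD of additive measurement noise on metabolites (mM).
#' @param gas_baseline Named numeric of baseline partial pressures (atm).
#' @param gas_cv Lognormal CV of gas pressures (keeps pressures >= 0).
#' @param ph_baseline,ph_sd Baseline pH and its noise SD; sole-mucin groups
#'   (`PGM`, `PCM`) are shifted up by `ph_mucin_shift` to emulate
#'   proteolytic ammonia release.
#' @param ph_mucin_shift Additive pH shift for sole-mucin groups.
#' @param seed Integer seed.
#' @return List of tibbles: `metabolites` (sample_id, metabolite, conc_mM),
#'   `gases` (sample_id, species, p_atm), `ph` (sample_id, pH).
#' @export
simulate_culture_chemistry <- function(design, effects = list(),
                                       baseline = c(acetate = 20, propionate = 8,
                                                    butyrate = 6, succinate = 0.5),
                                       noise_sd = 1,
                                       gas_baseline = c(CO2 = 0.30, H2 = 0.15,
                                                        CH4 = 0.02, H2S = 0.005),
                                       gas_cv = 0.1,
                                       ph_baseline = 6.3, ph_sd = 0.15,
                                       ph_mucin_shift = 0.7, seed = 1L) {
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  set.seed(seed)
  n <- nrow(design)

  met <- tidyr::expand_grid(sample_id = design$sample_id,
                            metabolite = names(baseline))
  met <- dplyr::left_join(met, design[, c("sample_id", "group")],
                          by = "sample_id")
  met$conc_mM <- baseline[met$metabolite]
  for (m in names(effects)) {
    shift <- effects[[m]]
    hit <- met$metabolite == m & met$group %in% names(shift)
    met$conc_mM[hit] <- met$conc_mM[hit] + shift[met$group[hit]]
  }
  met$conc_mM <- pmax(0, met$conc_mM + stats::rnorm(nrow(met), 0, noise_sd))
  ## below-detection concentrations are reported at an explicit floor
  met$conc_mM[met$conc_mM < 0.001] <- 0

  gas <- tidyr::expand_grid(sample_id = design$sample_id,
                            species = names(gas_baseline))
  sdlog <- sqrt(log(1 + gas_cv^2))
  gas$p_atm <- gas_baseline[gas$species] *
    stats::rlnorm(nrow(gas), -sdlog^2 / 2, sdlog)

  mucin_only <- design$group %in% c("PGM", "PCM")
  ph <- tibble::tibble(
    sample_id = design$sample_id,
    pH = ph_baseline + ifelse(mucin_only, ph_mucin_shift, 0) +
      stats::rnorm(n, 0, ph_sd)
  )
  list(metabolites = met[, c("sample_id", "metabolite", "conc_mM")],
       gases = gas, ph = ph)
}
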