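toy_obs <- function(...) {
  tibble::tibble(...)
}

test_that("unique-peptide abundances are intensity shares over bacteria", {
  idx <- build_peptide_index(toy_proteomes())
  obs <- toy_obs(
    sample_id = "s1",
    peptide = c("AAAAAAK", "EEEEEEEK", "CCCCCCCK"),
    intensity = c(100, 300, 1e6)  # shared peptide must not matter
  )
  prof <- quantify_unique_peptide_profile(obs, idx)
  expect_equal(prof$abundance[prof$taxon == "GenX alpha"], 0.25)
  expect_equal(prof$abundance[prof$taxon == "GenX beta"], 0.75)
  # adding another shared peptide changes no abundance
  obs2 <- dplyr::bind_rows(obs, toy_obs(sample_id = "s1",
                                        peptide = "DDDDDDDR",
                                        intensity = 5e5))
  prof2 <- quantify_unique_peptide_profile(obs2, idx)
  expect_equal(prof2$abundance, prof$abundance)
  # technical-injection duplicate rows are summed, shares unchanged
  prof3 <- quantify_unique_peptide_profile(dplyr::bind_rows(obs, obs), idx)
  expect_equal(prof3$abundance, prof$abundance)
})

test_that("samples with only shared peptides are flagged invalid", {
  idx <- build_peptide_index(toy_proteomes())
  obs <- toy_obs(sample_id = c("s1", "s2"),
                 peptide = c("CCCCCCCK", "AAAAAAK"),
                 intensity = c(10, 10))
  expect_warning(prof <- quantify_unique_peptide_profile(obs, idx),
                 "flagged invalid")
  expect_false(prof$valid[prof$sample_id == "s1"])
  expect_true(all(prof$valid[prof$sample_id == "s2"]))
  expect_error(quantify_unique_peptide_profile(obs[0, ], idx), "empty")
})

test_that("profiles sum to one per sample through every transformation", {
  pr <- random_fixture(909)
  idx <- build_peptide_index(pr)
  design <- sample_design(c("g1", "g2"), replicates = 2)
  truth <- community_truth(
    design, stats::setNames(seq_along(pr), names(pr))
  )
  obs <- simulate_peptide_observations(pr, truth, depth = 3000,
                                       background_fraction = 0, seed = 909)
  prof <- quantify_unique_peptide_profile(obs, idx)
  sums <- tapply(prof$abundance, prof$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  gen <- aggregate_to_rank(prof, "genus")
  gsums <- tapply(gen$abundance, gen$sample_id, sum)
  expect_true(all(abs(gsums - 1) < 1e-9))
  summ <- summarize_replicates(gen, design, top_n = 3)
  ssums <- tapply(summ$mean_abundance, summ$group, sum)
  expect_true(all(abs(ssums - 1) < 1e-9))
})

test_that("rank aggregation matches brute-force grouping", {
  idx <- build_peptide_index(toy_proteomes())
  obs <- toy_obs(sample_id = "s1",
                 peptide = c("AAAAAAK", "EEEEEEEK", "HHHHHHHK"),
                 intensity = c(20, 30, 50))
  prof <- quantify_unique_peptide_profile(obs, idx)
  gen <- aggregate_to_rank(prof, "genus")
  # two GenX species at 0.2 and 0.3 roll up to genus 0.5
  expect_equal(gen$abundance[gen$taxon == "GenX"], 0.5)
  expect_equal(gen$abundance[gen$taxon == "GenY"], 0.5)
  # aggregation to the profile's own rank is the identity
  expect_equal(aggregate_to_rank(prof, "species"), prof)
  # finer target rank is a parameter error
  expect_error(aggregate_to_rank(gen, "species"), "finer")
})

test_that("replicate summary pools everything beyond top_n into 'other'", {
  set.seed(11)
  n_taxa <- 20L
  design <- sample_design(c("g1", "g2"), replicates = 3)
  # build a profile tibble directly: random simplex per sample
  rows <- lapply(design$sample_id, function(sid) {
    w <- stats::rgamma(n_taxa, 1)
    tibble::tibble(sample_id = sid, taxon = sprintf("sp%02d", 1:n_taxa),
                   rank = "species", abundance = w / sum(w),
                   n_unique_peptides = 5L, valid = TRUE)
  })
  prof <- dplyr::bind_rows(rows)
  lin <- tibble::tibble(taxon_id = sprintf("t%02d", 1:n_taxa),
                        kingdom = "Bacteria", phylum = "P", class = "C",
                        order = "O", family = "F", genus = "G",
                        species = sprintf("sp%02d", 1:n_taxa))
  prof <- structure(prof, class = c("community_profile", class(prof)),
                    rank = "species", lineages = lin)
  out <- summarize_replicates(prof, design, top_n = 14)
  # brute force: per-group means, grand-mean ranking, pool ranks 15..20
  means <- aggregate(abundance ~ taxon + sample_id, data = prof, FUN = sum)
  means$group <- design$group[match(means$sample_id, design$sample_id)]
  gm <- aggregate(abundance ~ taxon + group, data = means, FUN = mean)
  grand <- aggregate(abundance ~ taxon, data = gm, FUN = mean)
  keep <- grand$taxon[order(-grand$abundance)][1:14]
  for (g in c("g1", "g2")) {
    want_other <- sum(gm$abundance[gm$group == g & !gm$taxon %in% keep])
    got_other <- out$mean_abundance[out$group == g & out$taxon == "other"]
    expect_equal(got_other, want_other)
  }
  # identical replicates: mean equals each replicate; top_n = all -> other 0
  one <- prof[prof$sample_id == design$sample_id[1L], ]
  rep_prof <- dplyr::bind_rows(lapply(design$sample_id, function(sid) {
    dplyr::mutate(one, sample_id = sid)
  }))
  rep_prof <- structure(rep_prof, class = class(prof), rank = "species",
                        lineages = lin)
  out2 <- summarize_replicates(rep_prof, design, top_n = n_taxa)
  expect_equal(out2$mean_abundance[out2$taxon == "other"], c(0, 0))
  m1 <- out2[out2$group == "g1" & out2$taxon != "other", ]
  expect_equal(stats::setNames(m1$mean_abundance, m1$taxon)[one$taxon],
               stats::setNames(one$abundance, one$taxon))
})

test_that("taxon relabeling permutes outputs identically", {
  idx <- build_peptide_index(toy_proteomes())
  obs <- toy_obs(sample_id = "s1",
                 peptide = c("AAAAAAK", "EEEEEEEK", "HHHHHHHK"),
                 intensity = c(10, 60, 30))
  prof <- quantify_unique_peptide_profile(obs, idx)
  ab <- stats::setNames(prof$abundance, prof$taxon)
  expect_equal(unname(ab[c("GenX alpha", "GenX beta", "GenY gamma")]),
               c(0.1, 0.6, 0.3))
})

test_that("host intensity is reported separately, outside the simplex", {
  pr <- toy_proteomes()
  hosts <- generate_host_proteomes(n_proteins = 3, seed = 1)
  idx <- build_peptide_index(c(pr, hosts))
  hpep <- tryptic_digest(hosts$human$proteins[[1L]])[1L]
  obs <- toy_obs(sample_id = "s1",
                 peptide = c("AAAAAAK", "EEEEEEEK", hpep),
                 intensity = c(50, 50, 100))
  prof <- quantify_unique_peptide_profile(obs, idx)
  expect_equal(sum(prof$abundance), 1)  # bacteria only
  expect_false(any(prof$taxon %in% c("Homo sapiens", "Sus scrofa")))
  expect_equal(attr(prof, "host")$host_share, 0.5)
})
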