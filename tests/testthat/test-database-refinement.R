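mk_lineages <- function() {
  tibble::tibble(
    taxon_id = c("bact1", "bact2", "bact3", "arch1", "bact16s", "human", "pig"),
    kingdom = c("Bacteria", "Bacteria", "Bacteria", "Archaea", "Bacteria",
                "Eukaryota", "Eukaryota"),
    phylum = "P", class = "C", order = "O", family = "F", genus = "G",
    species = c("Bact one", "Bact two", "Bact three", "Arch one",
                "Bact sixteen", "Homo sapiens", "Sus scrofa")
  )
}

mk_evidence <- function(design, counts) {
  # counts: named list taxon -> sample ids with >=1 specific peptide
  rows <- lapply(names(counts), function(tid) {
    tibble::tibble(taxon_id = tid, sample_id = counts[[tid]],
                   n_specific_peptides = 5L, identified = TRUE)
  })
  dplyr::bind_rows(rows)
}

test_that("ALC filtering is boundary-inclusive and schema-checked", {
  dn <- tibble::tibble(sample_id = "s1", peptide = c("a", "b", "c"),
                       alc = c(79.9, 80.0, 95))
  expect_message(kept <- filter_denovo_by_alc(dn, 80), "1 de novo")
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$alc >= 80))
  expect_equal(nrow(suppressMessages(filter_denovo_by_alc(dn, 0))), 3L)
  expect_equal(nrow(suppressMessages(filter_denovo_by_alc(dn, 100))), 0L)
  expect_error(filter_denovo_by_alc(dn[, 1:2]), "alc")
  expect_error(filter_denovo_by_alc(dn, 101), "\\[0, 100\\]")
})

test_that("taxon evidence tally counts species-unique peptides only", {
  pr <- toy_proteomes()
  idx <- build_peptide_index(pr, il_collapse = TRUE)
  dn <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s2", "s1"),
    peptide = c("AAAAAAK",    # unique to A
                "CCCCCCCK",   # shared A/B: contributes to neither
                "AAAAAAK",    # unique to A, second sample
                "HHHHHHHK",   # unique to C
                "ZZZZZZZZ")   # unmatched
  )
  tally <- tally_taxon_evidence(dn, idx)
  a <- tally[tally$taxon_id == "A", ]
  expect_setequal(a$sample_id, c("s1", "s2"))
  expect_true(all(a$n_specific_peptides == 1L))
  expect_false("B" %in% tally$taxon_id)
  expect_equal(tally$sample_id[tally$taxon_id == "C"], "s2")
})

test_that("tally equals a brute-force recount on a random fixture", {
  pr <- random_fixture(404)
  idx <- build_peptide_index(pr, il_collapse = TRUE)
  set.seed(404)
  peps <- sample(unique(idx$peptides$peptide), 200, replace = TRUE)
  dn <- tibble::tibble(sample_id = sample(c("s1", "s2", "s3"), 200,
                                          replace = TRUE),
                       peptide = peps)
  tally <- tally_taxon_evidence(dn, idx)
  # brute force: count distinct species-unique peptides per taxon and sample
  occ <- unique(as.data.frame(idx$peptides[, c("peptide", "taxon_id")]))
  owners <- split(occ$taxon_id, occ$peptide)
  rows <- unique(dn)
  for (tid in unique(idx$peptides$taxon_id)) {
    for (sid in c("s1", "s2", "s3")) {
      want <- sum(vapply(rows$peptide[rows$sample_id == sid], function(p) {
        o <- owners[[p]]
        !is.null(o) && length(unique(o)) == 1L && o[1L] == tid
      }, logical(1L)))
      got <- tally$n_specific_peptides[tally$taxon_id == tid &
                                         tally$sample_id == sid]
      expect_equal(if (length(got) == 0L) 0L else got, as.integer(want))
    }
  }
})

test_that("retention rules keep exactly the rule-implied taxon set", {
  design <- sample_design(groups = c("g1", "g2"), replicates = 3)
  sid <- function(g, r) sprintf("%s_r%d", g, r)
  evidence <- mk_evidence(design, list(
    bact1 = c(sid("g1", 1), sid("g1", 2), sid("g1", 3)),  # 3 in g1: kept
    bact2 = c(sid("g1", 1), sid("g1", 2), sid("g2", 1), sid("g2", 2)),  # 2+2: removed
    arch1 = design$sample_id,                             # archaeon: removed
    bact3 = c(sid("g2", 1), sid("g2", 2), sid("g2", 3))   # 3 in g2: kept
  ))
  out <- refine_taxon_set(evidence, design, mk_lineages(),
                          min_samples_per_group = 3,
                          taxa_16s = "bact16s")
  expect_setequal(out$taxon_id,
                  c("bact1", "bact3", "bact16s", "human", "pig"))
  expect_equal(out$provenance[out$taxon_id == "bact1"], "proteomic")
  expect_equal(out$provenance[out$taxon_id == "bact16s"], "16S")
  expect_equal(out$provenance[out$taxon_id == "human"], "host")
  # a proteomically-found taxon also in the 16S list is flagged both
  both <- refine_taxon_set(evidence, design, mk_lineages(),
                           taxa_16s = c("bact1", "bact16s"))
  expect_equal(both$provenance[both$taxon_id == "bact1"], "both")
})

test_that("16S taxa without proteomes are warned about, not dropped silently", {
  design <- sample_design(groups = "g1", replicates = 3)
  evidence <- mk_evidence(design, list(bact1 = design$sample_id))
  expect_warning(
    out <- refine_taxon_set(evidence, design, mk_lineages(),
                            taxa_16s = "Unknownius totally"),
    "no available proteome"
  )
  expect_equal(attr(out, "unresolved"), "Unknownius totally")
})

test_that("refinement is idempotent and monotone in the sample threshold", {
  design <- sample_design(groups = c("g1", "g2"), replicates = 3)
  set.seed(7)
  samples <- design$sample_id
  evidence <- mk_evidence(design, list(
    bact1 = sample(samples, 5), bact2 = sample(samples, 3),
    bact3 = sample(samples, 2), arch1 = samples
  ))
  lin <- mk_lineages()
  r1 <- refine_taxon_set(evidence, design, lin, min_samples_per_group = 3)
  # rerun on the evidence restricted to retained taxa: nothing changes
  ev2 <- evidence[evidence$taxon_id %in% r1$taxon_id, ]
  r2 <- refine_taxon_set(ev2, design, lin, min_samples_per_group = 3)
  expect_equal(r1, r2, ignore_attr = TRUE)
  # lowering the threshold never removes a retained taxon
  for (thr in c(2L, 1L)) {
    lo <- refine_taxon_set(evidence, design, lin, min_samples_per_group = thr)
    expect_true(all(r1$taxon_id %in% lo$taxon_id))
  }
  # the strict "all groups" reading removes taxa missing from any group
  all_rule <- refine_taxon_set(evidence, design, lin,
                               min_samples_per_group = 1,
                               group_rule = "all")
  any_rule <- refine_taxon_set(evidence, design, lin,
                               min_samples_per_group = 1)
  expect_true(all(all_rule$taxon_id %in% any_rule$taxon_id))
})

test_that("database export is additive, ordered and deterministic", {
  pr <- toy_proteomes()
  retained <- tibble::tibble(taxon_id = c("B", "A", "C"),
                             provenance = c("proteomic", "both", "16S"))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "db1.fasta"); m1 <- file.path(d, "m1.tsv")
  man <- export_refined_database(retained, pr, f1, m1)
  expect_equal(man$taxon_id, c("A", "B", "C"))  # deterministic order
  expect_equal(sum(man$n_proteins), 5L)         # 2 + 2 + 1 records
  fa <- Biostrings::readAAStringSet(f1)
  expect_equal(length(fa), 5L)
  # re-export is byte-identical
  f2 <- file.path(d, "db2.fasta"); m2 <- file.path(d, "m2.tsv")
  export_refined_database(retained, pr, f2, m2)
  expect_identical(readLines(f1), readLines(f2))
  # unresolvable taxon listed in manifest, absent from FASTA
  r2 <- dplyr::bind_rows(retained,
                         tibble::tibble(taxon_id = "ghost",
                                        provenance = "16S"))
  man2 <- export_refined_database(r2, pr, file.path(d, "db3.fasta"),
                                  file.path(d, "m3.tsv"))
  expect_true(is.na(man2$n_proteins[man2$taxon_id == "ghost"]))
  expect_equal(length(Biostrings::readAAStringSet(file.path(d, "db3.fasta"))),
               5L)
})
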