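test_that("consensus filter keeps families agreed on by enough tools", {
  hits <- tibble::tibble(
    protein_id = c("X", "X", "Y", "Y", "Y", "Z"),
    family = c("GH2", "GH2", "GH2", "GH3", "GH3", "GH13"),
    tool = c("hmm", "diamond", "hmm", "diamond", "peptide-pattern",
             "peptide-pattern")
  )
  out <- consensus_cazyme_filter(hits, min_tools = 2)
  expect_equal(out$family[out$protein_id == "X"], "GH2")
  expect_equal(out$family[out$protein_id == "Y"], "GH3")
  expect_false("Z" %in% out$protein_id)
  # duplicate reports by one tool count once
  dup <- tibble::tibble(protein_id = "W", family = "GH5",
                        tool = c("hmm", "hmm"))
  expect_equal(nrow(consensus_cazyme_filter(dup, 2)), 0L)
  expect_error(consensus_cazyme_filter(
    tibble::tibble(protein_id = "a", family = "GH1", tool = "blastx"), 2
  ), "unknown annotation tool")
  expect_error(consensus_cazyme_filter(
    tibble::tibble(protein_id = "a", family = "", tool = "hmm"), 1
  ), "empty CAZy family")
})

test_that("sulfatase hits pass through single-source, flagged distinctly", {
  hits <- tibble::tibble(protein_id = c("X", "X", "S"),
                         family = c("GH2", "GH2", "S1_4"),
                         tool = c("hmm", "diamond", "sulfatase"))
  out <- consensus_cazyme_filter(hits, min_tools = 2)
  expect_setequal(out$source, c("cazy-consensus", "sulfatase"))
  expect_equal(out$family[out$source == "sulfatase"], "S1_4")
})

test_that("raising min_tools never adds annotations; min_tools=1 is the union", {
  set.seed(31)
  tools <- c("hmm", "diamond", "peptide-pattern")
  for (i in 1:100) {
    n <- sample(5:25, 1L)
    hits <- tibble::tibble(
      protein_id = sample(letters[1:5], n, replace = TRUE),
      family = sample(paste0("GH", 1:4), n, replace = TRUE),
      tool = sample(tools, n, replace = TRUE)
    )
    keys <- lapply(1:3, function(k) {
      out <- consensus_cazyme_filter(hits, min_tools = k)
      paste(out$protein_id, out$family)
    })
    expect_true(all(keys[[2]] %in% keys[[1]]))
    expect_true(all(keys[[3]] %in% keys[[2]]))
    expect_setequal(keys[[1]],
                    unique(paste(hits$protein_id, hits$family)))
  }
})

test_that("peptide-enzyme matching is exact tryptic membership, de-duplicated", {
  cat <- reaction_catalog(tibble::tibble(
    reaction = c("r1", "r1", "r2"),
    taxon_id = c("A", "A", "B"),
    enzyme_id = c("e1", "e2", "e3"),
    sequence = c("AAAAAAKGGGGGGR", "AAAAAAKWWWWWWR", "CCCCCCCKDDDDDDDR")
  ))
  obs <- tibble::tibble(sample_id = "s1",
                        peptide = c("AAAAAAK", "CCCCCCCK", "NOTAPEPK"),
                        intensity = 1)
  m <- match_peptides_to_reference_enzymes(obs, cat)
  # AAAAAAK hits both enzymes of (A, r1) but is emitted once
  expect_equal(nrow(m[m$peptide == "AAAAAAK", ]), 1L)
  expect_equal(m$reaction[m$peptide == "CCCCCCCK"], "r2")
  expect_false("NOTAPEPK" %in% m$peptide)
  # substring mode is at least as sensitive
  m2 <- match_peptides_to_reference_enzymes(obs, cat, mode = "substring")
  expect_true(all(paste(m$peptide, m$reaction) %in%
                    paste(m2$peptide, m2$reaction)))
})

test_that("match table equals a brute-force digest-membership scan", {
  pr <- random_fixture(512)
  cat_rows <- list()
  k <- 0L
  for (tid in names(pr)[1:min(3, length(pr))]) {
    k <- k + 1L
    cat_rows[[k]] <- tibble::tibble(
      reaction = paste0("r", k), taxon_id = tid,
      enzyme_id = paste0("e", k),
      sequence = pr[[tid]]$proteins[[1L]]
    )
  }
  cat <- reaction_catalog(dplyr::bind_rows(cat_rows))
  idx <- build_peptide_index(pr)
  set.seed(512)
  obs <- tibble::tibble(
    sample_id = sample(c("s1", "s2"), 150, replace = TRUE),
    peptide = sample(unique(idx$peptides$peptide), 150, replace = TRUE),
    intensity = 1
  )
  got <- match_peptides_to_reference_enzymes(obs, cat)
  want <- list()
  for (i in seq_len(nrow(cat))) {
    prods <- brute_digest(cat$sequence[i])
    rows <- unique(obs[obs$peptide %in% prods, c("sample_id", "peptide")])
    if (nrow(rows) > 0L) {
      want[[i]] <- tibble::tibble(sample_id = rows$sample_id,
                                  peptide = rows$peptide,
                                  taxon_id = cat$taxon_id[i],
                                  reaction = cat$reaction[i])
    }
  }
  want <- dplyr::distinct(dplyr::bind_rows(want))
  key <- function(d) sort(paste(d$sample_id, d$peptide, d$taxon_id,
                                d$reaction))
  expect_equal(key(got), key(want))
})

test_that("copy numbers count distinct peptides and sum over groups", {
  matches <- tibble::tibble(
    sample_id = "s1",
    peptide = c("P1AAAAA", "P2AAAAA", "P3AAAAA", "P4AAAAA", "P5AAAAA"),
    taxon_id = c("A", "A", "A", "B", "B"),
    reaction = "r1"
  )
  by_taxon <- enzyme_copy_numbers(matches, scope = "taxon")
  cnt <- by_taxon$counts
  expect_equal(cnt$n_peptides[cnt$unit == "A"], 3L)
  expect_equal(cnt$n_peptides[cnt$unit == "B"], 2L)
  # duplicating a match row never changes any count
  dup <- enzyme_copy_numbers(dplyr::bind_rows(matches, matches[1, ]),
                             scope = "taxon")
  expect_equal(dup$counts, by_taxon$counts)
  # group scope: A and B in one group sum to 5
  gm <- tibble::tibble(taxon_id = c("A", "B"),
                       group = c("Bacteroides", "Bacteroides"))
  by_group <- enzyme_copy_numbers(matches, scope = "group", group_map = gm)
  expect_equal(by_group$counts$n_peptides[by_group$counts$unit == "Bacteroides"],
               5L)
  # missing taxon in the map is an error listing the offender
  expect_error(enzyme_copy_numbers(matches, scope = "group",
                                   group_map = gm[1, ]), "B")
  # empty match table still yields the full zero grid
  empty <- enzyme_copy_numbers(matches[0, ], scope = "group", group_map = gm,
                               design = sample_design("g", 2),
                               reactions = c("r1", "r2"))
  expect_equal(nrow(empty$counts), length(unique(gm$group)) * 2L * 2L)
  expect_true(all(empty$counts$n_peptides == 0L))
})

test_that("group additivity: group matrix equals the sum of member taxa", {
  pr <- random_fixture(613)
  idx <- build_peptide_index(pr)
  design <- sample_design(c("g1", "g2"), replicates = 2)
  set.seed(613)
  obs <- tibble::tibble(
    sample_id = sample(design$sample_id, 300, replace = TRUE),
    peptide = sample(unique(idx$peptides$peptide), 300, replace = TRUE),
    intensity = 1
  )
  cat <- reaction_catalog(dplyr::bind_rows(lapply(names(pr), function(tid) {
    tibble::tibble(reaction = "r1", taxon_id = tid,
                   enzyme_id = paste0(tid, "_e"),
                   sequence = pr[[tid]]$proteins[[2L]])
  })))
  matches <- match_peptides_to_reference_enzymes(obs, cat)
  expect_gt(nrow(matches), 0L)
  gmap <- default_metabolic_group_map(names(pr))
  tax <- enzyme_copy_numbers(matches, "taxon", design = design)
  grp <- enzyme_copy_numbers(matches, "group", group_map = gmap,
                             design = design)
  tc <- tax$counts
  tc$group <- assign_metabolic_group(tc$unit, gmap)
  want <- aggregate(n_peptides ~ group + reaction + sample_id, data = tc,
                    FUN = sum)
  for (i in seq_len(nrow(want))) {
    got <- grp$counts$n_peptides[
      grp$counts$unit == want$group[i] &
        grp$counts$reaction == want$reaction[i] &
        grp$counts$sample_id == want$sample_id[i]]
    expect_equal(got, want$n_peptides[i])
  }
})

test_that("metabolic group assignment is total with explicit unassigned", {
  gmap <- default_metabolic_group_map(sprintf("t%02d", 1:12))
  expect_equal(sort(unique(gmap$group)),
               sort(c("Butyric", "Akkermansia", "Bifido", "Bacteroides",
                      "Enterobacteria", "Lachnoclostridium",
                      "Asaccharolytic", "Succinivorans")))
  expect_equal(assign_metabolic_group("t02", gmap), "Akkermansia")
  expect_warning(out <- assign_metabolic_group(c("t01", "mystery"), gmap),
                 "unmapped")
  expect_equal(out[2L], "unassigned")
  expect_error(assign_metabolic_group("t01",
                                      tibble::tibble(taxon_id = "t01",
                                                     group = "Fancy")),
               "unknown metabolic group")
})
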