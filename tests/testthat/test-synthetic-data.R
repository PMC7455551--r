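test_that("gen_species_tree builds the labelled backbone and is deterministic", {
  tr <- exemplar_tree()
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  # Prasinodermophyta sister to Chlorophyta+Streptophyta under Viridiplantae
  v <- viridicore:::node_id(tr, "Viridiplantae")
  ch <- viridicore:::children_of(tr, v)
  tipsets <- lapply(ch, function(c0)
    tr$tip.label[viridicore:::tips_under(tr, c0)])
  expect_true(any(vapply(tipsets, identical, logical(1), "P.coloniale")))
  expect_true(any(vapply(tipsets, setequal, logical(1),
                         c("M.commoda", "C.atmophyticus"))))
  # determinism: same call, same Newick
  expect_identical(ape::write.tree(exemplar_tree()),
                   ape::write.tree(exemplar_tree()))
  # 2 taxa: a cherry
  cherry <- gen_species_tree(c("a", "b"))
  expect_equal(ape::Ntip(cherry), 2)
  expect_equal(cherry$Nnode, 1)
  expect_error(gen_species_tree(c("a", "a")), "duplicate")
})

test_that("gen_trait_history honours Dollo constraints and flags all-absent", {
  tr <- ten_leaf_tree()
  # root gain, no losses: present everywhere
  sim <- gen_trait_history(tr, 5, gain_prob = 0, loss_prob = 0,
                           seed = 1, root_present = 1)
  expect_true(all(sim$matrix == 1L))
  expect_true(all(vapply(sim$truth, function(t) t$gain == "root",
                         logical(1))))
  # no gain possible: all-absent and flagged
  sim0 <- gen_trait_history(tr, 4, gain_prob = 0, loss_prob = 0.5,
                            seed = 2)
  expect_true(all(sim0$matrix == 0L))
  expect_true(all(vapply(sim0$truth, `[[`, logical(1), "all_absent")))
  # at most one gain per trait under dollo
  sim2 <- gen_trait_history(tr, 50, gain_prob = 0.3, loss_prob = 0.1,
                            seed = 3)
  expect_true(all(vapply(sim2$truth, function(t)
    length(t$gains) <= 1, logical(1))))
  # determinism
  again <- gen_trait_history(tr, 50, gain_prob = 0.3, loss_prob = 0.1,
                             seed = 3)
  expect_identical(sim2, again)
})

test_that("planted gain on an internal stem yields exact subtree presence", {
  tr <- exemplar_tree()
  m <- trait_matrix(matrix(c(0, 0, 0, 1, 1), 1,
                           dimnames = list("tr1", tr$tip.label)))
  em <- dollo_map(m, tr)
  expect_equal(em$events$tr1$gain, "Chlorophyta_Streptophyta")
  expect_length(em$events$tr1$losses, 0)
})

test_that("tf_fixture encodes the published group-level distribution", {
  m <- tf_fixture()
  expect_equal(dim(m), c(73L, 5L))
  expect_equal(sum(m[, "P.coloniale"]), 55)
  expect_equal(unname(m["WRKY", ]), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(unname(m["MBF1", ]), c(1L, 1L, 0L, 1L, 1L))
  # five Viridiplantae-stem gains absent from Glaucoplantae+Rhodoplantae
  vg <- c("C2C2-Dof", "WRKY", "SBP", "GARP_ARR-B", "TAZ")
  expect_true(all(m[vg, c("Rhodoplantae", "Glaucoplantae")] == 0L))
  expect_true(all(m[vg, c("P.coloniale", "Chlorophyta", "Streptophyta")]
                  == 1L))
  # the other 50 P. coloniale types occur in Glaucoplantae and/or Rhodoplantae
  others <- setdiff(rownames(m)[m[, "P.coloniale"] == 1], vg)
  expect_length(others, 50)
  expect_true(all(rowSums(m[others, c("Rhodoplantae", "Glaucoplantae"),
                            drop = FALSE]) > 0))
})

test_that("gen_orthogroup_table realises the partition spec exactly", {
  groups <- list(A = c("a1", "a2"), B = "b1", C = c("c1", "c2"))
  spec <- c("A+B+C" = 2)
  tab <- gen_orthogroup_table(spec, groups, seed = 1)
  expect_equal(nrow(tab$counts), 2)
  for (g in names(groups))
    expect_true(all(rowSums(tab$counts[, groups[[g]], drop = FALSE]) >= 1))
  # empty spec -> empty table
  empty <- gen_orthogroup_table(c(), groups)
  expect_equal(nrow(empty$counts), 0)
  # round-trip with venn_partition on the published numbers
  tab2 <- fig2a_table()
  vp <- venn_partition(tab2)
  expect_equal(vp[names(fig2a_spec())], fig2a_spec())
  expect_equal(sum(vp), nrow(tab2$counts))
  # determinism
  expect_identical(fig2a_table(3)$counts, fig2a_table(3)$counts)
})

test_that("gen_reads covers the genome at the stated depth without errors", {
  sim <- gen_reads(2e4, depth = 10, read_length = 100, error_rate = 0,
                   seed = 5)
  expect_equal(sum(nchar(sim$reads)), 2e4 * 10, tolerance = 100 / 2e5)
  # every error-free read is an exact substring of reference or its rc
  idx <- sample(seq_along(sim$reads), 25)
  rc <- viridicore:::revcomp(sim$reference)
  for (r in sim$reads[idx])
    expect_true(grepl(r, sim$reference, fixed = TRUE) ||
                grepl(r, rc, fixed = TRUE))
  # determinism and error guard
  expect_identical(gen_reads(1e4, 5, 50, 0, seed = 9)$reads,
                   gen_reads(1e4, 5, 50, 0, seed = 9)$reads)
  expect_error(gen_reads(1e4, 5, 50, error_rate = 1), "error_rate")
})

test_that("gen_proteomes plants recoverable ortholog pairs", {
  # divergence 0: identical sequences, trivially recovered
  pr0 <- gen_proteomes(5, divergence = 0, n_decoys = 0, seed = 2,
                       len_range = c(60L, 80L))
  expect_identical(unname(pr0$proteome_a), unname(pr0$proteome_b))
  rbh0 <- reciprocal_best_hits(pr0$proteome_a, pr0$proteome_b)
  expect_setequal(paste(rbh0$id_a, rbh0$id_b),
                  paste(pr0$truth$pairs$id_a, pr0$truth$pairs$id_b))
  # no families: nothing to recover
  pr_empty <- gen_proteomes(0, n_decoys = 3, seed = 4,
                            len_range = c(60L, 80L))
  expect_equal(nrow(pr_empty$truth$pairs), 0)
  expect_error(gen_proteomes(2, divergence = -1), "divergence")
  # determinism
  expect_identical(gen_proteomes(3, 0.2, 2, seed = 8),
                   gen_proteomes(3, 0.2, 2, seed = 8))
})

test_that("gen_gene_models emits coherent GFF3 with exact truth", {
  gm <- gen_gene_models(1, exon_length_law = function(n) c(100L, 200L)[seq_len(n)],
                        intron_length_law = function(n) rep(50L, n),
                        intergenic_law = function(n) rep(100L, n),
                        n_exons_law = function() 2L, seed = 1)
  expect_equal(gm$truth$exon_lengths, c(100L, 200L))
  expect_equal(gm$truth$intron_lengths, 50L)
  ss <- exon_intron_lengths(read_gene_models(gm$gff), genome = gm$genome)
  expect_equal(unname(ss$exon_stats["mean"]), 150)
  expect_equal(unname(ss$intron_stats["mean"]), 50)
  expect_equal(ss$coding_fraction, gm$truth$cds_fraction, tolerance = 1e-9)
  # no genes: empty gff, coding fraction 0
  gm0 <- gen_gene_models(0, seed = 1)
  expect_equal(nrow(gm0$gff), 0)
  expect_equal(gm0$truth$cds_fraction, 0)
})

test_that("generators are pure functions of (config, seed)", {
  tr <- exemplar_tree()
  a <- gen_alignment_with_synapomorphies(tr, "Viridiplantae", 100,
                                         n_diagnostic = 4, seed = 6)
  b <- gen_alignment_with_synapomorphies(tr, "Viridiplantae", 100,
                                         n_diagnostic = 4, seed = 6)
  expect_identical(a, b)
  expect_identical(gen_gene_models(4, seed = 11), gen_gene_models(4, seed = 11))
})
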