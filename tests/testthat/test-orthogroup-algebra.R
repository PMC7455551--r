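test_that("venn_partition matches a brute-force per-orthogroup scan", {
  groups <- list(P = "p1", C = c("c1", "c2"), S = c("s1", "s2"))
  tab <- random_og_table(500, groups, seed = 41)
  vp <- venn_partition(tab)
  expect_equal(sum(vp), 500)
  # oracle: explicit loop
  oracle <- integer(0)
  for (i in seq_len(nrow(tab$counts))) {
    memb <- names(groups)[vapply(groups, function(sp)
      any(tab$counts[i, sp] > 0), logical(1))]
    key <- paste(memb, collapse = "+")
    oracle[key] <- if (key %in% names(oracle)) oracle[key] + 1L else 1L
  }
  for (k in names(oracle)) expect_equal(unname(vp[k]), unname(oracle[k]))
  expect_true(all(vp[setdiff(names(vp), names(oracle))] == 0))
  # invariant to species order and count magnitude
  perm <- tab
  perm$counts <- perm$counts[, sample(colnames(perm$counts)), drop = FALSE]
  perm$counts <- perm$counts * 7L
  expect_equal(venn_partition(orthogroup_table(perm$counts, groups)), vp)
  expect_error(venn_partition(tab, c("P", "X")), "unknown group")
})

test_that("single orthogroup present everywhere lands in the full subset", {
  groups <- list(A = "a", B = "b", C = "c")
  m <- matrix(1L, 1, 3, dimnames = list("OG1", c("a", "b", "c")))
  vp <- venn_partition(orthogroup_table(m, groups))
  expect_equal(unname(vp["A+B+C"]), 1)
  expect_equal(sum(vp), 1)
})

test_that("core_at_node reproduces the published minimal core of 4,092", {
  tab <- fig2a_table()
  tr <- exemplar_tree()
  core <- core_at_node(tab, tr, "Viridiplantae")
  expect_length(core, 4092)
  # an orthogroup private to P. coloniale spans one child side: excluded
  vp <- venn_partition(tab)
  expect_equal(length(core) + unname(vp["Prasinodermophyta"]) +
               unname(vp["Chlorophyta"]) + unname(vp["Streptophyta"]) +
               unname(vp["Chlorophyta+Streptophyta"]),
               nrow(tab$counts))
  expect_error(core_at_node(tab, tr, "P.coloniale"), "leaf")
})

test_that("core_at_node equals the brute-force two-sides oracle", {
  groups <- list(Rhodoplantae = "r1", Glaucoplantae = "g1",
                 Prasinodermophyta = c("p1", "p2"),
                 Chlorophyta = c("c1", "c2"), Streptophyta = c("s1", "s2"))
  tr <- gen_species_tree(groups)
  tab <- random_og_table(200, groups, seed = 43, p_present = 0.4)
  for (node in c("Viridiplantae", "Chlorophyta_Streptophyta",
                 "Archaeplastida")) {
    core <- core_at_node(tab, tr, node)
    v <- viridicore:::node_id(tr, node)
    ch <- viridicore:::children_of(tr, v)
    oracle <- rownames(tab$counts)[vapply(
      seq_len(nrow(tab$counts)), function(i) {
        sides <- vapply(ch, function(c0) {
          tips <- tr$tip.label[viridicore:::tips_under(tr, c0)]
          any(tab$counts[i, intersect(tips, colnames(tab$counts))] > 0)
        }, logical(1))
        sum(sides) >= 2
      }, logical(1))]
    expect_setequal(core, oracle)
  }
})

test_that("core_at_node is monotone in presences", {
  groups <- list(P = "p1", C = "c1", S = "s1")
  tr <- gen_species_tree(list(Rhodoplantae = "r1", Glaucoplantae = "g1",
                              Prasinodermophyta = "p1", Chlorophyta = "c1",
                              Streptophyta = "s1"))
  tab <- random_og_table(80, groups, seed = 47, p_present = 0.3)
  core0 <- core_at_node(tab, tr, "Viridiplantae")
  set.seed(48)
  m <- tab$counts
  zeros <- which(m == 0L)
  m[sample(zeros, 30)] <- 1L
  core1 <- core_at_node(orthogroup_table(m, groups), tr, "Viridiplantae")
  expect_true(all(core0 %in% core1))
})

test_that("taxon_span_percentages weights proteins by planted spans", {
  groups <- list(P = "p1", Chlorophyta = "c1", Streptophyta = "s1")
  # p1 has 6 genes in C+S-shared OGs, 3 in C-only OGs, 1 in S-only OGs
  m <- rbind(
    OG1 = c(p1 = 6L, c1 = 1L, s1 = 1L),
    OG2 = c(p1 = 3L, c1 = 2L, s1 = 0L),
    OG3 = c(p1 = 1L, c1 = 0L, s1 = 4L))
  tab <- orthogroup_table(m, groups)
  frac <- taxon_span_percentages(tab)
  expect_equal(unname(frac["p1", c("shared", "a_specific", "b_specific")]),
               c(0.6, 0.3, 0.1))
  # species whose every orthogroup spans both focal groups
  expect_equal(unname(frac["c1", "shared"]), 1 / 3)
  m2 <- m; m2[, "p1"] <- 0L
  # empty species: all fractions 0 (genes removed)
  frac2 <- taxon_span_percentages(orthogroup_table(m2, groups))
  expect_true(all(frac2["p1", ] == 0))
})

test_that("trichotomy applies the published rules in order", {
  groups <- list(earlyC = paste0("c", 1:5), earlyS = paste0("s", 1:5))
  mk <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    colnames(m) <- unlist(groups)
    rownames(m) <- paste0("F", seq_len(nrow(m)))
    orthogroup_table(m, groups)
  }
  # meanA 6 vs meanB 2: groupA since 6 > 2*2
  tab <- mk(c(4L, 6L, 8L, 5L, 7L, 2L, 3L, 1L, 2L, 2L))
  expect_equal(classify_lineage_families(tab, "earlyC", "earlyS")$label,
               "groupA-family")
  # one species 100 vs nine others averaging 5: outlier
  tab2 <- mk(c(100L, rep(5L, 9)))
  res2 <- classify_lineage_families(tab2, "earlyC", "earlyS")
  expect_equal(res2$label, "removed-outlier")
  expect_match(res2$reason, "10x")
  # single-species family: singleton, not outlier
  tab3 <- mk(c(3L, rep(0L, 9)))
  expect_equal(classify_lineage_families(tab3, "earlyC", "earlyS")$label,
               "removed-singleton")
  # boundary: meanA exactly 2x meanB is shared (strict inequality)
  tab4 <- mk(c(rep(4L, 5), rep(2L, 5)))
  expect_equal(classify_lineage_families(tab4, "earlyC", "earlyS")$label,
               "shared")
  # all-zero family is malformed
  m5 <- rbind(F1 = rep(0L, 10))
  colnames(m5) <- unlist(groups)
  expect_error(classify_lineage_families(orthogroup_table(m5, groups),
                                         "earlyC", "earlyS"), "all-zero")
})

test_that("trichotomy is invariant to within-group relabeling and scaling", {
  groups <- list(A = paste0("a", 1:4), B = paste0("b", 1:4))
  tab <- random_og_table(120, groups, seed = 51, p_present = 0.7)
  res <- classify_lineage_families(tab, "A", "B")
  # relabel species within groups (swap columns a1<->a2, b1<->b3)
  m <- tab$counts
  m[, c("a1", "a2")] <- m[, c("a2", "a1")]
  m[, c("b1", "b3")] <- m[, c("b3", "b1")]
  res2 <- classify_lineage_families(orthogroup_table(m, groups), "A", "B")
  expect_equal(res2$label, res$label)
  # scale all counts in each family by 3
  res3 <- classify_lineage_families(
    orthogroup_table(tab$counts * 3L, groups), "A", "B")
  expect_equal(res3$label, res$label)
})

test_that("OrthoFinder gene-count TSV round-trips (Total column tolerated)", {
  tab <- fig2a_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroup_table(tab, path)
  back <- read_orthogroup_table(path, groups = fig2a_groups())
  expect_equal(back$counts, tab$counts)
  expect_equal(venn_partition(back), venn_partition(tab))
})
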