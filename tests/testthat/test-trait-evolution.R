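test_that("dollo_map handles the trivial ubiquitous trait", {
  tr <- exemplar_tree()
  m <- trait_matrix(matrix(1L, 1, 5, dimnames = list("t1", tr$tip.label)))
  em <- dollo_map(m, tr)
  expect_equal(em$events$t1$gain, "Archaeplastida")
  expect_length(em$events$t1$losses, 0)
  # all-absent trait is rejected with its label
  m0 <- trait_matrix(matrix(0L, 1, 5, dimnames = list("bad", tr$tip.label)))
  expect_error(dollo_map(m0, tr), "bad")
})

test_that("tf_fixture mapping reproduces the published gains and losses", {
  em <- dollo_map(tf_fixture(), group_tree())
  expect_equal(unname(em$branch_gains["Viridiplantae"]), 5L)
  expect_equal(unname(em$branch_losses["P.coloniale"]), 6L)
  expect_equal(unname(em$branch_gains["Chlorophyta_Streptophyta"]), 5L)
  expect_equal(unname(em$branch_gains["Streptophyta"]), 7L)
  # ancestral toolbox at the Archaeplastida root: the 50 P. coloniale
  # types shared with Glaucoplantae/Rhodoplantae (plus the 6 later lost
  # on the P. coloniale branch, which were also ancestral)
  tb <- ancestral_toolbox(em, "Archaeplastida")
  pres_p <- rownames(tf_fixture())[tf_fixture()[, "P.coloniale"] == 1]
  expect_length(intersect(tb, pres_p), 50)
  expect_length(tb, 56)
  expect_error(ancestral_toolbox(em, "Nonesuch"), "unknown")
})

test_that("toolbox at a leaf equals the observed presence set", {
  m <- tf_fixture()
  em <- dollo_map(m, group_tree())
  for (leaf in colnames(m))
    expect_setequal(ancestral_toolbox(em, leaf),
                    rownames(m)[m[, leaf] == 1])
})

test_that("reconstructed leaf states reproduce the input matrix", {
  tr <- ten_leaf_tree()
  sim <- gen_trait_history(tr, 60, gain_prob = 0.25, loss_prob = 0.1,
                           seed = 61)
  keep <- !vapply(sim$truth, `[[`, logical(1), "all_absent")
  m <- sim$matrix[keep, , drop = FALSE]
  em <- dollo_map(m, tr)
  expect_equal(em$node_presence[, colnames(m)], unclass(m)[, colnames(m)],
               ignore_attr = TRUE)
})

test_that("dollo loss counts equal the exhaustive single-gain minimum", {
  trees <- list(
    gen_species_tree(paste0("t", 1:5)),
    gen_species_tree(list(A = c("a1", "a2"), B = c("b1", "b2"),
                          C = c("c1", "c2"), D = c("d1", "d2"))),
    ten_leaf_tree())
  trees[[3]] <- ape::keep.tip(trees[[3]],
                              trees[[3]]$tip.label[1:8])
  trees[[3]] <- viridicore:::ensure_node_labels(trees[[3]])
  set.seed(63)
  for (tr in trees) {
    n <- length(tr$tip.label)
    pats <- unique(replicate(12, {
      p <- sample(0:1, n, replace = TRUE)
      if (!any(p == 1)) p[1] <- 1L
      p
    }, simplify = FALSE))
    m <- do.call(rbind, pats)
    dimnames(m) <- list(paste0("t", seq_len(nrow(m))), tr$tip.label)
    em <- dollo_map(trait_matrix(m), tr)
    for (i in seq_len(nrow(m))) {
      oracle <- dollo_oracle(tr, m[i, ])
      expect_equal(length(em$events[[i]]$losses), oracle,
                   info = paste("pattern", paste(m[i, ], collapse = "")))
    }
  }
})

test_that("EventMap is invariant to trait and taxon permutations", {
  tr <- ten_leaf_tree()
  sim <- gen_trait_history(tr, 30, gain_prob = 0.3, loss_prob = 0.1,
                           seed = 67)
  keep <- !vapply(sim$truth, `[[`, logical(1), "all_absent")
  m <- unclass(sim$matrix)[keep, , drop = FALSE]
  em <- dollo_map(trait_matrix(m), tr)
  set.seed(68)
  mp <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
  emp <- dollo_map(trait_matrix(mp), tr)
  for (t in rownames(m)) {
    expect_equal(emp$events[[t]]$gain, em$events[[t]]$gain)
    expect_setequal(emp$events[[t]]$losses, em$events[[t]]$losses)
  }
})

test_that("simulated histories are recovered at moderate rates", {
  tr <- ten_leaf_tree()
  sim <- gen_trait_history(tr, 200, gain_prob = 0.2, loss_prob = 0.02,
                           seed = 21)
  keep <- !vapply(sim$truth, `[[`, logical(1), "all_absent")
  m <- sim$matrix[keep, , drop = FALSE]
  em <- dollo_map(m, tr)
  tot <- 0L; rec <- 0L
  for (t in rownames(m)) {
    tru <- sim$truth[[t]]
    g <- if (tru$gain == "root") "Archaeplastida" else tru$gain
    planted <- c(g, tru$losses)
    mapped <- c(em$events[[t]]$gain, em$events[[t]]$losses)
    tot <- tot + length(planted)
    rec <- rec + sum(planted %in% mapped)
  }
  expect_gte(rec / tot, 0.95)
  # and the internal-node states match the generator truth whenever the
  # mapped gain equals the planted gain (identifiable histories)
  for (t in rownames(m)[1:50]) {
    tru <- sim$truth[[t]]
    g <- if (tru$gain == "root") "Archaeplastida" else tru$gain
    if (!identical(em$events[[t]]$gain, g)) next
    expect_equal(em$node_presence[t, names(tru$node_states)],
                 as.integer(tru$node_states), ignore_attr = TRUE)
  }
})

test_that("Viridiplantae-internal inferences are root-choice invariant", {
  # alternative rooting: Glaucoplantae sister to (Rhodoplantae, Viridiplantae)
  alt <- ape::read.tree(text = paste0(
    "(Glaucoplantae,(Rhodoplantae,(P.coloniale,(Chlorophyta,Streptophyta)",
    "Chlorophyta_Streptophyta)Viridiplantae)RG)Root;"))
  alt <- viridicore:::ensure_node_labels(alt)
  em1 <- dollo_map(tf_fixture(), group_tree())
  em2 <- dollo_map(tf_fixture(), alt)
  for (br in c("Viridiplantae", "Chlorophyta_Streptophyta", "Streptophyta",
               "P.coloniale")) {
    expect_equal(em2$branch_gains[[br]], em1$branch_gains[[br]])
    expect_equal(em2$branch_losses[[br]], em1$branch_losses[[br]])
  }
})

test_that("event_table rows are conserved and carry the published loss", {
  em <- dollo_map(tf_fixture(), group_tree())
  tab <- event_table(em)
  expect_equal(nrow(tab), sum(em$branch_gains) + sum(em$branch_losses))
  expect_true(any(tab$branch == "P.coloniale" & tab$event == "loss" &
                  tab$trait == "MADS_MIKC"))
  # empty matrix gives an empty table
  tr <- group_tree()
  m0 <- trait_matrix(matrix(integer(0), 0, 5,
                            dimnames = list(NULL, tr$tip.label)))
  expect_equal(nrow(event_table(dollo_map(m0, tr))), 0)
})

test_that("fitch mode reports flip events consistent with leaf states", {
  tr <- exemplar_tree()
  m <- trait_matrix(matrix(c(1, 0, 1, 1, 0), 1,
                           dimnames = list("t1", tr$tip.label)))
  emf <- dollo_map(m, tr, mode = "fitch")
  # events exist and parsimony cost is at most the Dollo cost
  emd <- dollo_map(m, tr)
  cost_f <- sum(emf$branch_gains) + sum(emf$branch_losses)
  cost_d <- sum(emd$branch_gains) + sum(emd$branch_losses)
  expect_lte(cost_f, cost_d)
})
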