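# Shared fixtures, built in code at test time.

# Venn partition of the published four-species comparison restricted to the
# three green lineages, plus the lineage-unique orthogroups.
fig2a_spec <- function() {
  c("Prasinodermophyta+Chlorophyta+Streptophyta" = 3292,
    "Prasinodermophyta+Chlorophyta" = 621,
    "Prasinodermophyta+Streptophyta" = 179,
    "Chlorophyta+Streptophyta" = 760,
    "Prasinodermophyta" = 1356,
    "Chlorophyta" = 500,
    "Streptophyta" = 800)
}

fig2a_groups <- function() {
  list(Prasinodermophyta = "P.coloniale",
       Chlorophyta = "M.commoda",
       Streptophyta = "C.atmophyticus")
}

fig2a_table <- function(seed = 7L) {
  gen_orthogroup_table(fig2a_spec(), fig2a_groups(), seed = seed)
}

# Archaeplastida backbone with exemplar species per clade.
exemplar_tree <- function() {
  gen_species_tree(list(Rhodoplantae = "Porphyra",
                        Glaucoplantae = "Cyanophora",
                        Prasinodermophyta = "P.coloniale",
                        Chlorophyta = "M.commoda",
                        Streptophyta = "C.atmophyticus"))
}

# deeper species-level tree for simulation round-trips
ten_leaf_tree <- function() {
  gen_species_tree(list(Rhodoplantae = c("Pye", "Cme"),
                        Glaucoplantae = "Cpa",
                        Prasinodermophyta = c("Pco", "Pca"),
                        Chlorophyta = c("Mco", "Ota"),
                        Streptophyta = c("Cat", "Kni", "Mvi")))
}

# random membership table over k groups (one species each) for oracle tests
random_og_table <- function(n_og, groups, seed, p_present = 0.5,
                            max_count = 5L) {
  sp <- unlist(groups, use.names = FALSE)
  set.seed(seed)
  m <- matrix(0L, n_og, length(sp),
              dimnames = list(sprintf("OG%05d", seq_len(n_og)), sp))
  for (i in seq_len(n_og)) {
    repeat {
      row <- ifelse(stats::runif(length(sp)) < p_present,
                    sample.int(max_count, length(sp), replace = TRUE), 0L)
      if (any(row > 0)) break
    }
    m[i, ] <- as.integer(row)
  }
  orthogroup_table(m, groups)
}

# exhaustive minimal-loss count for a single-gain history (Dollo oracle):
# enumerate every gain placement and every loss subset, smallest subsets
# first, and report the global minimum number of losses reproducing the
# tip pattern.
dollo_oracle <- function(tree, pattern) {
  tips <- seq_along(tree$tip.label)
  pres <- tips[pattern[tree$tip.label] == 1]
  stopifnot(length(pres) >= 1)
  paths <- lapply(tips, function(t) viridicore:::path_from_root(tree, t))
  best <- Inf
  n <- length(tree$tip.label)
  for (g in seq_len(n + tree$Nnode)) {
    clade_tips <- viridicore:::tips_under(tree, g)
    if (!all(pres %in% clade_tips)) next
    if (any(pattern[tree$tip.label[setdiff(tips, clade_tips)]] == 1)) next
    clade <- viridicore:::nodes_under(tree, g)
    edges <- setdiff(clade, g)         # candidate loss branches (by child)
    ne <- length(edges)
    states_for <- function(losses) vapply(clade_tips, function(tp)
      as.integer(!any(paths[[tp]] %in% losses)), integer(1))
    target <- unname(pattern[tree$tip.label[clade_tips]])
    if (ne == 0) {
      if (identical(states_for(integer(0)), target)) best <- min(best, 0)
      next
    }
    bits <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ne)))
    pc <- rowSums(bits)
    for (r in order(pc)) {             # smallest loss sets first
      if (pc[r] >= best) break
      if (identical(states_for(edges[bits[r, ]]), target)) {
        best <- pc[r]
        break                          # minimal for this gain placement
      }
    }
  }
  best
}
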