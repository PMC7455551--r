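#' Default clade backbone for Archaeplastida group trees
#'
#' Rooted backbone `(Rhodoplantae,(Glaucoplantae,(Prasinodermophyta,
#' (Chlorophyta,Streptophyta))))`: the Prasinodermophyta diverge before the
#' Chlorophyta/Streptophyta split, and the Glaucoplantae are sister to all
#' Viridiplantae.  Internal nodes carry clade labels used throughout the
#' package ("Archaeplastida", "Glaucoplantae_Viridiplantae", "Viridiplantae",
#' "Chlorophyta_Streptophyta").
#'
#' @return Character scalar, a Newick string.
#' @export
default_backbone <- function() {
  paste0("(Rhodoplantae,(Glaucoplantae,(Prasinodermophyta,",
         "(Chlorophyta,Streptophyta)Chlorophyta_Streptophyta)",
         "Viridiplantae)Glaucoplantae_Viridiplantae)Archaeplastida;")
}

#' Simulate a rooted, clade-labelled species tree
#'
#' Builds a rooted binary species tree from named groups of taxa.  When the
#' group names are the five Archaeplastida backbone clades the default
#' backbone topology is used; otherwise the groups are arranged on a ladder
#' in the order given.  Groups with more than one taxon are expanded into a
#' ladder subtree whose stem node carries the group name.  The construction
#' is fully deterministic; `seed` is accepted (and recorded) so every
#' generator shares one calling convention.
#'
#' @param groups Named list of character vectors (group -> taxon labels), or
#'   a plain character vector of taxon labels (each its own group).
#' @param seed Integer; recorded in the result, does not alter the topology.
#' @param backbone Newick string over the group names; defaults to
#'   [default_backbone()] when the group names match its five clades.
#' @return An [ape::phylo] tree with `node.label` set; attribute `seed`.
#' @examples
#' tr <- gen_species_tree(list(Rhodoplantae = "Porphyra",
#'                             Glaucoplantae = "Cyanophora",
#'                             Prasinodermophyta = "P.coloniale",
#'                             Chlorophyta = c("Micromonas", "Ostreococcus"),
#'                             Streptophyta = c("Chlorokybus", "Mesostigma")))
#' @export
gen_species_tree <- function(groups, seed = 1L, backbone = NULL) {
  if (is.character(groups)) {
    groups <- as.list(groups)
    names(groups) <- unlist(groups)
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  taxa <- unlist(groups, use.names = FALSE)
  if (length(taxa) < 2) stop("need at least 2 taxa")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")

  ladder <- function(labels) {
    # (a,(b,(c,d))) right ladder; single label stays a leaf
    if (length(labels) == 1) return(labels)
    out <- labels[length(labels)]
    for (i in rev(seq_len(length(labels) - 1)))
      out <- paste0("(", labels[i], ",", out, ")")
    out
  }
  # single-member groups stay a leaf (Newick has no unary nodes); the
  # group label is then recoverable via attr(tree, "groups")
  sub <- vapply(names(groups), function(g) {
    memb <- groups[[g]]
    if (length(memb) == 1) {
      if (memb == g) g else memb   # group label recoverable via groups map
    } else paste0(ladder(memb), g)
  }, character(1))

  backbone_names <- c("Rhodoplantae", "Glaucoplantae", "Prasinodermophyta",
                      "Chlorophyta", "Streptophyta")
  if (is.null(backbone) && setequal(names(groups), backbone_names))
    backbone <- default_backbone()
  if (is.null(backbone)) {
    nwk <- paste0(ladder(sub), "Root;")
  } else {
    nwk <- backbone
    for (g in names(groups))
      nwk <- sub(paste0("(?<![A-Za-z0-9_.])", g, "(?![A-Za-z0-9_.])"),
                 sub[[g]], nwk, perl = TRUE)
  }
  tree <- ape::read.tree(text = nwk)
  tree <- ensure_node_labels(tree)
  attr(tree, "seed") <- as.integer(seed)
  attr(tree, "groups") <- groups
  tree
}

#' Five-clade group tree used for group-level trait matrices
#'
#' One leaf per clade: Rhodoplantae, Glaucoplantae, P.coloniale (standing in
#' for the Prasinodermophyta), Chlorophyta, Streptophyta, on the default
#' backbone.
#'
#' @return An [ape::phylo] tree with labelled internal nodes.
#' @export
group_tree <- function() {
  nwk <- sub("Prasinodermophyta", "P.coloniale", default_backbone(),
             fixed = TRUE)
  ensure_node_labels(ape::read.tree(text = nwk))
}

#' Simulate binary trait histories on a tree
#'
#' Traits evolve down the tree under a single-gain ("Dollo") process: on
#' each branch a still-absent trait is gained with probability `gain_prob`
#' (at most one gain per trait), and a present trait is lost with
#' probability `loss_prob`; once lost a trait is never regained.  With
#' `mode = "free"` gains are not restricted to one event.  The returned
#' ground truth records the planted gain and loss branches per trait
#' (branches are named by their child node label).
#'
#' @param tree Rooted [ape::phylo] with node labels (see
#'   [gen_species_tree()]).
#' @param n_traits Number of traits to simulate.
#' @param gain_prob,loss_prob Per-branch event probabilities in `[0, 1]`.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param mode `"dollo"` (default, at most one gain) or `"free"`.
#' @param root_present Probability a trait is present at the root
#'   (default 0: gains happen on branches).
#' @return List with `matrix` (a [trait_matrix()]: traits x taxa 0/1),
#'   and `truth`: per-trait list of `gain` (branch label or NA),
#'   `losses` (branch labels), `all_absent` flag, and `node_states`
#'   (presence at every labelled node).
#' @export
gen_trait_history <- function(tree, n_traits, gain_prob, loss_prob,
                              seed = 1L, mode = c("dollo", "free"),
                              root_present = 0) {
  mode <- match.arg(mode)
  stopifnot(gain_prob >= 0, gain_prob <= 1, loss_prob >= 0, loss_prob <= 1,
            n_traits >= 1)
  tree <- ensure_node_labels(tree)
  n <- n_tips(tree)
  labels <- c(tree$tip.label, tree$node.label)
  # preorder of nodes
  ord <- integer(0)
  stack <- root_node(tree)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    stack <- c(stack, rev(children_of(tree, v)))
  }
  with_seed(seed, {
    mat <- matrix(0L, n_traits, n,
                  dimnames = list(paste0("trait_", sprintf("%03d",
                                                           seq_len(n_traits))),
                                  tree$tip.label))
    truth <- vector("list", n_traits)
    for (t in seq_len(n_traits)) {
      state <- logical(max(tree$edge))        # per node
      gained <- FALSE
      gain_br <- NA_character_; losses <- character(0)
      gains <- character(0)
      r <- root_node(tree)
      state[r] <- stats::runif(1) < root_present
      if (state[r]) { gained <- TRUE; gain_br <- "root" ; gains <- "root" }
      for (v in ord) {
        if (v == r) next
        p <- parent_of(tree, v)
        if (state[p]) {
          state[v] <- TRUE
          if (stats::runif(1) < loss_prob) {
            state[v] <- FALSE
            losses <- c(losses, labels[v])
          }
        } else {
          can_gain <- mode == "free" || !gained
          if (can_gain && stats::runif(1) < gain_prob) {
            state[v] <- TRUE
            gained <- TRUE
            gains <- c(gains, labels[v])
            if (is.na(gain_br)) gain_br <- labels[v]
          }
        }
      }
      mat[t, ] <- as.integer(state[seq_len(n)])
      node_states <- state[(n + 1):(n + tree$Nnode)]
      names(node_states) <- tree$node.label
      truth[[t]] <- list(gain = gain_br, gains = gains, losses = losses,
                         all_absent = !any(state[seq_len(n)]),
                         node_states = node_states)
    }
    names(truth) <- rownames(mat)
    list(matrix = trait_matrix(mat), truth = truth)
  })
}

#' Canonical group-level TF/TR presence fixture
#'
#' A deterministic transcription factor / transcriptional regulator
#' presence/absence matrix over the five Archaeplastida clades, encoding the
#' published group-level distribution: 55 types present in P. coloniale, of
#' which 5 (C2C2-Dof, WRKY, SBP, GARP_ARR-B, TAZ) are absent from both
#' Glaucoplantae and Rhodoplantae (Viridiplantae-stem gains) and 50 are also
#' present in Glaucoplantae/Rhodoplantae (ancestral toolbox); 6 types
#' (C2H2, C3H, CCAAT_HAP2, MADS_MIKC, MBF1, Zinc-finger-MIZ) present in all
#' groups except P. coloniale (losses on its branch); 5 types only in
#' Chlorophyta+Streptophyta; and 7 types only in Streptophyta.  Unnamed
#' ancestral types carry synthetic labels `TFTR_A01..A50`.
#'
#' @return A [trait_matrix()] with 73 rows and columns `Rhodoplantae`,
#'   `Glaucoplantae`, `P.coloniale`, `Chlorophyta`, `Streptophyta`.
#' @export
tf_fixture <- function() {
  cols <- c("Rhodoplantae", "Glaucoplantae", "P.coloniale",
            "Chlorophyta", "Streptophyta")
  viri_gains <- c("C2C2-Dof", "WRKY", "SBP", "GARP_ARR-B", "TAZ")
  pcol_losses <- c("C2H2", "C3H", "CCAAT_HAP2", "MADS_MIKC", "MBF1",
                   "Zinc-finger-MIZ")
  cs_gains <- c("ABI3/VP1", "Dicer", "HD_DDT", "Pseudo_ARR-B", "Whirly")
  s_gains <- c("HD-ZIP_I_II", "HD-ZIP_III", "HD-PLINC", "GRF", "LUG",
               "SRS", "Trihelix")
  ancestral <- sprintf("TFTR_A%02d", 1:50)
  rows <- c(ancestral, viri_gains, pcol_losses, cs_gains, s_gains)
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  m[ancestral, ] <- 1L
  m[viri_gains, c("P.coloniale", "Chlorophyta", "Streptophyta")] <- 1L
  m[pcol_losses, setdiff(cols, "P.coloniale")] <- 1L
  m[cs_gains, c("Chlorophyta", "Streptophyta")] <- 1L
  m[s_gains, "Streptophyta"] <- 1L
  trait_matrix(m)
}
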