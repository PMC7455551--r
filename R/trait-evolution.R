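#' Binary trait presence/absence matrix
#'
#' Thin wrapper around a traits x taxa 0/1 integer matrix with unique row
#' (trait) and column (taxon) labels.  Taxon columns must match the tips of
#' the tree the matrix is mapped on: group-level matrices are mapped on a
#' collapsed group tree (see [group_tree()]), species-level matrices on the
#' full species tree.
#'
#' @param x Matrix (logical or 0/1 numeric) with dimnames.
#' @return Integer matrix of class `trait_matrix`.
#' @export
trait_matrix <- function(x) {
  if (nrow(x) > 0 && is.null(rownames(x)))
    stop("trait matrix needs trait rownames")
  if (is.null(colnames(x)))
    stop("trait matrix needs taxon colnames")
  if (is.null(rownames(x))) rownames(x) <- character(0)
  if (anyDuplicated(rownames(x))) stop("duplicate trait labels")
  if (anyDuplicated(colnames(x))) stop("duplicate taxon labels")
  m <- x
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0L | m > 1L))
    stop("trait matrix entries must be 0/1")
  structure(m, class = c("trait_matrix", "matrix", "array"))
}

#' Read / write a trait matrix as TSV
#'
#' Traits in rows, taxa in columns, 0/1 entries; first column holds the
#' trait labels.
#'
#' @param path File path.
#' @param x A [trait_matrix()].
#' @return `read_trait_matrix` returns a [trait_matrix()].
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  trait_matrix(as.matrix(df))
}

#' @rdname read_trait_matrix
#' @export
write_trait_matrix <- function(x, path) {
  df <- data.frame(trait = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map traits on a species tree under Dollo parsimony
#'
#' Each trait is assumed to arise exactly once: the gain is placed on the
#' stem branch of the most recent common ancestor (MRCA) of all taxa
#' carrying the trait, and losses are the minimal set of branches explaining
#' every absence inside that clade, i.e. the stems of the maximal all-absent
#' subtrees.  This reproduces the gains-then-losses reasoning used when a
#' family present in Viridiplantae but absent from Glaucoplantae and
#' Rhodoplantae is inferred to have been gained on the Viridiplantae stem.
#' A Fitch-style multiple-gain mode is available for sensitivity checks.
#'
#' @param matrix A [trait_matrix()]; columns must be exactly the tree tips.
#' @param tree Rooted [ape::phylo] with labelled internal nodes.
#' @param mode `"dollo"` (default) or `"fitch"` (unordered parsimony via
#'   [ape::MPR]-style down-pass; events are reported per branch).
#' @return An object of class `event_map`: list with
#'   `events` (per trait: `gain` branch label, `losses` branch labels),
#'   `branch_gains`/`branch_losses` (named counts per branch, branches named
#'   by child node label), `node_presence` (traits x nodes 0/1 matrix over
#'   tips and internal nodes), `tree`, `matrix`.
#' @examples
#' em <- dollo_map(tf_fixture(), group_tree())
#' em$branch_gains[["Viridiplantae"]]   # 5 stem gains
#' @export
dollo_map <- function(matrix, tree, mode = c("dollo", "fitch")) {
  mode <- match.arg(mode)
  tree <- ensure_node_labels(tree)
  if (!setequal(colnames(matrix), tree$tip.label))
    stop("matrix taxa must match tree tips")
  m <- matrix[, tree$tip.label, drop = FALSE]
  n <- n_tips(tree)
  labels <- c(tree$tip.label, tree$node.label)
  all_nodes <- seq_len(n + tree$Nnode)
  events <- vector("list", nrow(m))
  names(events) <- rownames(m)
  node_presence <- matrix(0L, nrow(m), length(all_nodes),
                          dimnames = list(rownames(m), labels))
  for (t in seq_len(nrow(m))) {
    pres <- which(m[t, ] == 1L)
    if (length(pres) == 0)
      stop("trait has no presence taxon: ", rownames(m)[t])
    g <- mrca_of(tree, pres)
    clade <- nodes_under(tree, g)
    # all-absent status per node within the gain clade
    absent <- logical(max(all_nodes))
    absent_of <- function(v) {
      tips <- tips_under(tree, v)
      all(m[t, tree$tip.label[tips]] == 0L)
    }
    for (v in clade) absent[v] <- absent_of(v)
    losses <- clade[absent[clade] &
                    vapply(clade, function(v) {
                      p <- parent_of(tree, v)
                      v != g && (!is.na(p)) && !absent[p]
                    }, logical(1))]
    # presence at nodes: inside clade, not at/below a loss stem
    present_nodes <- setdiff(clade[!vapply(clade, function(v) {
      any(vapply(path_from_root(tree, v), function(u)
        u %in% losses, logical(1)))
    }, logical(1))], integer(0))
    present_nodes <- intersect(present_nodes, clade[!absent[clade]])
    node_presence[t, labels[present_nodes]] <- 1L
    events[[t]] <- list(gain = labels[g], losses = labels[losses])
  }
  if (mode == "fitch")
    events <- fitch_events(m, tree, events)
  branch_gains <- branch_losses <- stats::setNames(
    integer(length(labels)), labels)
  for (ev in events) {
    for (gb in ev$gain) if (!is.na(gb))
      branch_gains[gb] <- branch_gains[gb] + 1L
    for (lb in ev$losses) branch_losses[lb] <- branch_losses[lb] + 1L
  }
  structure(list(events = events, branch_gains = branch_gains,
                 branch_losses = branch_losses,
                 node_presence = node_presence,
                 tree = tree, matrix = m),
            class = "event_map")
}

# Fitch small-parsimony events (sensitivity mode): unordered two-state
# parsimony; each state flip on a branch is reported as a gain or loss.
#' @noRd
fitch_events <- function(m, tree, dollo_events) {
  n <- n_tips(tree)
  labels <- c(tree$tip.label, tree$node.label)
  postorder <- rev(unique(path_order(tree)))
  lapply(seq_len(nrow(m)), function(t) {
    sets <- vector("list", n + tree$Nnode)
    for (i in seq_len(n)) sets[[i]] <- m[t, tree$tip.label[i]]
    for (v in postorder) {
      if (v <= n) next
      ch <- children_of(tree, v)
      inter <- Reduce(intersect, sets[ch])
      sets[[v]] <- if (length(inter)) inter else Reduce(union, sets[ch])
    }
    # top-down resolve, preferring parent state
    state <- integer(n + tree$Nnode)
    r <- root_node(tree)
    state[r] <- if (1L %in% sets[[r]] && !(0L %in% sets[[r]])) 1L else 0L
    gains <- character(0); losses <- character(0)
    for (v in path_order(tree)) {
      if (v == r) next
      p <- parent_of(tree, v)
      state[v] <- if (state[p] %in% sets[[v]]) state[p] else sets[[v]][1]
      if (state[v] > state[p]) gains <- c(gains, labels[v])
      if (state[v] < state[p]) losses <- c(losses, labels[v])
    }
    list(gain = if (length(gains)) gains else NA_character_,
         losses = losses)
  })
}

# preorder node sequence
#' @noRd
path_order <- function(tree) {
  ord <- integer(0); stack <- root_node(tree)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    stack <- c(stack, rev(children_of(tree, v)))
  }
  ord
}

#' @export
print.event_map <- function(x, ...) {
  cat("Dollo event map:", nrow(x$matrix), "traits on",
      length(x$tree$tip.label), "tips\n")
  nz <- x$branch_gains > 0 | x$branch_losses > 0
  df <- data.frame(branch = names(x$branch_gains)[nz],
                   gains = x$branch_gains[nz],
                   losses = x$branch_losses[nz], row.names = NULL)
  print(df)
  invisible(x)
}

#' Ancestral trait toolbox at a node
#'
#' Traits inferred present in the ancestor at `node`: the gain lies on or
#' above the node's stem and no loss occurred on the path from the root to
#' the node.
#'
#' @param event_map Result of [dollo_map()].
#' @param node Tip or internal node label.
#' @return Character vector of trait labels.
#' @export
ancestral_toolbox <- function(event_map, node) {
  tree <- event_map$tree
  v <- node_id(tree, node)   # errors on unknown labels
  lbl <- node_label(tree, v)
  rownames(event_map$node_presence)[event_map$node_presence[, lbl] == 1L]
}

#' Per-branch gain/loss event table
#'
#' One row per (branch, event, trait); totals equal the event-map branch
#' aggregates.
#'
#' @param event_map Result of [dollo_map()].
#' @return data.frame with columns `branch`, `event` ("gain"/"loss"),
#'   `trait`.
#' @export
event_table <- function(event_map) {
  rows <- list()
  for (tr in names(event_map$events)) {
    ev <- event_map$events[[tr]]
    for (g in ev$gain) if (!is.na(g))
      rows[[length(rows) + 1]] <- data.frame(branch = g, event = "gain",
                                             trait = tr)
    for (l in ev$losses)
      rows[[length(rows) + 1]] <- data.frame(branch = l, event = "loss",
                                             trait = tr)
  }
  if (!length(rows))
    return(data.frame(branch = character(0), event = character(0),
                      trait = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$branch, out$event, out$trait), , drop = FALSE]
}
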