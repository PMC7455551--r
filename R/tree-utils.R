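# Internal helpers over ape "phylo" trees.  All functions assume a rooted
# tree; internal nodes are addressed by their node labels (clade names).

#' @noRd
n_tips <- function(tree) length(tree$tip.label)

# Auto-label unlabelled internal nodes as N<k> so every branch can be named
# by its child node.
#' @noRd
ensure_node_labels <- function(tree) {
  nn <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- rep("", nn)
  blank <- is.na(tree$node.label) | tree$node.label == ""
  tree$node.label[blank] <- paste0("N", which(blank))
  dup <- duplicated(c(tree$tip.label, tree$node.label))
  if (any(dup)) stop("duplicate node/tip labels in tree")
  tree
}

# Node number (tips 1..n, internals n+1..n+Nnode) for a tip or internal label.
#' @noRd
node_id <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop("unknown node label: ", label)
  n_tips(tree) + j
}

#' @noRd
node_label <- function(tree, node) {
  n <- n_tips(tree)
  ifelse(node <= n, tree$tip.label[node], tree$node.label[node - n])
}

#' @noRd
root_node <- function(tree) n_tips(tree) + 1L

#' @noRd
children_of <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

#' @noRd
parent_of <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p) == 0) NA_integer_ else p
}

# Tips (numbers) below a node, node itself included when it is a tip.
#' @noRd
tips_under <- function(tree, node) {
  n <- n_tips(tree)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- children_of(tree, v)
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}

# All nodes (tips + internals) in the clade rooted at `node`, inclusive.
#' @noRd
nodes_under <- function(tree, node) {
  out <- node
  stack <- node
  n <- n_tips(tree)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > n) {
      ch <- children_of(tree, v)
      out <- c(out, ch)
      stack <- c(stack, ch)
    }
  }
  sort(out)
}

# Path of nodes from the root down to `node`, inclusive.
#' @noRd
path_from_root <- function(tree, node) {
  path <- node
  while (!is.na(p <- parent_of(tree, node))) {
    path <- c(p, path)
    node <- p
  }
  path
}

#' @noRd
mrca_of <- function(tree, tips) {
  if (length(tips) == 1) return(tips)
  paths <- lapply(tips, function(t) path_from_root(tree, t))
  shared <- Reduce(intersect, paths)
  shared[length(shared)]
}

# Evaluate code with a private RNG stream; global .Random.seed untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
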