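#' Venn partition of orthogroup membership
#'
#' Assigns each orthogroup to exactly one subset of the requested groups:
#' the set of groups with at least one member species present (count > 0).
#' Counts over all subsets sum to the number of orthogroups; orthogroups
#' absent from every requested group are tallied under `"(none)"`.
#' Membership only is used, so the partition is invariant to gene-count
#' magnitude and species order.
#'
#' @param table An [orthogroup_table()].
#' @param groups Character vector of group names (2-5 for a drawable Venn;
#'   any number is counted).
#' @return Named integer vector over all non-empty subsets of `groups`
#'   (keys are group names joined by `+`, in the order given), plus
#'   `"(none)"` when applicable.
#' @export
venn_partition <- function(table, groups = names(table$groups)) {
  unknown <- setdiff(groups, names(table$groups))
  if (length(unknown)) stop("unknown group name: ", unknown[1])
  present <- matrix(FALSE, nrow(table$counts), length(groups),
                    dimnames = list(rownames(table$counts), groups))
  for (g in groups)
    present[, g] <-
      rowSums(table$counts[, table$groups[[g]], drop = FALSE] > 0L) > 0L
  keys <- apply(present, 1, function(p)
    if (!any(p)) "(none)" else paste(groups[p], collapse = "+"))
  # enumerate all non-empty subsets, keep order stable
  all_keys <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(groups, k, paste, collapse = "+", simplify = FALSE)))
  out <- stats::setNames(integer(length(all_keys)), all_keys)
  tab <- table(keys)
  out[names(tab)[names(tab) != "(none)"]] <-
    as.integer(tab[names(tab) != "(none)"])
  if ("(none)" %in% names(tab)) out["(none)"] <- as.integer(tab["(none)"])
  out
}

#' Reconstruct the minimal core gene-family set at a tree node
#'
#' The span rule: an orthogroup is placed in the ancestor at `node` when it
#' is present in at least one taxon of each of two or more distinct child
#' subtrees of that node, i.e. it spans the node's basal split and must
#' have been present in the ancestor (barring independent gains).  At the
#' Viridiplantae root with children Prasinodermophyta and
#' Chlorophyta+Streptophyta this equals (P AND C) OR (P AND S).
#'
#' Tree tips may be species names from the table or group names (presence
#' of a group = any member species present).
#'
#' @param table An [orthogroup_table()].
#' @param tree Rooted [ape::phylo] with labelled internal nodes.
#' @param node Internal node label.
#' @return Character vector of orthogroup ids.
#' @export
core_at_node <- function(table, tree, node) {
  tree <- ensure_node_labels(tree)
  v <- node_id(tree, node)
  if (v <= n_tips(tree)) stop("node must be internal, got leaf: ", node)
  tip_species <- function(tip_label) {
    if (tip_label %in% colnames(table$counts)) return(tip_label)
    if (tip_label %in% names(table$groups))
      return(table$groups[[tip_label]])
    character(0)
  }
  ch <- children_of(tree, v)
  sides <- lapply(ch, function(c0) {
    tips <- tree$tip.label[tips_under(tree, c0)]
    sp <- unlist(lapply(tips, tip_species))
    if (length(sp) == 0) return(rep(FALSE, nrow(table$counts)))
    rowSums(table$counts[, sp, drop = FALSE] > 0L) > 0L
  })
  if (all(vapply(sides, function(s) !any(s), logical(1))))
    stop("no species of the table found under node ", node)
  spans <- Reduce(`+`, sides)
  rownames(table$counts)[spans >= 2L]
}

#' Per-species taxon-span protein percentages
#'
#' Classifies each orthogroup by its span over two focal groups: present in
#' both (e.g. Viridiplantae-wide), present only in the first
#' (Chlorophyta-specific) or only in the second (Streptophyta-specific).
#' Every protein (gene) inherits its orthogroup's class; per-species
#' fractions are gene-count weighted and sum to at most 1 (genes in
#' orthogroups spanning neither focal group form the remainder).
#'
#' @param table An [orthogroup_table()].
#' @param group_a,group_b Focal group names (default `"Chlorophyta"`,
#'   `"Streptophyta"`).
#' @return Numeric matrix species x classes
#'   (`shared`, `a_specific`, `b_specific`, `unassigned`), rows sum to 1
#'   (all-zero for a species with no genes).
#' @export
taxon_span_percentages <- function(table, group_a = "Chlorophyta",
                                   group_b = "Streptophyta") {
  for (g in c(group_a, group_b))
    if (!g %in% names(table$groups)) stop("unknown group name: ", g)
  in_a <- rowSums(table$counts[, table$groups[[group_a]],
                               drop = FALSE] > 0L) > 0L
  in_b <- rowSums(table$counts[, table$groups[[group_b]],
                               drop = FALSE] > 0L) > 0L
  class_of <- ifelse(in_a & in_b, "shared",
                     ifelse(in_a, "a_specific",
                            ifelse(in_b, "b_specific", "unassigned")))
  classes <- c("shared", "a_specific", "b_specific", "unassigned")
  species <- colnames(table$counts)
  out <- matrix(0, length(species), length(classes),
                dimnames = list(species, classes))
  for (cl in classes) {
    rows <- class_of == cl
    out[, cl] <- colSums(table$counts[rows, , drop = FALSE])
  }
  tot <- rowSums(out)
  out[tot > 0, ] <- out[tot > 0, , drop = FALSE] / tot[tot > 0]
  out
}

#' Early-lineage gene-family trichotomy
#'
#' Classifies every gene family (orthogroup) into groupA-biased,
#' groupB-biased or shared, after two filters, applied in this order:
#' (1) *outlier* families where any one species' gene count exceeds ten
#' times the mean count of all other species in the table (zeros included
#' in the mean; the test requires that mean to be positive), and
#' (2) *singleton* families present in only one species.
#' A family is groupA-biased when the mean count over groupA species is
#' more than twice the groupB mean (strict inequality), and vice versa;
#' group means include member species with zero genes.
#'
#' @param table An [orthogroup_table()].
#' @param group_a,group_b Group names, e.g. early-diverging Chlorophyta vs
#'   early-diverging Streptophyta exemplars.
#' @return data.frame (class `trichotomy_result`) with one row per family:
#'   `family`, `label` in `{groupA-family, groupB-family, shared,
#'   removed-outlier, removed-singleton}`, `mean_a`, `mean_b`, `reason`.
#' @export
classify_lineage_families <- function(table, group_a, group_b) {
  for (g in c(group_a, group_b))
    if (!g %in% names(table$groups)) stop("unknown group name: ", g)
  spa <- table$groups[[group_a]]
  spb <- table$groups[[group_b]]
  if (!length(spa) || !length(spb)) stop("both groups must be non-empty")
  cnt <- table$counts
  if (any(rowSums(cnt) == 0L))
    stop("malformed table: family with all-zero counts: ",
         rownames(cnt)[rowSums(cnt) == 0L][1])
  n_sp <- ncol(cnt)
  label <- character(nrow(cnt)); reason <- character(nrow(cnt))
  mean_a <- rowMeans(cnt[, spa, drop = FALSE])
  mean_b <- rowMeans(cnt[, spb, drop = FALSE])
  for (i in seq_len(nrow(cnt))) {
    x <- cnt[i, ]
    others_mean <- (sum(x) - x) / (n_sp - 1)
    outlier <- any(x > 10 * others_mean & others_mean > 0)
    if (outlier) {
      label[i] <- "removed-outlier"
      reason[i] <- paste0("species ",
        names(x)[which(x > 10 * others_mean & others_mean > 0)[1]],
        " count ", max(x), " exceeds 10x mean of others")
    } else if (sum(x > 0L) == 1L) {
      label[i] <- "removed-singleton"
      reason[i] <- paste0("present only in ", names(x)[x > 0L])
    } else if (mean_a[i] > 2 * mean_b[i]) {
      label[i] <- "groupA-family"
    } else if (mean_b[i] > 2 * mean_a[i]) {
      label[i] <- "groupB-family"
    } else {
      label[i] <- "shared"
    }
  }
  structure(data.frame(family = rownames(cnt), label = label,
                       mean_a = mean_a, mean_b = mean_b, reason = reason,
                       row.names = NULL),
            class = c("trichotomy_result", "data.frame"),
            groups = c(a = group_a, b = group_b))
}
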