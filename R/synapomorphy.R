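# Tree-aware synapomorphy scanning: find alignment columns where every
# member of a clade shares a derived state absent from all other taxa, then
# classify candidates against taxon-richer control alignments as genuine
# non-homoplasious synapomorphies (NHS), parallelisms or reversals.

IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

#' @noRd
is_unambiguous <- function(x, alphabet) {
  if (alphabet == "DNA") x %in% c("A", "C", "G", "T")
  else x %in% AA20
}

# could `x` (possibly ambiguous) represent `state`?
#' @noRd
could_match <- function(x, state, alphabet) {
  if (x %in% c("-", "?")) return(FALSE)
  if (alphabet == "DNA") {
    exp <- IUPAC_EXPAND[[x]]
    if (is.null(exp)) return(FALSE)
    state %in% exp
  } else {
    x == state || x == "X"
  }
}

#' Find clade-diagnostic alignment columns
#'
#' A column is a candidate synapomorphy for `clade` when all clade members
#' share one unambiguous state and no outside taxon has (or could have,
#' via an ambiguity code) that state.  Columns with gaps or ambiguity codes
#' within the clade are skipped unless `strictness < 1`, in which case up
#' to `(1 - strictness)` of clade rows may be gapped (the non-gapped rows
#' must still agree).  Ambiguity codes in outside taxa are expanded and
#' treated as potentially matching, which is conservative against false
#' synapomorphies.
#'
#' @param aln An [alignment_block()] (or named character vector).
#' @param tree Rooted labelled [ape::phylo] whose tips index the alignment
#'   rows.
#' @param clade Internal node label; needs >= 2 members present in `aln`.
#' @param strictness Minimum fraction of clade rows that must be
#'   unambiguous (default 1).
#' @return data.frame with `column` (1-based), `clade_state`,
#'   `outside_states` (comma-joined).
#' @export
diagnostic_positions <- function(aln, tree, clade, strictness = 1) {
  if (!methods::is(aln, "alignment_block"))
    aln <- alignment_block(aln, alphabet = "DNA")
  tree <- ensure_node_labels(tree)
  members <- tree$tip.label[tips_under(tree, node_id(tree, clade))]
  members <- intersect(members, names(aln$seqs))
  if (length(members) < 2)
    stop("clade '", clade, "' has fewer than 2 members in the alignment")
  outs <- setdiff(names(aln$seqs), members)
  m <- block_matrix(aln)
  m[] <- toupper(m)
  hits <- list()
  for (j in seq_len(ncol(m))) {
    cl <- m[members, j]
    ok <- is_unambiguous(cl, aln$alphabet)
    if (mean(ok) < strictness || !any(ok)) next
    states <- unique(cl[ok])
    if (length(states) != 1) next
    st <- states
    out_vals <- m[outs, j]
    if (any(vapply(out_vals, could_match, logical(1), state = st,
                   alphabet = aln$alphabet))) next
    hits[[length(hits) + 1]] <- data.frame(
      column = j, clade_state = st,
      outside_states = paste(sort(unique(
        out_vals[is_unambiguous(out_vals, aln$alphabet)])),
        collapse = ","))
  }
  if (!length(hits))
    return(data.frame(column = integer(0), clade_state = character(0),
                      outside_states = character(0)))
  do.call(rbind, hits)
}

#' Classify candidate synapomorphies against control alignments
#'
#' Homoplasy control follows the published procedure: every candidate from
#' the primary scan is looked up in one or more taxon-richer control
#' alignments sharing the coordinate frame (or related to it by
#' `column_map`).  A candidate becomes a *parallelism* when the clade state
#' occurs in any non-member in any control, a *reversal* when any clade
#' member lacks the clade state (carrying a different unambiguous state) in
#' a control, *NHS* when at least one control covers the column and shows
#' neither, and *ambiguous* when no control covers the column.
#'
#' @param candidates data.frame from [diagnostic_positions()].
#' @param control_alns List of [alignment_block()]s (may be empty: all
#'   candidates come back ambiguous, with a warning).
#' @param clade_members Character vector naming every clade member,
#'   including control-only taxa.
#' @param column_maps Optional list (per control) mapping primary column ->
#'   control column (named vector); identity by default.  Unmappable
#'   columns are marked ambiguous, never dropped.
#' @return data.frame of class `synapomorphy_records`: `column`,
#'   `clade_state`, `outside_states`, `class` in
#'   `{NHS, parallelism, reversal, ambiguous}`, `n_support` (control taxa
#'   consistent with the synapomorphy).
#' @export
homoplasy_check <- function(candidates, control_alns, clade_members,
                            column_maps = NULL) {
  if (!nrow(candidates)) {
    out <- cbind(candidates, class = character(0), n_support = integer(0))
    class(out) <- c("synapomorphy_records", "data.frame")
    return(out)
  }
  if (!length(control_alns))
    warning("no control alignments supplied; all candidates ambiguous")
  cls <- character(nrow(candidates))
  support <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    col0 <- candidates$column[i]
    st <- candidates$clade_state[i]
    verdict <- "ambiguous"; n_sup <- 0L
    for (ci in seq_along(control_alns)) {
      ctrl <- control_alns[[ci]]
      j <- if (is.null(column_maps)) col0 else {
        mp <- column_maps[[ci]]
        if (as.character(col0) %in% names(mp)) mp[[as.character(col0)]]
        else NA_integer_
      }
      if (is.na(j)) next
      m <- block_matrix(ctrl)
      m[] <- toupper(m)
      if (j > ncol(m)) next
      inn <- intersect(rownames(m), clade_members)
      out <- setdiff(rownames(m), clade_members)
      if (!length(inn) && !length(out)) next
      vals_in <- m[inn, j]
      vals_out <- m[out, j]
      parallel <- any(vapply(vals_out, could_match, logical(1),
                             state = st, alphabet = ctrl$alphabet))
      revert <- any(is_unambiguous(vals_in, ctrl$alphabet) & vals_in != st)
      if (parallel) { verdict <- "parallelism"; break }
      if (revert) { verdict <- "reversal"; break }
      verdict <- "NHS"
      n_sup <- n_sup + sum(vals_in == st) +
        sum(!vapply(vals_out, could_match, logical(1), state = st,
                    alphabet = ctrl$alphabet))
    }
    cls[i] <- verdict
    support[i] <- n_sup
  }
  out <- cbind(candidates, class = cls, n_support = support)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synapomorphy_records", "data.frame")
  out
}

#' Report synapomorphy records
#'
#' Writes (optionally) an annotated TSV sorted by column and returns the
#' per-class summary counts.
#'
#' @param records Result of [homoplasy_check()].
#' @param path Optional TSV output path (header-only when empty).
#' @return Named integer vector of class counts (`NHS`, `parallelism`,
#'   `reversal`, `ambiguous`).
#' @export
synapomorphy_report <- function(records, path = NULL) {
  records <- records[order(records$column), , drop = FALSE]
  if (!is.null(path))
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  counts <- table(factor(records$class,
                         levels = c("NHS", "parallelism", "reversal",
                                    "ambiguous")))
  stats::setNames(as.integer(counts), names(counts))
}
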