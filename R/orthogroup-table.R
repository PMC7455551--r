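#' Orthogroup gene-count table
#'
#' An orthogroup x species matrix of non-negative gene counts plus a named
#' grouping of the species into taxon groups (e.g. Prasinodermophyta,
#' Chlorophyta, Streptophyta).  A species is a *member* of an orthogroup
#' when its count is positive.  Every species must belong to exactly one
#' group.
#'
#' @param counts Integer matrix, orthogroups in rows (rownames = orthogroup
#'   ids), species in columns.
#' @param groups Named list: group name -> character vector of species.
#' @return Object of class `orthogroup_table` with elements `counts`,
#'   `groups`.
#' @export
orthogroup_table <- function(counts, groups) {
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts needs orthogroup rownames")
  if (is.null(colnames(counts)))
    stop("counts needs species colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L))
    stop("gene counts must be non-negative integers")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must have unique names")
  sp <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(sp)) stop("each species must be in exactly one group")
  if (!setequal(sp, colnames(counts)))
    stop("groups must partition the species set of the table")
  structure(list(counts = counts, groups = groups),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("Orthogroup table:", nrow(x$counts), "orthogroups x",
      ncol(x$counts), "species in", length(x$groups), "groups\n")
  invisible(x)
}

#' Read an OrthoFinder-style gene-count TSV
#'
#' Accepts the `Orthogroups.GeneCount.tsv` dialect: first column the
#' orthogroup id, one column per species, and an optional trailing `Total`
#' column (ignored).
#'
#' @param path TSV path.
#' @param groups Named list group -> species; defaults to one group per
#'   species.
#' @return An [orthogroup_table()].
#' @export
read_orthogroup_table <- function(path, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  rn <- df[[1]]
  df <- df[, -1, drop = FALSE]
  if (tolower(colnames(df)[ncol(df)]) == "total")
    df <- df[, -ncol(df), drop = FALSE]
  m <- as.matrix(df)
  rownames(m) <- rn
  if (is.null(groups))
    groups <- stats::setNames(as.list(colnames(m)), colnames(m))
  orthogroup_table(m, groups)
}

#' @rdname read_orthogroup_table
#' @param x An [orthogroup_table()].
#' @export
write_orthogroup_table <- function(x, path) {
  df <- data.frame(Orthogroup = rownames(x$counts), x$counts,
                   Total = rowSums(x$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical key for a subset of groups, in table group order
#' @noRd
subset_key <- function(sub, group_order) {
  paste(group_order[sort(match(sub, group_order))], collapse = "+")
}

#' Simulate an orthogroup table with exact Venn partition sizes
#'
#' Generates `sum(partition_spec)` orthogroups whose group-membership Venn
#' partition equals `partition_spec` exactly: for each subset of groups, the
#' stated number of orthogroups has at least one member species per group in
#' the subset and zero genes in all other groups.  Per-species gene counts
#' of member species are drawn from `gene_count_law` (zero-truncated where
#' needed so membership is guaranteed).
#'
#' @param partition_spec Named integer vector; names are subsets of group
#'   names joined by `+` (e.g. `"Prasinodermophyta+Chlorophyta"`), values
#'   are orthogroup counts.
#' @param groups Named list group -> species vector.
#' @param gene_count_law Function `n -> n` non-negative integer counts;
#'   defaults to Poisson(1).
#' @param seed Integer seed (fixed seed => identical table).
#' @return An [orthogroup_table()].
#' @examples
#' spec <- c("P+C+S" = 3292, "P+C" = 621, "P+S" = 179, "C+S" = 760)
#' groups <- list(P = "P.coloniale", C = "Micromonas", S = "Chlorokybus")
#' tab <- gen_orthogroup_table(spec, groups, seed = 7)
#' @export
gen_orthogroup_table <- function(partition_spec, groups,
                                 gene_count_law = function(n)
                                   stats::rpois(n, 1),
                                 seed = 1L) {
  if (length(partition_spec) == 0) {
    sp <- unlist(groups, use.names = FALSE)
    m <- matrix(integer(0), 0, length(sp),
                dimnames = list(character(0), sp))
    return(orthogroup_table(m, groups))
  }
  if (any(partition_spec < 0)) stop("partition counts must be >= 0")
  subsets <- strsplit(names(partition_spec), "+", fixed = TRUE)
  bad <- !vapply(subsets, function(s) all(s %in% names(groups)), logical(1))
  if (any(bad))
    stop("unknown group in partition spec: ",
         names(partition_spec)[bad][1])
  sp <- unlist(groups, use.names = FALSE)
  total <- sum(partition_spec)
  with_seed(seed, {
    m <- matrix(0L, total, length(sp),
                dimnames = list(sprintf("OG%07d", seq_len(total)), sp))
    row <- 1L
    for (i in seq_along(partition_spec)) {
      for (k in seq_len(partition_spec[i])) {
        for (g in subsets[[i]]) {
          memb <- groups[[g]]
          cnt <- as.integer(gene_count_law(length(memb)))
          if (all(cnt == 0))    # force membership of the group
            cnt[sample.int(length(memb), 1)] <- 1L
          m[row, memb] <- cnt
        }
        row <- row + 1L
      }
    }
    orthogroup_table(m, groups)
  })
}
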