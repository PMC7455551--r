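#' Aligned sequence block
#'
#' One locus of a multiple sequence alignment: equal-length rows keyed by
#' taxon, with the gap symbol `-`.
#'
#' @param seqs Named character vector of aligned sequences (or XStringSet).
#' @param locus Locus label.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return Object of class `alignment_block`: list with `locus`, `seqs`,
#'   `alphabet`.
#' @export
alignment_block <- function(seqs, locus = "locus1",
                            alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (methods::is(seqs, "XStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("aligned sequences need unique taxon names")
  if (length(unique(nchar(seqs))) > 1)
    stop("aligned sequences must have equal length")
  structure(list(locus = locus, seqs = seqs, alphabet = alphabet),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("Alignment block '", x$locus, "': ", length(x$seqs), " taxa x ",
      if (length(x$seqs)) nchar(x$seqs[[1]]) else 0, " ", x$alphabet,
      " columns\n", sep = "")
  invisible(x)
}

#' @noRd
block_matrix <- function(block) {
  if (!length(block$seqs))
    return(matrix(character(0), 0, 0))
  do.call(rbind, strsplit(block$seqs, ""))
}

#' @noRd
matrix_block <- function(m, locus, alphabet) {
  alignment_block(stats::setNames(apply(m, 1, paste, collapse = ""),
                                  rownames(m)), locus, alphabet)
}

#' Gap symbols counted by the column mask
#'
#' `-` and `?` always; the missing-data code (`N` for nucleotide, `X` for
#' amino acid) when `missing_as_gap`.
#'
#' @noRd
gap_symbols <- function(alphabet, missing_as_gap = TRUE) {
  g <- c("-", "?")
  if (missing_as_gap) g <- c(g, if (alphabet == "DNA") c("N", "n")
                             else c("X", "x"))
  g
}

#' Remove gap-rich alignment columns
#'
#' A column is removed when the fraction of sequences with a gap (or
#' missing-data symbol) at that position is `>= threshold`; with the
#' default 0.5 a column where half the sequences are gapped is dropped.
#' Kept columns preserve their order and the returned index list maps them
#' back to the original coordinates.
#'
#' @param block An [alignment_block()].
#' @param threshold Gap fraction at/above which a column is masked
#'   (default 0.5).
#' @param missing_as_gap Count `N`/`X`/`?` as gaps (default TRUE).
#' @return List with `block` (masked alignment) and `kept` (1-based
#'   original column indices, strictly increasing).
#' @export
mask_gappy_columns <- function(block, threshold = 0.5,
                               missing_as_gap = TRUE) {
  if (!length(block$seqs)) stop("empty alignment block")
  m <- block_matrix(block)
  gaps <- gap_symbols(block$alphabet, missing_as_gap)
  gap_frac <- colMeans(matrix(m %in% gaps, nrow(m), ncol(m)))
  kept <- which(gap_frac < threshold)
  if (!length(kept))
    warning("all columns removed from block '", block$locus, "'")
  out <- matrix_block(m[, kept, drop = FALSE], block$locus,
                      block$alphabet)
  list(block = out, kept = kept)
}

#' Concatenate alignment blocks into a partitioned supermatrix
#'
#' Blocks are linked in the order given; the taxon set is the union over
#' blocks and a taxon missing from a block is filled with `-` across that
#' block's span.  Partition coordinates are 1-based inclusive, contiguous
#' and non-overlapping, and sum to the total length.
#'
#' @param blocks List of [alignment_block()]s sharing one alphabet and with
#'   unique locus labels.
#' @param kept_maps Optional list (parallel to `blocks`) of kept-column
#'   index vectors from [mask_gappy_columns()], recorded in the result.
#' @return Object of class `supermatrix`: list with `seqs` (named character
#'   vector), `partitions` (data.frame `label`, `start`, `end`),
#'   `column_maps` (per block: original index -> concatenated index),
#'   `alphabet`.
#' @export
concatenate <- function(blocks, kept_maps = NULL) {
  if (!length(blocks)) stop("no blocks to concatenate")
  alpha <- unique(vapply(blocks, function(b) b$alphabet, character(1)))
  if (length(alpha) != 1) stop("blocks must share one alphabet")
  loci <- vapply(blocks, function(b) b$locus, character(1))
  if (anyDuplicated(loci)) stop("duplicate locus labels")
  taxa <- unique(unlist(lapply(blocks, function(b) names(b$seqs))))
  lens <- vapply(blocks, function(b)
    if (length(b$seqs)) nchar(b$seqs[[1]]) else 0L, integer(1))
  starts <- as.integer(cumsum(c(1L, lens[-length(lens)])))
  ends <- as.integer(cumsum(lens))
  rows <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      if (tx %in% names(b$seqs)) b$seqs[[tx]]
      else paste(rep("-", lens[i]), collapse = "")
    }, character(1)), collapse = "")
  }, character(1))
  column_maps <- lapply(seq_along(blocks), function(i) {
    orig <- if (is.null(kept_maps)) seq_len(lens[i]) else kept_maps[[i]]
    stats::setNames(seq_len(lens[i]) + starts[i] - 1, orig)
  })
  names(column_maps) <- loci
  structure(list(seqs = rows,
                 partitions = data.frame(label = loci, start = starts,
                                         end = ends),
                 column_maps = column_maps, alphabet = alpha),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$seqs), "taxa x",
      if (length(x$seqs)) nchar(x$seqs[[1]]) else 0, "columns in",
      nrow(x$partitions), "partitions\n")
  invisible(x)
}

#' Mask blocks then concatenate
#'
#' Convenience wrapper: applies [mask_gappy_columns()] to every block and
#' concatenates the survivors, recording the kept-column maps.
#'
#' @inheritParams concatenate
#' @inheritParams mask_gappy_columns
#' @return A `supermatrix` (see [concatenate()]).
#' @export
build_supermatrix <- function(blocks, threshold = 0.5,
                              missing_as_gap = TRUE) {
  masked <- lapply(blocks, mask_gappy_columns, threshold = threshold,
                   missing_as_gap = missing_as_gap)
  concatenate(lapply(masked, `[[`, "block"),
              kept_maps = lapply(masked, `[[`, "kept"))
}

#' Write a supermatrix with its partition file
#'
#' Writes the alignment as relaxed PHYLIP (`ntaxa ncols` header, one
#' name-sequence pair per line) or FASTA, plus a partition file in RAxML
#' (`DNA, label = start-end`) or NEXUS `charset` dialect with 1-based
#' inclusive ranges.  Taxon names illegal for the dialect (whitespace,
#' parentheses, etc.) are sanitised to `_` and the mapping reported via a
#' message and the return value.
#'
#' @param matrix A `supermatrix`.
#' @param prefix Output path prefix; files `<prefix>.phy`/`.fasta` and
#'   `<prefix>.partitions` are created.
#' @param format `"phylip"` or `"fasta"`.
#' @param dialect `"raxml"` or `"nexus"`.
#' @return Invisible list with the written `paths` and the `name_map`.
#' @export
write_partitioned <- function(matrix, prefix, format = c("phylip", "fasta"),
                              dialect = c("raxml", "nexus")) {
  format <- match.arg(format)
  dialect <- match.arg(dialect)
  if (!length(matrix$seqs)) stop("empty supermatrix")
  nm <- names(matrix$seqs)
  safe <- gsub("[^A-Za-z0-9_.|-]", "_", nm)
  if (anyDuplicated(safe)) safe <- make.unique(safe, sep = "_")
  if (!identical(safe, nm))
    message("sanitised ", sum(safe != nm), " taxon name(s) for ", format)
  aln_path <- paste0(prefix, if (format == "phylip") ".phy" else ".fasta")
  if (format == "phylip") {
    width <- max(nchar(safe)) + 2
    lines <- c(paste(length(matrix$seqs), nchar(matrix$seqs[[1]])),
               paste0(formatC(safe, width = -width), matrix$seqs))
    writeLines(lines, aln_path)
  } else {
    write_fasta(stats::setNames(matrix$seqs, safe), aln_path)
  }
  part_path <- paste0(prefix, ".partitions")
  p <- matrix$partitions
  dtype <- if (matrix$alphabet == "DNA") "DNA" else "WAG"
  if (dialect == "raxml") {
    writeLines(sprintf("%s, %s = %d-%d", dtype, p$label, p$start, p$end),
               part_path)
  } else {
    writeLines(c("#nexus", "begin sets;",
                 sprintf("  charset %s = %d-%d;", p$label, p$start, p$end),
                 "end;"), part_path)
  }
  invisible(list(paths = c(alignment = aln_path, partitions = part_path),
                 name_map = stats::setNames(safe, nm)))
}

#' Read a relaxed PHYLIP alignment
#'
#' Counterpart of [write_partitioned()]: `ntaxa ncols` header then one
#' whitespace-separated name/sequence pair per line.
#'
#' @param path File path.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_phylip <- function(path, alphabet = c("DNA", "AA")) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  seqs <- stats::setNames(vapply(parts, `[`, character(1), 2),
                          vapply(parts, `[`, character(1), 1))
  if (length(seqs) != hdr[1] || any(nchar(seqs) != hdr[2]))
    stop("PHYLIP header does not match body")
  seqs
}
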