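# Structural genome descriptors: GC content, repeat/coding fractions,
# exon/intron length distributions, gene size and spacing.  GFF3 is 1-based
# inclusive; BED is 0-based half-open; conversion is centralised here.

#' Parse gene models into a feature table
#'
#' Accepts a GFF3 file path (parsed with rtracklayer) or a data.frame in
#' GFF3 column layout (e.g. from [gen_gene_models()]).  Attributes `ID` and
#' `Parent` are extracted; exon and CDS features are linked to their
#' transcript.
#'
#' @param x GFF3 path or data.frame with columns `seqid`, `type`, `start`,
#'   `end`, `strand`, `attributes`.
#' @return Object of class `gene_model_set`: data.frame with columns
#'   `seqid`, `type`, `start`, `end`, `strand`, `id`, `parent`.
#' @export
read_gene_models <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 files requires rtracklayer")
    gr <- rtracklayer::import(x)
    df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                     type = as.character(gr$type),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     id = if (!is.null(gr$ID)) gr$ID else NA_character_,
                     parent = vapply(
                       if (!is.null(gr$Parent)) as.list(gr$Parent)
                       else rep(list(character(0)), length(gr)),
                       function(p) if (length(p)) p[1] else NA_character_,
                       character(1)))
  } else {
    attr_field <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))
      vapply(m, function(z) if (length(z) == 2) z[2] else NA_character_,
             character(1))
    }
    df <- data.frame(seqid = x$seqid, type = x$type, start = x$start,
                     end = x$end, strand = x$strand,
                     id = attr_field(x$attributes, "ID"),
                     parent = attr_field(x$attributes, "Parent"))
  }
  structure(df, class = c("gene_model_set", "data.frame"))
}

#' @noRd
as_dna <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_seq_file(genome, as = "DNAStringSet")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  genome
}

#' GC content of a genome
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from the
#' denominator.
#'
#' @param genome Named character vector, DNAStringSet or FASTA path.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(genome) {
  dna <- as_dna(genome)
  if (!length(dna) || sum(Biostrings::width(dna)) == 0)
    stop("empty sequence set")
  freq <- colSums(Biostrings::letterFrequency(dna, c("A", "C", "G", "T")))
  if (sum(freq) == 0) stop("no unambiguous bases in the sequence set")
  unname((freq["G"] + freq["C"]) / sum(freq))
}

#' Fraction of the genome covered by a set of intervals
#'
#' Overlapping or duplicate intervals are merged before summing, so the
#' result is idempotent and invariant to interval order or splitting.
#'
#' @param genome Genome (see [gc_content()]); lengths come from it.
#' @param intervals data.frame with `seqid`, `start`, `end` (1-based
#'   inclusive), or a [GenomicRanges::GRanges], or a BED file path (0-based
#'   half-open, converted here).
#' @param role Free-text label ("repeat", "CDS", ...) carried into the
#'   result attributes.
#' @return Fraction in `[0, 1]`.
#' @export
interval_fraction <- function(genome, intervals, role = "interval") {
  dna <- as_dna(genome)
  lens <- stats::setNames(Biostrings::width(dna), names(dna))
  if (is.character(intervals) && length(intervals) == 1) {
    bed <- utils::read.table(intervals,
                             col.names = c("seqid", "start", "end")[1:3])
    intervals <- data.frame(seqid = bed$seqid, start = bed$start + 1L,
                            end = bed$end)
  }
  if (methods::is(intervals, "GRanges")) {
    intervals <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(intervals)),
      start = GenomicRanges::start(intervals),
      end = GenomicRanges::end(intervals))
  }
  if (!nrow(intervals)) return(structure(0, role = role))
  bad <- !(intervals$seqid %in% names(lens)) |
    intervals$start < 1 | intervals$end > lens[intervals$seqid] |
    intervals$start > intervals$end
  if (any(bad))
    stop("interval outside sequence bounds at ",
         intervals$seqid[bad][1], ":", intervals$start[bad][1], "-",
         intervals$end[bad][1])
  covered <- sum(vapply(split(intervals, intervals$seqid), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    sum(IRanges::width(r))
  }, numeric(1)))
  structure(covered / sum(lens), role = role)
}

#' Exon/intron length distributions and structural summary
#'
#' Introns are derived as the gaps between consecutive exons of the same
#' transcript (exons sorted by coordinate; lengths are strand-invariant).
#' Overlapping exons within a transcript are rejected with the transcript
#' id.  The summary reports exon/intron length lists with mean, median and
#' quartiles, mean gene length, mean intergenic spacing, and the coding
#' (CDS) and exonic genome fractions when the genome is supplied.
#'
#' @param models A [read_gene_models()] table (or GFF3 path /
#'   data.frame accepted by it).
#' @param genome Optional genome for the coverage fractions.
#' @param species Label carried into the summary.
#' @return Object of class `structure_summary`: list with `species`,
#'   `exon_lengths`, `intron_lengths`, `exon_stats`, `intron_stats`
#'   (named vectors: mean, median, q1, q3, n), `mean_gene_length`,
#'   `mean_gene_spacing`, `coding_fraction` (CDS), `exonic_fraction`,
#'   `gc`, `n_genes`.
#' @export
exon_intron_lengths <- function(models, genome = NULL,
                                species = "species1") {
  if (!methods::is(models, "gene_model_set"))
    models <- read_gene_models(models)
  exons <- models[models$type == "exon", , drop = FALSE]
  genes <- models[models$type == "gene", , drop = FALSE]
  if (nrow(exons) && anyNA(exons$parent))
    stop("exon features must carry a Parent attribute")
  exon_lengths <- integer(0); intron_lengths <- integer(0)
  for (tx in unique(exons$parent)) {
    e <- exons[exons$parent == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) == 0) next
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tx)
    exon_lengths <- c(exon_lengths, e$end - e$start + 1L)
    if (nrow(e) > 1)
      intron_lengths <- c(intron_lengths,
                          e$start[-1] - e$end[-nrow(e)] - 1L)
  }
  qstats <- function(x) {
    if (!length(x))
      return(c(mean = NA_real_, median = NA_real_, q1 = NA_real_,
               q3 = NA_real_, n = 0))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
      n = length(x))
  }
  spacing <- NA_real_
  if (nrow(genes) > 1) {
    sp <- unlist(lapply(split(genes, genes$seqid), function(g) {
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) < 2) return(numeric(0))
      g$start[-1] - g$end[-nrow(g)] - 1L
    }))
    if (length(sp)) spacing <- mean(sp)
  }
  coding <- exonic <- gc <- NA_real_
  if (!is.null(genome)) {
    cds <- models[models$type == "CDS", c("seqid", "start", "end")]
    exn <- exons[, c("seqid", "start", "end")]
    coding <- if (nrow(cds)) as.numeric(interval_fraction(genome, cds,
                                                          "CDS")) else 0
    exonic <- if (nrow(exn)) as.numeric(interval_fraction(genome, exn,
                                                          "exon")) else 0
    gc <- gc_content(genome)
  }
  structure(list(species = species,
                 exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths,
                 exon_stats = qstats(exon_lengths),
                 intron_stats = qstats(intron_lengths),
                 mean_gene_length = if (nrow(genes))
                   mean(genes$end - genes$start + 1) else NA_real_,
                 mean_gene_spacing = spacing,
                 coding_fraction = coding,
                 exonic_fraction = exonic,
                 gc = gc,
                 n_genes = nrow(genes)),
            class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf(
    "Structure summary [%s]: %d genes; exon mean %.1f bp (n=%d); intron mean %.1f bp (n=%d)\n",
    x$species, x$n_genes, x$exon_stats["mean"], x$exon_stats["n"],
    x$intron_stats["mean"], x$intron_stats["n"]))
  if (!is.na(x$coding_fraction))
    cat(sprintf("  GC %.3f; coding fraction %.3f\n", x$gc,
                x$coding_fraction))
  invisible(x)
}

#' Tidy comparison table across species
#'
#' One row per (species, metric); input order preserved; metrics with no
#' data carry an explicit NA rather than being dropped.
#'
#' @param summaries List of [exon_intron_lengths()] summaries (>= 2).
#' @return data.frame `species`, `metric`, `value`.
#' @export
compare_species <- function(summaries) {
  if (length(summaries) < 2) stop("need summaries for >= 2 species")
  metrics <- c(exon_mean = function(s) unname(s$exon_stats["mean"]),
               exon_median = function(s) unname(s$exon_stats["median"]),
               intron_mean = function(s) unname(s$intron_stats["mean"]),
               intron_median = function(s) unname(s$intron_stats["median"]),
               mean_gene_length = function(s) s$mean_gene_length,
               mean_gene_spacing = function(s) s$mean_gene_spacing,
               coding_fraction = function(s) s$coding_fraction,
               gc = function(s) s$gc)
  rows <- lapply(summaries, function(s) {
    data.frame(species = s$species, metric = names(metrics),
               value = vapply(metrics, function(f) as.numeric(f(s)),
                              numeric(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
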