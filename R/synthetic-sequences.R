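# Sequence-level generators: genomes, reads, proteomes, alignments with
# planted synapomorphies, and gene models.  All are pure functions of
# (arguments, seed) and attach ground truth sufficient to score the
# consuming module.

#' Simulate a random genome sequence
#'
#' @param length Genome length in bases.
#' @param gc GC fraction (default 0.5).
#' @param seed Integer seed.
#' @return Single character string of A/C/G/T.
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Simulate shotgun reads from a genome of known size
#'
#' Uniformly placed, unstranded (half reverse-complemented) fixed-length
#' reads at a target depth; i.i.d. substitution errors at `error_rate`.
#' Total read bases equal `genome_length * depth` up to one read.
#'
#' @param genome_length Genome size in bases (a fresh genome is simulated),
#'   or a genome string via `genome=`.
#' @param depth Mean base coverage (> 0).
#' @param read_length Read length (< genome length).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed; fixed seed gives byte-identical reads.
#' @param gc GC content of the simulated genome.
#' @param genome Optional explicit genome sequence (overrides
#'   `genome_length`).
#' @return List with `reference` (genome string), `reads` (named character
#'   vector), and `truth` (`genome_size`, `depth`, `read_length`,
#'   `error_rate`, `n_errors`, `seed`).
#' @export
gen_reads <- function(genome_length, depth, read_length, error_rate = 0,
                      seed = 1L, gc = 0.5, genome = NULL) {
  if (error_rate >= 1 || error_rate < 0)
    stop("error_rate must be in [0, 1)")
  if (depth <= 0) stop("depth must be > 0")
  if (is.null(genome))
    genome <- random_genome(genome_length, gc = gc, seed = seed + 1L)
  genome_length <- nchar(genome)
  if (read_length >= genome_length)
    stop("read_length must be smaller than the genome")
  with_seed(seed, {
    n_reads <- round(genome_length * depth / read_length)
    starts <- sample.int(genome_length - read_length + 1L, n_reads,
                         replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    rc <- stats::runif(n_reads) < 0.5
    if (any(rc)) reads[rc] <- revcomp(reads[rc])
    n_err <- 0L
    if (error_rate > 0) {
      n_err <- stats::rbinom(1L, n_reads * read_length, error_rate)
      if (n_err > 0) {
        pos <- sample.int(n_reads * read_length, n_err)
        ri <- (pos - 1L) %/% read_length + 1L
        pi <- (pos - 1L) %% read_length + 1L
        for (k in seq_len(n_err)) {
          old <- substr(reads[ri[k]], pi[k], pi[k])
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          substr(reads[ri[k]], pi[k], pi[k]) <- new
        }
      }
    }
    names(reads) <- sprintf("read%07d", seq_len(n_reads))
    list(reference = genome, reads = reads,
         truth = list(genome_size = genome_length, depth = depth,
                      read_length = read_length, error_rate = error_rate,
                      n_errors = n_err, seed = as.integer(seed)))
  })
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
random_protein <- function(n_len) {
  paste(sample(AA20, n_len, replace = TRUE), collapse = "")
}

#' @noRd
mutate_protein <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  aa <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(aa)) < divergence
  if (any(hit))
    aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA20, a), 1),
                      character(1))
  paste(aa, collapse = "")
}

#' @noRd
shuffle_protein <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

#' Simulate a proteome pair with planted ortholog families
#'
#' Each planted family contributes one true ortholog pair: an ancestral
#' protein placed (mutated at `divergence/2` substitutions per site on each
#' side) in both proteomes.  Decoys are composition-preserving shuffles of
#' family members, keeping the alignment-score background realistic.
#'
#' @param n_families Number of planted ortholog families.
#' @param divergence Expected substitutions per site between the two
#'   orthologs of a pair (>= 0).
#' @param n_decoys Decoy proteins added to each proteome.
#' @param seed Integer seed.
#' @param len_range Protein length range (uniform draw), default 150-250.
#' @return List with `proteome_a`, `proteome_b` (named character vectors)
#'   and `truth$pairs` (data.frame `id_a`, `id_b`).
#' @export
gen_proteomes <- function(n_families, divergence = 0.3, n_decoys = 0,
                          seed = 1L, len_range = c(150L, 250L)) {
  if (divergence < 0) stop("divergence must be >= 0")
  with_seed(seed, {
    half <- divergence / 2
    a <- character(0); b <- character(0)
    for (f in seq_len(n_families)) {
      anc <- random_protein(sample(len_range[1]:len_range[2], 1))
      a[sprintf("A_fam%03d", f)] <- mutate_protein(anc, half)
      b[sprintf("B_fam%03d", f)] <- mutate_protein(anc, half)
    }
    pool <- c(a, b)
    for (d in seq_len(n_decoys)) {
      src_a <- if (length(pool)) sample(pool, 1) else
        random_protein(sample(len_range[1]:len_range[2], 1))
      src_b <- if (length(pool)) sample(pool, 1) else
        random_protein(sample(len_range[1]:len_range[2], 1))
      a[sprintf("A_decoy%03d", d)] <- shuffle_protein(src_a)
      b[sprintf("B_decoy%03d", d)] <- shuffle_protein(src_b)
    }
    pairs <- if (n_families > 0)
      data.frame(id_a = sprintf("A_fam%03d", seq_len(n_families)),
                 id_b = sprintf("B_fam%03d", seq_len(n_families)))
    else data.frame(id_a = character(0), id_b = character(0))
    list(proteome_a = a, proteome_b = b,
         truth = list(pairs = pairs, seed = as.integer(seed)))
  })
}

#' Simulate an alignment with planted clade-diagnostic columns
#'
#' Builds a nucleotide alignment over the tips of `tree` plus a taxon-richer
#' control alignment (extra clade members and extra outsiders) in the same
#' coordinate frame.  Planted columns are clade-diagnostic in the main
#' alignment; in the control alignment, *parallel* columns place the clade
#' state in an extra outsider and *reversal* columns revert an extra clade
#' member to the outside state, while *diagnostic* columns stay concordant
#' (genuine non-homoplasious synapomorphies).  Background columns are
#' constant except for a `background_rate` fraction of randomised columns.
#'
#' @param tree Rooted labelled [ape::phylo].
#' @param clade_label Internal node label; the clade must have >= 2 members
#'   (a single-taxon state is an autapomorphy, not a synapomorphy).
#' @param aln_length Total alignment length.
#' @param n_diagnostic,n_parallel,n_reversal Planted column counts; their
#'   sum must not exceed `aln_length`.
#' @param background_rate Fraction of non-planted columns fully randomised.
#' @param seed Integer seed.
#' @param n_extra_in,n_extra_out Extra control taxa inside / outside the
#'   clade (default 2 each).
#' @return List with `aln` (an [alignment_block()]), `control`
#'   (alignment_block over main + extra taxa), `clade_members` (clade taxa
#'   incl. control-only members), and `truth` (`diagnostic`, `parallel`,
#'   `reversal` column indices, 1-based).
#' @export
gen_alignment_with_synapomorphies <- function(tree, clade_label, aln_length,
                                              n_diagnostic = 0,
                                              n_parallel = 0,
                                              n_reversal = 0,
                                              background_rate = 0,
                                              seed = 1L,
                                              n_extra_in = 2L,
                                              n_extra_out = 2L) {
  tree <- ensure_node_labels(tree)
  v <- node_id(tree, clade_label)
  members <- tree$tip.label[tips_under(tree, v)]
  if (length(members) < 2)
    stop("clade of size 1: an autapomorphy, not a synapomorphy")
  outsiders <- setdiff(tree$tip.label, members)
  if (!length(outsiders)) stop("clade must not cover the whole tree")
  n_plant <- n_diagnostic + n_parallel + n_reversal
  if (n_plant > aln_length)
    stop("planted columns exceed alignment length")
  nt <- c("A", "C", "G", "T")
  extra_in <- if (n_extra_in > 0)
    sprintf("%s_ctrl_in%02d", clade_label, seq_len(n_extra_in))
  else character(0)
  extra_out <- if (n_extra_out > 0)
    sprintf("ctrl_out%02d", seq_len(n_extra_out)) else character(0)
  main_taxa <- tree$tip.label
  ctrl_taxa <- c(main_taxa, extra_in, extra_out)
  with_seed(seed, {
    main <- matrix("", length(main_taxa), aln_length,
                   dimnames = list(main_taxa, NULL))
    ctrl <- matrix("", length(ctrl_taxa), aln_length,
                   dimnames = list(ctrl_taxa, NULL))
    # background: per-column shared state, randomised at background_rate
    base_state <- sample(nt, aln_length, replace = TRUE)
    for (j in seq_len(aln_length)) {
      main[, j] <- base_state[j]
      ctrl[, j] <- base_state[j]
    }
    noisy <- which(stats::runif(aln_length) < background_rate)
    for (j in noisy) {
      main[, j] <- sample(nt, length(main_taxa), replace = TRUE)
      ctrl[main_taxa, j] <- main[, j]
      ctrl[c(extra_in, extra_out), j] <-
        sample(nt, length(extra_in) + length(extra_out), replace = TRUE)
    }
    cols <- sample.int(aln_length, n_plant)
    classes <- rep(c("diagnostic", "parallel", "reversal"),
                   c(n_diagnostic, n_parallel, n_reversal))
    for (k in seq_along(cols)) {
      j <- cols[k]
      states <- sample(nt, 2)
      clade_state <- states[1]; out_state <- states[2]
      main[members, j] <- clade_state
      main[outsiders, j] <- out_state
      ctrl[members, j] <- clade_state
      ctrl[outsiders, j] <- out_state
      ctrl[extra_in, j] <- clade_state
      ctrl[extra_out, j] <- out_state
      if (classes[k] == "parallel" && length(extra_out))
        ctrl[extra_out[1], j] <- clade_state
      if (classes[k] == "reversal" && length(extra_in))
        ctrl[extra_in[1], j] <- out_state
    }
    truth <- list(diagnostic = sort(cols[classes == "diagnostic"]),
                  parallel = sort(cols[classes == "parallel"]),
                  reversal = sort(cols[classes == "reversal"]))
    list(aln = alignment_block(apply(main, 1, paste, collapse = ""),
                               locus = "main", alphabet = "DNA"),
         control = alignment_block(apply(ctrl, 1, paste, collapse = ""),
                                   locus = "control", alphabet = "DNA"),
         clade_members = c(members, extra_in),
         truth = truth)
  })
}

#' Simulate gene models with known exon/intron structure
#'
#' Genes are laid out without overlap on a single contig: intergenic gap,
#' then alternating exons and introns.  Every transcript's CDS equals its
#' exons (ab initio style, no UTRs), so the true coding fraction is the
#' exonic fraction.  Coordinates are 1-based inclusive (GFF3).
#'
#' @param n_genes Number of genes.
#' @param exon_length_law,intron_length_law,intergenic_law Functions
#'   `n -> n` positive lengths; defaults log-normal-ish draws.
#' @param n_exons_law Function `() -> 1` exon count per gene (default
#'   1-6 uniform).
#' @param seed Integer seed.
#' @param gc GC content of the genome sequence.
#' @return List with `genome` (named character vector, one contig), `gff`
#'   (data.frame in GFF3 column layout) and `truth` (`exon_lengths`,
#'   `intron_lengths`, `cds_fraction`, `gene_spans`).
#' @export
gen_gene_models <- function(n_genes,
                            exon_length_law = function(n)
                              pmax(30L, as.integer(stats::rlnorm(n, 5, 0.5))),
                            intron_length_law = function(n)
                              pmax(20L, as.integer(stats::rlnorm(n, 4.5, 0.4))),
                            intergenic_law = function(n)
                              pmax(50L, as.integer(stats::rlnorm(n, 5.5, 0.5))),
                            n_exons_law = function() sample(1:6, 1),
                            seed = 1L, gc = 0.5) {
  with_seed(seed, {
    rows <- list(); pos <- 0L
    exon_lengths <- integer(0); intron_lengths <- integer(0)
    gene_spans <- integer(0)
    for (g in seq_len(n_genes)) {
      gap <- as.integer(intergenic_law(1))
      stopifnot(gap > 0)
      pos <- pos + gap
      k <- n_exons_law()
      ex <- as.integer(exon_length_law(k))
      intr <- if (k > 1) as.integer(intron_length_law(k - 1)) else integer(0)
      stopifnot(all(ex > 0), all(intr > 0))
      gid <- sprintf("gene%04d", g)
      strand <- if (g %% 2 == 0) "-" else "+"
      gstart <- pos + 1L
      estart <- gstart
      exon_rows <- list()
      for (e in seq_len(k)) {
        eend <- estart + ex[e] - 1L
        exon_rows[[e]] <- c(estart, eend)
        if (e < k) estart <- eend + intr[e] + 1L
      }
      gend <- exon_rows[[k]][2]
      rows[[length(rows) + 1]] <- data.frame(
        seqid = "contig1", source = "sim", type = "gene",
        start = gstart, end = gend, score = ".", strand = strand,
        phase = ".", attributes = sprintf("ID=%s", gid))
      mid <- paste0(gid, ".t1")
      rows[[length(rows) + 1]] <- data.frame(
        seqid = "contig1", source = "sim", type = "mRNA",
        start = gstart, end = gend, score = ".", strand = strand,
        phase = ".", attributes = sprintf("ID=%s;Parent=%s", mid, gid))
      for (e in seq_len(k)) {
        for (ty in c("exon", "CDS")) {
          rows[[length(rows) + 1]] <- data.frame(
            seqid = "contig1", source = "sim", type = ty,
            start = exon_rows[[e]][1], end = exon_rows[[e]][2],
            score = ".", strand = strand, phase = if (ty == "CDS") "0" else ".",
            attributes = sprintf("ID=%s.%s%d;Parent=%s", mid,
                                 tolower(ty), e, mid))
        }
      }
      exon_lengths <- c(exon_lengths, ex)
      intron_lengths <- c(intron_lengths, intr)
      gene_spans <- c(gene_spans, gend - gstart + 1L)
      pos <- gend
    }
    pos <- pos + as.integer(intergenic_law(1))   # trailing intergenic
    genome_len <- max(pos, 1L)
    genome <- stats::setNames(
      random_genome(genome_len, gc = gc, seed = seed + 7L), "contig1")
    gff <- if (length(rows)) do.call(rbind, rows) else
      data.frame(seqid = character(0), source = character(0),
                 type = character(0), start = integer(0), end = integer(0),
                 score = character(0), strand = character(0),
                 phase = character(0), attributes = character(0))
    cds_fraction <- if (n_genes > 0) sum(exon_lengths) / genome_len else 0
    list(genome = genome, gff = gff,
         truth = list(exon_lengths = exon_lengths,
                      intron_lengths = intron_lengths,
                      cds_fraction = cds_fraction,
                      gene_spans = gene_spans,
                      genome_length = genome_len,
                      seed = as.integer(seed)))
  })
}

#' Write a GFF3 data.frame to file
#'
#' @param gff data.frame in GFF3 column layout (as from
#'   [gen_gene_models()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  if (nrow(gff))
    utils::write.table(gff, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
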